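# Fixtures, storage and configuration plumbing: the conjugate-Gaussian
# test problem with a closed-form posterior, columnar on-disk storage for
# simulation tables, and preset prior boxes for the bundled simulators.

#' Conjugate-Gaussian test problem with closed-form posterior
#'
#' Builds the linear-Gaussian fixture `x = theta + eps`,
#' `eps ~ N(0, noise_cov)`, with Gaussian prior `N(prior_mean, prior_cov)`.
#' The posterior is available in closed form, making the fixture the
#' canonical oracle for testing inference machinery.
#'
#' @param dim Dimensionality.
#' @param prior_mean,prior_cov Prior moments (defaults: standard normal).
#' @param noise_cov Observation noise covariance (default identity).
#' @return A list with elements `prior`, `simulator(theta, seed)`,
#'   `extractor(raw)`, and `posterior(x_o)` returning the analytic
#'   posterior as a list with `mean`, `cov`, `log_density(theta)` and
#'   `sample(n)`.
#' @export
conjugate_fixture <- function(dim = 2L, prior_mean = rep(0, dim),
                              prior_cov = diag(1, dim),
                              noise_cov = diag(1, dim)) {
  if (!is.matrix(prior_cov)) prior_cov <- diag(prior_cov, dim)
  if (!is.matrix(noise_cov)) noise_cov <- diag(noise_cov, dim)
  prior <- prior_gaussian(prior_mean, prior_cov)
  noise_chol <- chol(noise_cov)
  simulator <- function(theta, seed = NULL) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    as.numeric(theta) + as.numeric(rnorm(dim) %*% noise_chol)
  }
  extractor <- identity
  posterior <- function(x_o) {
    # precision-weighted combination of prior and likelihood
    P0 <- solve(prior_cov); Pn <- solve(noise_cov)
    S <- solve(P0 + Pn)
    m <- as.numeric(S %*% (P0 %*% prior_mean + Pn %*% as.numeric(x_o)))
    ch <- chol(S)
    list(
      mean = m, cov = S,
      log_density = function(theta) {
        theta <- as_row_matrix(theta)
        dev <- sweep(theta, 2L, m, "-")
        y <- t(backsolve(ch, t(dev), transpose = TRUE))
        -0.5 * dim * log(2 * pi) - sum(log(diag(ch))) - 0.5 * rowSums(y^2)
      },
      sample = function(n, seed = NULL) {
        if (!is.null(seed)) set.seed(as.integer(seed))
        sweep(matrix(rnorm(n * dim), n, dim) %*% ch, 2L, m, "+")
      }
    )
  }
  list(prior = prior, simulator = simulator, extractor = extractor,
       posterior = posterior, dim = dim)
}

#' Save / load a simulation table as a columnar container
#'
#' Tables are stored column-by-column (Parquet when the `arrow` package is
#' available, RDS otherwise) together with a plain-text YAML sidecar naming
#' the simulator, prior and extractor provenance.  Round trips are
#' bit-exact for double-precision columns.
#'
#' @param tab A [simulation_table()].
#' @param path Output file path.
#' @param meta Optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
save_table <- function(tab, path, meta = list()) {
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(as.data.frame(tab), path)
    fmt <- "parquet"
  } else {
    saveRDS(as.data.frame(tab), path)
    fmt <- "rds"
  }
  side <- c(list(format = fmt, n_rows = nrow(tab),
                 columns = names(tab), schema_version = 1L), meta)
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path) {
  side_path <- paste0(path, ".meta.yaml")
  if (!file.exists(side_path)) stop("missing table sidecar metadata", call. = FALSE)
  side <- yaml::read_yaml(side_path)
  if (is.null(side$schema_version) || side$schema_version != 1L) {
    stop("unsupported simulation-table schema version", call. = FALSE)
  }
  df <- if (identical(side$format, "parquet")) {
    as.data.frame(arrow::read_parquet(path))
  } else {
    readRDS(path)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("simulation_table", class(out))
  out
}

#' Preset model configurations
#'
#' Returns the bundled prior specification (and default settings) for one
#' of the named models, read from the versioned YAML presets shipped with
#' the package.
#'
#' @param model One of `"glm_temporal"`, `"gabor"`, `"omnimodel"`, `"hh"`,
#'   `"stg"`.
#' @return A list with at least `prior` (a `prior` object) and the raw
#'   preset fields.
#' @export
model_preset <- function(model = c("glm_temporal", "gabor", "omnimodel",
                                   "hh", "stg")) {
  model <- match.arg(model)
  path <- system.file("extdata", "presets", paste0(model, ".yaml"),
                      package = "snpet")
  cfg <- yaml::read_yaml(path)
  prior <- switch(model,
    glm_temporal = glm_temporal_prior(sigma = cfg$prior$sigma),
    gabor = gabor_prior(),
    omnimodel = prior_box(unlist(cfg$prior$lower), unlist(cfg$prior$upper),
                          names = unlist(cfg$prior$names)),
    hh = prior_box(unlist(cfg$prior$lower), unlist(cfg$prior$upper),
                   names = unlist(cfg$prior$names)),
    stg = stg_prior()
  )
  c(list(prior = prior), cfg)
}
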