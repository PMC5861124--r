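# Run configuration, profile/fit serialization, fixtures, logging.

#' Synthetic cyclization-profile fixture
#'
#' Evaluates the periodic piecewise-quadratic profile form at the given
#' lengths and optionally adds independent Gaussian noise — a cheap stand-in
#' for a Monte Carlo profile when exercising the fitting layer.
#'
#' @param params list (or `profile_fit`) with `phi, p, a, b, c`.
#' @param N_range lengths, bp.
#' @param noise_sigma Gaussian noise standard deviation in log10 J units.
#' @param seed optional seed for the noise.
#' @return data frame with columns `N`, `log10J`.
#' @export
generate_profile_fixture <- function(params, N_range = 146:170,
                                     noise_sigma = 0, seed = NULL) {
  stopifnot(all(c("phi", "p", "a", "b", "c") %in% names(params)),
            noise_sigma >= 0)
  y <- predict_profile(params, N_range)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sigma)
  }
  data.frame(N = N_range, log10J = y)
}

#' Read and write cyclization profiles as CSV
#'
#' Profiles are stored with columns `N, log10J, stderr, hits, M, censored`
#' (extra columns written by other tools are preserved on read; only `N` and
#' `log10J` are required).
#'
#' @param profile data frame (e.g. from [cyclization_profile()]).
#' @param file CSV path.
#' @return `read_profile_csv` returns the data frame; `write_profile_csv`
#'   returns `file` invisibly.
#' @export
write_profile_csv <- function(profile, file) {
  stopifnot(is.data.frame(profile), all(c("N", "log10J") %in% names(profile)))
  utils::write.csv(profile, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("N", "log10J") %in% names(df)))
    stop("profile CSV must have columns N and log10J")
  df
}

#' Write a profile fit as JSON
#'
#' @param fit a `profile_fit`.
#' @param file JSON path.
#' @return `file`, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "profile_fit"))
  jsonlite::write_json(unclass(fit)[c("phi", "p", "a", "b", "c", "rss", "n")],
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a run configuration
#'
#' A run configuration is YAML (or JSON) with a `molecule` block (see
#' [read_molecule()] for its fields), and optional `N_range` (two-element
#' min/max or explicit list; default 146-170), `M`, `eps`, `delta`,
#' `n_z_bins`, `seed`. Every referenced field is validated before any
#' sampling starts; a missing or invalid field is reported by name.
#'
#' @param file YAML or JSON path.
#' @return validated list of class `run_config`.
#' @export
read_run_config <- function(file) {
  x <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = FALSE)
       else yaml::read_yaml(file)
  if (is.null(x$molecule)) stop("run config is missing field: molecule")
  spec <- .spec_from_list(x$molecule)
  nr <- x$N_range
  N_range <- if (is.null(nr)) 146:170
             else if (length(nr) == 2L) seq.int(nr[[1]], nr[[2]])
             else as.integer(unlist(nr))
  if (any(N_range < spec$N * 0 + 2)) stop("invalid field: N_range")
  num1 <- function(field, default, lo = -Inf) {
    v <- x[[field]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= lo)
      stop("invalid field: ", field)
    v
  }
  cfg <- list(molecule = spec,
              N_range = N_range,
              M = as.integer(num1("M", 2^16, lo = 0)),
              tol = closure_tolerances(num1("eps", 30, lo = 0),
                                       num1("delta", 0.3, lo = 0)),
              grid = bin_grid(num1("n_z_bins", 128, lo = 0)),
              seed = as.integer(num1("seed", 1)))
  class(cfg) <- "run_config"
  cfg
}

#' Run a configured cyclization-profile experiment
#'
#' Computes the cyclization profile of the configured molecule family (the
#' configured molecule's segments at every N in `N_range`), fits it, runs the
#' tolerance-halving convergence check at the first uncensored length, and
#' writes `profile.csv`, `fit.json` and `run.log` to `out_dir`. Files are
#' written atomically (temp file, then rename). Reruns with the same
#' configuration reproduce the profile bit for bit.
#'
#' @param config a `run_config` (from [read_run_config()]) or a path to one.
#' @param out_dir output directory, created if needed.
#' @return list with `profile`, `fit` (NULL if too few uncensored points),
#'   `convergence`, and the output `paths`.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec0 <- config$molecule
  spec_fun <- function(N) {
    s <- spec0; s$N <- as.integer(N); s
  }
  profile <- cyclization_profile(spec_fun, config$N_range, config$M,
                                 config$tol, config$seed, grid = config$grid)
  # convergence check at the best-cyclizing length, reusing its ensembles
  kbest <- which.max(ifelse(profile$censored, -Inf, profile$hits))
  conv <- NULL
  if (length(kbest) == 1L && !profile$censored[kbest]) {
    seeds <- matrix(.half_seeds(config$seed, 2L * nrow(profile)), ncol = 2L)
    spc <- spec_fun(profile$N[kbest])
    m <- ceiling((profile$N[kbest] + 1) / 2)
    fh <- generate_half_ensemble(spc, "first", m, config$M, seeds[kbest, 1L])
    sh <- generate_half_ensemble(spc, "second", m, config$M, seeds[kbest, 2L])
    conv <- tolerance_convergence(fh, sh, config$tol, config$grid)
  }
  fit <- if (sum(!profile$censored) >= 10)
    fit_profile(profile, weights = 1 / profile$stderr^2) else NULL

  atomically <- function(write_fun, path) {
    tmp <- paste0(path, ".tmp")
    write_fun(tmp)
    file.rename(tmp, path)
    path
  }
  paths <- list(
    profile = atomically(function(f) write_profile_csv(profile, f),
                         file.path(out_dir, "profile.csv")),
    fit = if (!is.null(fit))
      atomically(function(f) write_fit_json(fit, f),
                 file.path(out_dir, "fit.json")),
    log = file.path(out_dir, "run.log")
  )
  log_lines <- c(
    sprintf("dnacyclize run: N = %s, M = %d, eps = %g A, delta = %g, seed = %d",
            paste(range(config$N_range), collapse = "-"), config$M,
            config$tol$eps, config$tol$delta, config$seed),
    sprintf("hits: %s", paste(round(profile$hits), collapse = " ")),
    sprintf("censored lengths: %s",
            if (any(profile$censored)) paste(profile$N[profile$censored],
                                             collapse = " ") else "none"),
    if (!is.null(conv) && isTRUE(!conv$converged))
      sprintf("WARNING: tolerance-halving check failed (shift %.3f, se %.3f): tolerances too coarse",
              conv$shift, conv$se)
    else if (!is.null(conv) && isTRUE(conv$converged))
      sprintf("tolerance-halving check passed (shift %.3f, se %.3f)",
              conv$shift, conv$se),
    if (!is.null(fit))
      sprintf("fit: phi %.2f p %.2f a %.3f b %.4f c %.4f", fit$phi, fit$p,
              fit$a, fit$b, fit$c)
  )
  atomically(function(f) writeLines(log_lines, f), paths$log)
  list(profile = profile, fit = fit, convergence = conv, paths = paths)
}
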