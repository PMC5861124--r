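# Fitting cyclization profiles to the piecewise-quadratic periodic form
#
#   log10 J = a + b (N - phi) + c [f(N, phi, p)]^2,
#   f(N, phi, p) = mod(N - phi + p/2, p) - p/2,
#
# and the downstream knob-regression / degeneracy / calibration layer.

#' Periodic sawtooth deviation from the nearest peak
#'
#' `f(N, phi, p) = mod(N - phi + p/2, p) - p/2`: the signed distance (in bp)
#' from N to the nearest profile peak `phi + k p`, ranging over
#' `[-p/2, p/2)` and vanishing exactly at the peaks.
#'
#' @param N length in basepairs (vectorized).
#' @param phi location of a peak, bp.
#' @param p oscillation period, bp (positive).
#' @return numeric vector.
#' @export
f_periodic <- function(N, phi, p) {
  if (!is.numeric(p) || any(p <= 0)) stop("period p must be positive")
  (N - phi + p / 2) %% p - p / 2
}

# weighted linear fit of y ~ 1 + N + f^2 at fixed (phi, p); returns
# list(coef = c(a, b, c) in the a + b(N - phi) + c f^2 parameterization, rss);
# with nonpos_c, a positive quadratic coefficient is rejected (rss = Inf)
.fit_linear_at <- function(N, y, w, phi, p, nonpos_c = FALSE) {
  f2 <- f_periodic(N, phi, p)^2
  X <- cbind(1, N - phi, f2)
  fit <- stats::lm.wfit(X, y, w)
  rss <- sum(w * fit$residuals^2)
  if (nonpos_c && !is.na(fit$coefficients[3]) && fit$coefficients[3] > 0)
    rss <- Inf
  list(coef = unname(fit$coefficients), rss = rss)
}

#' Fit a cyclization profile to the periodic piecewise-quadratic form
#'
#' Least-squares fit of `y = a + b (N - phi) + c f(N, phi, p)^2` to a
#' cyclization profile. For fixed `(phi, p)` the model is linear in
#' `(a, b, c)` and solved exactly; `(phi, p)` are found by a dense grid
#' (phi step 0.02 bp over `(145, 145 + p]`, p step 0.01 bp over
#' `[9.5, 11.5]`) followed by local polish. The fitted `phi` is reported
#' in `(145, 145 + p]`; ties break to the smallest admissible `phi`.
#' Censored points (NA y) are dropped.
#'
#' @param profile data frame with columns `N` and `log10J` (or `y`), e.g.
#'   from [cyclization_profile()] or [read_profile_csv()].
#' @param weights optional fit weights (e.g. `1/stderr^2`); default unweighted.
#' @param p_range period search interval, bp.
#' @param phi_step,p_step grid resolutions, bp.
#' @param polish run local optimization from the best grid point.
#' @param c_sign `"free"` or `"nonpositive"`: optionally constrain the fitted
#'   quadratic coefficient to `c <= 0`. All molecules in the studied regime
#'   oscillate with peaks at `f = 0`; on sparse, noisy profiles the
#'   unconstrained fit can latch onto the anti-phase `c > 0` branch, and the
#'   constraint removes that degeneracy.
#' @return object of class `profile_fit`: list with `phi, p, a, b, c, rss, n`.
#' @export
fit_profile <- function(profile, weights = NULL, p_range = c(9.5, 11.5),
                        phi_step = 0.02, p_step = 0.01, polish = TRUE,
                        c_sign = c("free", "nonpositive")) {
  c_sign <- match.arg(c_sign)
  nonpos <- c_sign == "nonpositive"
  if (is.data.frame(profile)) {
    N <- profile$N
    y <- if (!is.null(profile$log10J)) profile$log10J else profile$y
  } else stop("profile must be a data frame with columns N and log10J (or y)")
  if (is.null(y)) stop("profile has no log10J (or y) column")
  keep <- is.finite(N) & is.finite(y)
  if (!is.null(weights)) keep <- keep & is.finite(weights)
  N <- N[keep]; y <- y[keep]
  w <- if (is.null(weights)) rep(1, length(N)) else weights[keep]
  if (length(N) < 10) stop("need at least 10 uncensored points")
  if (diff(range(N)) < 1.5 * p_range[1])
    stop("profile must span at least 1.5 periods")

  S0 <- sum(w); SN <- sum(w * N); SNN <- sum(w * N^2)
  Sy <- sum(w * y); SNy <- sum(w * N * y); Syy <- sum(w * y^2)
  scale <- Syy + 1e-300

  best <- list(rss = Inf, phi = NA_real_, p = NA_real_)
  any_ok <- FALSE
  for (p in seq(p_range[1], p_range[2], by = p_step)) {
    phis <- seq(145 + phi_step, 145 + p, by = phi_step)
    Fm <- (outer(N, phis, "-") + p / 2) %% p - p / 2  # f(N, phi, p)
    F2 <- Fm * Fm
    A  <- colSums(w * F2)
    B  <- colSums(w * N * F2)
    C4 <- colSums(w * F2 * F2)
    D  <- colSums(w * y * F2)
    # symmetric 3x3 solve by cofactors, vectorized over phi
    C11 <- SNN * C4 - B * B
    C12 <- A * B - SN * C4
    C13 <- SN * B - SNN * A
    C22 <- S0 * C4 - A * A
    C23 <- SN * A - S0 * B
    C33 <- S0 * SNN - SN * SN
    det <- S0 * C11 + SN * C12 + A * C13
    ok <- abs(det) > 1e-9 * (abs(S0 * SNN * C4) + scale)
    if (!any(ok)) next
    any_ok <- TRUE
    x1 <- (C11 * Sy + C12 * SNy + C13 * D) / det
    x2 <- (C12 * Sy + C22 * SNy + C23 * D) / det
    x3 <- (C13 * Sy + C23 * SNy + C33 * D) / det
    rss <- Syy - (x1 * Sy + x2 * SNy + x3 * D)
    rss[!ok] <- Inf
    if (nonpos) rss[x3 > 0] <- Inf
    k <- which.min(rss)
    if (rss[k] < best$rss) best <- list(rss = rss[k], phi = phis[k], p = p)
  }
  if (!any_ok)
    stop("degenerate design: all lengths fall at the same phase")
  if (!is.finite(best$rss))
    stop("no admissible fit on the grid")

  phi <- best$phi; p <- best$p
  if (polish) {
    obj <- function(par) {
      if (par[2] <= 0) return(Inf)
      .fit_linear_at(N, y, w, par[1], par[2], nonpos)$rss
    }
    opt <- stats::optim(c(phi, p), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    # restart once: Nelder-Mead can stall on the piecewise-smooth surface
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 5000))
    if (opt2$value <= best$rss + 1e-12 * scale) {
      phi <- opt2$par[1]; p <- opt2$par[2]
    }
  }
  # report phi in (145, 145 + p]
  r <- (phi - 145) %% p
  phi <- 145 + (if (r == 0) p else r)
  lin <- .fit_linear_at(N, y, w, phi, p)
  if (nonpos && !is.na(lin$coef[3]) && lin$coef[3] > 0) {
    # boundary solution: flat quadratic term
    X <- cbind(1, N - phi)
    fl <- stats::lm.wfit(X, y, w)
    lin <- list(coef = c(unname(fl$coefficients), 0),
                rss = sum(w * fl$residuals^2))
  }
  structure(list(phi = phi, p = p, a = lin$coef[1], b = lin$coef[2],
                 c = lin$coef[3], rss = lin$rss, n = length(N)),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(paste0("profile_fit: phi = %.2f bp, p = %.2f bp, a = %.3f, ",
                     "b = %.4f, c = %.4f (rss %.3g, n = %d)\n"),
              x$phi, x$p, x$a, x$b, x$c, x$rss, x$n))
  cat(sprintf("  peak-to-trough difference -c (p/2)^2 = %.3f\n",
              -x$c * (x$p / 2)^2))
  invisible(x)
}

#' Evaluate the fitted profile form
#'
#' @param fit a `profile_fit` (or list with `phi, p, a, b, c`).
#' @param N lengths at which to evaluate.
#' @return fitted log10 J values.
#' @export
predict_profile <- function(fit, N) {
  fit$a + fit$b * (N - fit$phi) + fit$c * f_periodic(N, fit$phi, fit$p)^2
}

#' Linear regression of a fitted profile parameter on a model knob
#'
#' Ordinary (optionally weighted) least squares of one fitted profile
#' parameter against a model knob measured from a reference point, e.g.
#' peak height `a` against bend angle minus 90 degrees.
#'
#' @param fits data frame with one row per molecule and a column named
#'   `param`, e.g. from [reference_fits()] or by row-binding `profile_fit`
#'   results; alternatively a numeric vector of parameter values.
#' @param knob_values numeric knob values, one per row.
#' @param param name of the parameter column (`"phi"`, `"p"`, `"a"`, `"b"`,
#'   `"c"`).
#' @param reference knob reference value subtracted before regression.
#' @return object of class `knob_regression`: list with `slope`,
#'   `intercept`, `knob_name`, `reference`, `n`.
#' @export
knob_regression <- function(fits, knob_values, param = "a", reference = 0) {
  yv <- if (is.data.frame(fits)) {
    if (is.null(fits[[param]])) stop("no column named '", param, "'")
    fits[[param]]
  } else as.numeric(fits)
  stopifnot(length(yv) == length(knob_values))
  keep <- is.finite(yv) & is.finite(knob_values)
  if (sum(keep) < 3) stop("knob regression needs at least 3 points")
  x <- knob_values[keep] - reference
  co <- stats::coef(stats::lm(yv[keep] ~ x))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 param = param, knob_name = deparse(substitute(knob_values)),
                 reference = reference, n = sum(keep)),
            class = "knob_regression")
}

#' @export
print.knob_regression <- function(x, ...) {
  cat(sprintf("%s ~ %.4g %+.4g (knob - %g)   [n = %d]\n",
              x$param, x$intercept, x$slope, x$reference, x$n))
  invisible(x)
}

#' Reference profile-fit parameter tables
#'
#' Published best-fit `(phi, p, a, b, c)` values for the single-knob molecule
#' families of the baseline analysis (bend angle; overall stiffness scale;
#' helical repeat; left- and right-handed bend non-planarity; twist-to-bend
#' stiffness ratio), shipped as plain-text tables. These are the inputs to
#' the knob-regression layer and to its acceptance checks.
#'
#' @param family one of `"bend_angle"`, `"stiffness_scale"`,
#'   `"helical_repeat"`, `"pitch_left"`, `"pitch_right"`,
#'   `"twist_stiffness"`.
#' @return data frame with the knob column and `phi, p, a, b, c`.
#' @export
reference_fits <- function(family = c("bend_angle", "stiffness_scale",
                                      "helical_repeat", "pitch_left",
                                      "pitch_right", "twist_stiffness")) {
  family <- match.arg(family)
  path <- system.file("extdata", paste0("fits_", family, ".csv"),
                      package = "dnacyclize", mustWork = TRUE)
  utils::read.csv(path)
}

# published regression constants of the single-knob calibration layer
.CAL <- list(
  a_base        = 1.325,   # combined intercept of the bend/stiffness relation
  a_per_bend    = 0.021,   # d a / d bend (deg^-1), bend in [60, 120]
  a_bend_int    = 1.31,    # intercept of the bend-only relation at 90 deg
  a_per_beta    = -4.45,   # d a / d beta
  phi_base      = 147.2,
  phi_per_rep   = 14.3,    # d phi / d helical repeat
  phi_per_pc    = 2.45,    # merged d phi / d (Pitch/Circumf)
  a_per_abs_pc  = 0.3,     # -d a / d |Pitch/Circumf|
  pc_per_rep    = -5.84,   # degenerate-family Pitch/Circumf per repeat
  bend_per_abs_pc = 14.3,  # published 0.3 / 0.021, as rounded in the rule
  bend_per_beta = 212,     # published 4.45 / 0.021
  c_base        = -0.114,
  c_per_k3      = -0.077,  # d c / d (K3/K1)
  a_per_k3      = 0.30,
  k3_ref        = 1.5,
  bend_ref      = 90,
  rep_ref       = 10.5
)

#' Families of molecules with degenerate cyclization profiles
#'
#' Constructs molecule families predicted to share a cyclization profile.
#' `"bend-stiffness"` trades intrinsic bend against the overall stiffness
#' scale: `bend = 90 + 212 (beta - 1)` degrees, with `beta` the knob.
#' `"twist-helicity-bend"` compensates a change of helical repeat with bend
#' non-planarity and bend angle:
#' `Pitch/Circumf = -5.84 (repeat - 10.5)` and
#' `bend = 90 + 14.3 |Pitch/Circumf|` degrees, with the helical repeat the
#' knob. Knobs outside the validated ranges (bend within 60 to 120 degrees,
#' `|Pitch/Circumf| <= 1`) are an error.
#'
#' @param kind `"bend-stiffness"` or `"twist-helicity-bend"`.
#' @param knob_values `beta` values, or helical repeats.
#' @param N molecule length for the constructed specs.
#' @param bend_bp basepairs carrying the bend.
#' @return list with `specs` (list of [molecule_spec()]) and `table`
#'   (data frame of the knob and derived parameters).
#' @export
degenerate_family <- function(kind = c("bend-stiffness", "twist-helicity-bend"),
                              knob_values, N = 147, bend_bp = 63) {
  kind <- match.arg(kind)
  cal <- .CAL
  if (kind == "bend-stiffness") {
    beta <- knob_values
    bend <- cal$bend_ref + cal$bend_per_beta * (beta - 1)
    if (any(bend < 60 | bend > 120))
      stop("beta ", paste(beta[bend < 60 | bend > 120], collapse = ", "),
           " maps to a bend angle outside the validated 60-120 degree range")
    specs <- lapply(seq_along(beta), function(i)
      bent_molecule(N, bend_deg = bend[i], bend_bp = bend_bp,
                    stiffness = stiffness_set(scale_beta = beta[i])))
    table <- data.frame(beta = beta, bend_deg = bend)
  } else {
    rep_ <- knob_values
    pc <- cal$pc_per_rep * (rep_ - cal$rep_ref)
    if (any(abs(pc) > 1))
      stop("helical repeat ", paste(rep_[abs(pc) > 1], collapse = ", "),
           " needs |Pitch/Circumf| > 1, outside the validated range")
    bend <- cal$bend_ref + cal$bend_per_abs_pc * abs(pc)
    if (any(bend < 60 | bend > 120))
      stop("compensating bend angle falls outside the validated 60-120 degree range")
    specs <- lapply(seq_along(rep_), function(i)
      bent_molecule(N, bend_deg = bend[i], bend_bp = bend_bp,
                    pitch_over_circumf = pc[i], helical_repeat = rep_[i]))
    table <- data.frame(helical_repeat = rep_, pitch_over_circumf = pc,
                        bend_deg = bend)
  }
  list(specs = specs, table = table)
}

#' Calibrate a complex DNA model down to two parameters
#'
#' Inverts the knob regressions to express a fitted cyclization profile as an
#' overall stiffness scale `beta` and a twist-to-bend ratio `K3/K1`:
#' `K3/K1` is read off the quadratic coefficient through
#' `c = -0.114 - 0.077 (K3/K1 - 1.5)`, and `beta` from the peak height
#' through `a = 1.325 + 0.021 (bend - 90) - 4.45 (beta - 1)`, given an
#' independently estimated intrinsic bend. With `refine = TRUE` the baseline
#' of the `a` relation is first shifted by `0.30 (K3/K1 - 1.5)` to account
#' for the peak-height dependence on `K3/K1`.
#'
#' @param a_fit fitted peak height `a` (log10 nM).
#' @param c_fit fitted quadratic coefficient `c` (per bp^2).
#' @param bend_estimate_deg independently estimated intrinsic bend, degrees.
#' @param refine apply the `K3/K1` baseline shift when solving for `beta`.
#' @return list with `K3_over_K1`, `beta`, `beta_unrefined`, and
#'   `extrapolated` (TRUE when any inverted knob leaves its calibrated
#'   range: `K3/K1` in 0.5-1.5, `beta` in 0.87-1.13, bend in 60-120).
#' @export
calibrate_simple_model <- function(a_fit, c_fit, bend_estimate_deg,
                                   refine = TRUE) {
  stopifnot(is.finite(a_fit), is.finite(c_fit), is.finite(bend_estimate_deg))
  cal <- .CAL
  k3 <- cal$k3_ref + (c_fit - cal$c_base) / cal$c_per_k3
  solve_beta <- function(a0)
    1 + (a0 + cal$a_per_bend * (bend_estimate_deg - cal$bend_ref) - a_fit) /
      (-cal$a_per_beta)
  beta0 <- solve_beta(cal$a_base)
  beta <- if (refine) solve_beta(cal$a_base + cal$a_per_k3 * (k3 - cal$k3_ref))
          else beta0
  extrap <- k3 < 0.5 || k3 > 1.5 || beta < 0.87 || beta > 1.13 ||
    bend_estimate_deg < 60 || bend_estimate_deg > 120
  list(K3_over_K1 = k3, beta = beta, beta_unrefined = beta0,
       extrapolated = extrap)
}
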