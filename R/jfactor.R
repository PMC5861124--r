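# Half-molecule Monte Carlo J-factor estimation.
#
# Cyclization is the coincidence of frame 1 and the fictitious frame N+1.
# M sampled first halves and M second halves give M^2 effective molecules;
# a pair "closes" when the end-to-end distance is within eps (Angstrom) and
# the relative rotation is within delta in the sin(phi/2) metric. J is the
# hit fraction divided by the closure volume (4/3) pi eps^3 times the
# normalized Haar ball volume, converted to nM.

# 1 / Angstrom^3 expressed in nM
.NM_PER_INV_A3 <- 1e36 / 6.02214076e23

#' Closure tolerances
#'
#' @param eps translational closure radius, Angstrom.
#' @param delta rotational closure radius in the sin(phi/2) metric, in (0, 1].
#' @return object of class `closure_tolerances`.
#' @export
closure_tolerances <- function(eps = 30, delta = 0.3) {
  stopifnot(is.finite(eps), is.finite(delta))
  if (eps <= 0) stop("eps must be positive")
  if (delta <= 0 || delta > 1) stop("delta must lie in (0, 1]")
  structure(list(eps = eps, delta = delta), class = "closure_tolerances")
}

#' Cube-binning grid for pair matching
#'
#' Half-molecule end positions are sorted into cells before pairing so that
#' only the 3x3x3 cell neighborhood of each end needs to be searched. Cell
#' widths are forced to at least `eps` at pairing time (a narrower cell would
#' silently miss matches); `n_z_bins` caps the number of z-slabs, mirroring
#' the archived z-bin layout of large runs.
#'
#' @param n_z_bins maximum number of z slabs (default 128).
#' @param xy_bin_width cell width in x and y, Angstrom; default `eps`.
#' @param z_range z extent used to size the slabs; default the observed range.
#' @return object of class `bin_grid`.
#' @export
bin_grid <- function(n_z_bins = 128L, xy_bin_width = NULL, z_range = NULL) {
  stopifnot(n_z_bins >= 1)
  structure(list(n_z_bins = as.integer(n_z_bins),
                 xy_bin_width = xy_bin_width, z_range = z_range),
            class = "bin_grid")
}

.half_seeds <- function(seed, n = 2L) {
  # deterministic per-task substreams from one master seed, all below 2^31
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sample an ensemble of half-molecule end states
#'
#' Draws `M` independent Boltzmann samples of the first (steps `1..m-1`) or
#' second (steps `m..N`) half of the molecule and records each sub-chain's
#' end state. Second halves store the raw end position; first halves store
#' the rotated position `-T^{-1} r`, so that closure of a (first, second)
#' pair reduces to a direct comparison of stored positions and the composed
#' rotation `T_first T_second` against the identity. Rotations are stored as
#' unit quaternions (scalar part first).
#'
#' @param spec a [molecule_spec()].
#' @param which `"first"` or `"second"`.
#' @param split_m split frame index `m` with `1 < m < N + 1`; default
#'   `ceiling((N + 1) / 2)` (balanced halves).
#' @param M sample count.
#' @param seed integer seed for the sampler's own RNG stream.
#' @return object of class `half_ensemble`: list with `pos` (M x 3, Angstrom),
#'   `quat` (M x 4), `which`, `M`, `split_m`, `N`, `seed`.
#' @export
generate_half_ensemble <- function(spec, which = c("first", "second"),
                                   split_m = NULL, M, seed) {
  which <- match.arg(which)
  stopifnot(inherits(spec, "molecule_spec"), M >= 1)
  N <- spec$N
  if (is.null(split_m)) split_m <- ceiling((N + 1) / 2)
  if (split_m <= 1 || split_m >= N + 1)
    stop("split_m must satisfy 1 < m < N + 1")
  shape <- build_intrinsic_shape(spec)
  sds <- .coord_sds(spec$stiffness)
  rng <- if (which == "first") c(1L, split_m - 1L) else c(split_m, N)
  out <- .cpp_sample_half(shape$theta, shape$trans, sds$theta, sds$trans,
                          rng[1L], rng[2L], as.integer(M), seed,
                          which == "first")
  structure(list(pos = out$pos, quat = out$quat, which = which, M = M,
                 split_m = as.integer(split_m), N = N, seed = seed),
            class = "half_ensemble")
}

#' @export
print.half_ensemble <- function(x, ...) {
  cat(sprintf("half_ensemble: %s half, M = %d, split m = %d (N = %d), seed %s\n",
              x$which, x$M, x$split_m, x$N, format(x$seed)))
  invisible(x)
}

#' Count closing first/second half pairs
#'
#' Counts the pairs whose reconstructed full molecule closes within the
#' tolerances, using cube binning: z-slab adjacency, then x/y cell adjacency,
#' then the z-difference, then the full Euclidean distance, then the SO(3)
#' distance. The binned count is exactly the brute-force all-pairs count; a
#' grid whose cells would be narrower than `eps` is an error.
#'
#' @param first,second [generate_half_ensemble()] results from the same
#'   molecule and split.
#' @param tol a [closure_tolerances()].
#' @param grid a [bin_grid()].
#' @return number of closing pairs.
#' @export
pair_and_count <- function(first, second, tol = closure_tolerances(),
                           grid = bin_grid()) {
  stopifnot(inherits(first, "half_ensemble"), inherits(second, "half_ensemble"),
            inherits(tol, "closure_tolerances"), inherits(grid, "bin_grid"))
  if (first$which != "first" || second$which != "second")
    stop("arguments must be a first and a second half ensemble, in that order")
  if (first$N != second$N || first$split_m != second$split_m)
    stop("ensembles come from different molecules or splits")
  zr <- grid$z_range
  if (is.null(zr)) {
    z <- c(first$pos[, 3L], second$pos[, 3L])
    zr <- diff(range(z))
  }
  wz <- max(tol$eps, zr / grid$n_z_bins)
  wxy <- if (is.null(grid$xy_bin_width)) tol$eps else grid$xy_bin_width
  if (wxy < tol$eps || (!is.null(grid$z_range) && zr / grid$n_z_bins > 0 && wz < tol$eps))
    stop("bin width below eps: adjacent-cell search would miss matches")
  .cpp_pair_count(first$pos, first$quat, second$pos, second$quat,
                  tol$eps, tol$delta, wxy, wz)
}

#' J-factor from a hit count
#'
#' Converts a closing-pair count into a J-factor: the hit fraction over
#' `M^2` pairs divided by the closure volume
#' `(4/3) pi eps^3 * haar_ball_volume(delta)` (Angstrom^3 times normalized
#' Haar volume), expressed in nM. The log10 standard error is Poisson,
#' `1/(ln 10 sqrt(hits))`; a zero-hit result is reported as J = 0 with an
#' upper bound evaluated at one hit.
#'
#' @param hits closing-pair count.
#' @param M half-ensemble size (the pair total is `M^2`), or a length-2
#'   vector of the two ensemble sizes.
#' @param tol a [closure_tolerances()].
#' @return object of class `j_estimate`: list with `J_nM`, `log10J`, `hits`,
#'   `pairs_total`, `stderr_log10`, `upper_bound` (flag and value).
#' @export
estimate_J <- function(hits, M, tol = closure_tolerances()) {
  stopifnot(hits >= 0, all(M >= 1), inherits(tol, "closure_tolerances"))
  pairs_total <- if (length(M) == 2L) prod(M) else M^2
  vol <- (4 / 3) * pi * tol$eps^3 * haar_ball_volume(tol$delta)
  dens <- function(h) h / (pairs_total * vol) * .NM_PER_INV_A3
  censored <- hits == 0
  J <- dens(hits)
  structure(list(
    J_nM = J,
    log10J = if (censored) NA_real_ else log10(J),
    hits = hits,
    pairs_total = pairs_total,
    stderr_log10 = if (censored) NA_real_ else 1 / (log(10) * sqrt(hits)),
    upper_bound = censored,
    J_upper_nM = if (censored) dens(1) else NA_real_
  ), class = "j_estimate")
}

#' @export
print.j_estimate <- function(x, ...) {
  if (x$upper_bound) {
    cat(sprintf("J < %.3g nM (0 hits in %.3g pairs; upper bound at 1 hit)\n",
                x$J_upper_nM, x$pairs_total))
  } else {
    cat(sprintf("J = %.4g nM (log10 J = %.3f +/- %.3f; %d hits in %.3g pairs)\n",
                x$J_nM, x$log10J, x$stderr_log10, round(x$hits), x$pairs_total))
  }
  invisible(x)
}

#' One-shot J-factor for a molecule
#'
#' Generates both half ensembles, counts closing pairs, and returns the
#' [estimate_J()] result. Two sub-seeds (one per half) are derived
#' deterministically from `seed`.
#'
#' @param spec a [molecule_spec()].
#' @param M half-ensemble size.
#' @param tol a [closure_tolerances()].
#' @param seed master seed.
#' @param split_m split index; default balanced.
#' @param grid a [bin_grid()].
#' @return a `j_estimate`.
#' @export
jfactor <- function(spec, M, tol = closure_tolerances(), seed = 1L,
                    split_m = NULL, grid = bin_grid()) {
  seeds <- .half_seeds(seed)
  fh <- generate_half_ensemble(spec, "first", split_m, M, seeds[1L])
  sh <- generate_half_ensemble(spec, "second", split_m, M, seeds[2L])
  est <- estimate_J(pair_and_count(fh, sh, tol, grid), M, tol)
  est$seed <- seed
  est
}

#' Closure-tolerance convergence check
#'
#' Recounts the same pair of ensembles with both tolerances halved and
#' compares the shift in log10 J against the combined Poisson standard
#' errors. In the small-tolerance regime the estimated density, and hence
#' log10 J, is insensitive to halving; a shift beyond `n_se` combined
#' standard errors flags tolerances that are too coarse.
#'
#' @param first,second half ensembles.
#' @param tol a [closure_tolerances()].
#' @param grid a [bin_grid()].
#' @param n_se allowed shift in combined standard errors.
#' @return list with both `j_estimate`s, the `shift` in log10 J, the
#'   combined standard error, and `converged`.
#' @export
tolerance_convergence <- function(first, second, tol = closure_tolerances(),
                                  grid = bin_grid(), n_se = 2) {
  half <- closure_tolerances(tol$eps / 2, tol$delta / 2)
  Mpair <- c(first$M, second$M)
  est <- estimate_J(pair_and_count(first, second, tol, grid), Mpair, tol)
  est_half <- estimate_J(pair_and_count(first, second, half, grid), Mpair, half)
  if (est$upper_bound || est_half$upper_bound) {
    return(list(full = est, halved = est_half, shift = NA_real_,
                se = NA_real_, converged = NA))
  }
  shift <- est_half$log10J - est$log10J
  se <- sqrt(est$stderr_log10^2 + est_half$stderr_log10^2)
  list(full = est, halved = est_half, shift = shift, se = se,
       converged = abs(shift) <= n_se * se)
}

#' Cyclization profile over a range of lengths
#'
#' Computes log10 J for a family of molecules indexed by total length N
#' (default 146 to 170, a bit over two helical-repeat periods). Each length
#' gets its own pair of sub-seeds derived from the master seed; lengths with
#' zero hits are recorded as censored (NA log10 J) and are excluded from
#' profile fits.
#'
#' @param spec_fun function of N returning a [molecule_spec()], e.g.
#'   `function(N) bent_molecule(N, bend_deg = 90)`.
#' @param N_range integer vector of lengths.
#' @param M half-ensemble size per length.
#' @param tol a [closure_tolerances()].
#' @param seed master seed; per-length sub-seeds are derived from it.
#' @param split_rule function of N giving the split index; default balanced.
#' @param grid a [bin_grid()].
#' @return data frame of class `cyclization_profile` with columns
#'   `N, log10J, stderr, hits, M, censored`.
#' @export
cyclization_profile <- function(spec_fun, N_range = 146:170, M = 2^16,
                                tol = closure_tolerances(), seed = 1L,
                                split_rule = function(N) ceiling((N + 1) / 2),
                                grid = bin_grid()) {
  stopifnot(is.function(spec_fun), length(N_range) >= 1)
  seeds <- matrix(.half_seeds(seed, 2L * length(N_range)), ncol = 2L)
  rows <- lapply(seq_along(N_range), function(k) {
    N <- N_range[k]
    spec <- spec_fun(N)
    m <- split_rule(N)
    fh <- generate_half_ensemble(spec, "first", m, M, seeds[k, 1L])
    sh <- generate_half_ensemble(spec, "second", m, M, seeds[k, 2L])
    est <- estimate_J(pair_and_count(fh, sh, tol, grid), M, tol)
    data.frame(N = N, log10J = est$log10J, stderr = est$stderr_log10,
               hits = est$hits, M = M, censored = est$upper_bound)
  })
  out <- do.call(rbind, rows)
  attr(out, "tol") <- tol
  attr(out, "seed") <- seed
  class(out) <- c("cyclization_profile", "data.frame")
  out
}
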