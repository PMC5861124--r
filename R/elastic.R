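# Diagonal-quadratic elastic energy and exact Boltzmann sampling.
#
# The energy is E = 1/2 sum_i sum_j [ K_j (theta_j - that_j)^2
#                                     + A_j (a_j - ahat_j)^2 ]  (RT units),
# so the Boltzmann distribution factorizes over coordinates and sampling is
# direct Gaussian: no Metropolis chain is needed.

.coord_sds <- function(stiff) {
  sk <- 1 / sqrt(stiff$scale_beta * stiff$K)
  sa <- if (stiff$extensible) 1 / sqrt(stiff$scale_beta * stiff$A) else c(0, 0, 0)
  list(theta = sk, trans = sa)
}

.steps_as_matrices <- function(steps, N = NULL) {
  if (is.list(steps) && !is.null(steps$theta) && is.matrix(steps$theta))
    return(list(theta = steps$theta, trans = steps$trans))
  stopifnot(is.list(steps), all(vapply(steps, inherits, TRUE, "step_coords")))
  list(theta = vapply(steps, function(s) s$theta, numeric(3)),
       trans = vapply(steps, function(s) s$trans, numeric(3)))
}

#' Elastic energy of a configuration
#'
#' Evaluates the diagonal quadratic energy (in RT) of a set of step
#' coordinates relative to the intrinsic shape of a molecule, with the global
#' stiffness scale applied to all six stiffnesses. The intrinsic shape itself
#' has zero energy.
#'
#' @param steps a list of [step_coords()] of length N, or a list with 3 x N
#'   matrices `theta` and `trans` (as returned by [build_intrinsic_shape()]
#'   or [sample_steps()]).
#' @param spec a [molecule_spec()].
#' @return energy in RT.
#' @export
energy <- function(steps, spec) {
  stopifnot(inherits(spec, "molecule_spec"))
  st <- .steps_as_matrices(steps)
  shape <- build_intrinsic_shape(spec)
  if (ncol(st$theta) != spec$N)
    stop("configuration has ", ncol(st$theta), " steps; molecule has N = ", spec$N)
  k <- spec$stiffness
  dth <- st$theta - shape$theta
  dtr <- st$trans - shape$trans
  0.5 * k$scale_beta * (sum(k$K * rowSums(dth^2)) + sum(k$A * rowSums(dtr^2)))
}

#' Sample step coordinates from the Boltzmann distribution
#'
#' Draws each internal coordinate independently from a Gaussian centred on its
#' intrinsic value with variance `RT / (scale_beta * K_j)` (rotations) or
#' `RT / (scale_beta * A_j)` (translations); with an inextensible stiffness
#' set, translations are held at their intrinsic values. Sampling is exact for
#' the diagonal quadratic energy. Uses R's RNG (seed with [set.seed()]).
#'
#' @param spec a [molecule_spec()].
#' @param first_bp index of the first step to sample (default 1).
#' @param n_steps number of consecutive steps (default to the end of the
#'   molecule).
#' @return list with 3 x `n_steps` matrices `theta` and `trans`.
#' @export
sample_steps <- function(spec, first_bp = 1L, n_steps = spec$N - first_bp + 1L) {
  stopifnot(inherits(spec, "molecule_spec"),
            first_bp >= 1, first_bp + n_steps - 1 <= spec$N)
  shape <- build_intrinsic_shape(spec)
  idx <- seq.int(first_bp, first_bp + n_steps - 1L)
  sds <- .coord_sds(spec$stiffness)
  noise_t <- matrix(stats::rnorm(3 * n_steps, sd = sds$theta), 3L, n_steps)
  noise_a <- if (all(sds$trans == 0)) matrix(0, 3L, n_steps)
             else matrix(stats::rnorm(3 * n_steps, sd = sds$trans), 3L, n_steps)
  list(theta = shape$theta[, idx, drop = FALSE] + noise_t,
       trans = shape$trans[, idx, drop = FALSE] + noise_a)
}

#' Bending stiffness from persistence length
#'
#' `K1 = Lp / ell` in RT units with `Lp` in nm and `ell = 0.34` nm: the
#' baseline 46.3 nm persistence length gives `K1 = 46.3/0.34 = 136.18` RT.
#'
#' @param Lp_nm persistence length, nm (positive).
#' @param ell_nm basepair rise, nm.
#' @return `K1` in RT units.
#' @export
stiffness_from_persistence <- function(Lp_nm, ell_nm = 0.34) {
  stopifnot(is.numeric(Lp_nm))
  if (any(!is.finite(Lp_nm)) || any(Lp_nm <= 0))
    stop("persistence length must be positive")
  Lp_nm / ell_nm
}

#' @rdname stiffness_from_persistence
#' @param K1 bending stiffness, RT units.
#' @export
persistence_from_stiffness <- function(K1, ell_nm = 0.34) {
  stopifnot(is.numeric(K1))
  if (any(!is.finite(K1)) || any(K1 <= 0)) stop("K1 must be positive")
  K1 * ell_nm
}

#' Anisotropic bending pair at fixed harmonic mean
#'
#' Splits a bending stiffness into an anisotropic pair `(K1, K2)` with a given
#' ratio `K2/K1 >= 1` while preserving the harmonic mean
#' `2/(1/K1 + 1/K2)`; J-factors are insensitive to this split over ratios
#' 1 to 8, which motivates the isotropic baseline.
#'
#' @param harmonic_mean target harmonic mean, RT units.
#' @param ratio `K2/K1`, at least 1.
#' @return named vector `c(K1 = , K2 = )`.
#' @export
anisotropic_pair <- function(harmonic_mean, ratio = 1) {
  stopifnot(is.finite(harmonic_mean), is.finite(ratio))
  if (harmonic_mean <= 0) stop("harmonic_mean must be positive")
  if (ratio < 1) stop("ratio K2/K1 must be >= 1")
  K1 <- harmonic_mean * (1 + ratio) / (2 * ratio)
  c(K1 = K1, K2 = ratio * K1)
}
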