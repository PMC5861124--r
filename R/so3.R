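# Rotation-group distance, Haar ball volume, Haar sampling.
#
# The closure criterion uses d(R1, R2) = sin(phi/2), phi the angle of the
# relative rotation R1^T R2. This is the unique rotation-invariant distance
# whose ball of radius delta has normalized Haar volume
# (2/pi)(asin(delta) - delta sqrt(1 - delta^2)): the Haar measure of
# {angle <= phi} is (phi - sin(phi))/pi, and substituting delta = sin(phi/2)
# gives the closed form.

#' Rotation distance used for chain closure
#'
#' `sin(phi/2)`, where `phi` in `[0, pi]` is the angle of the relative
#' rotation between two frames. Ranges from 0 (identical orientation) to 1
#' (rotation by pi about any axis), and is invariant under a common rotation
#' of both arguments.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return distance in `[0, 1]`.
#' @export
rotation_distance <- function(R1, R2) {
  if (!.is_rotation(R1) || !.is_rotation(R2))
    stop("inputs must be rotation matrices (orthogonal, det +1)")
  cphi <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  cphi <- min(1, max(-1, cphi))
  sqrt((1 - cphi) / 2)
}

#' Normalized Haar volume of a rotation-distance ball
#'
#' Volume, under the normalized Haar measure on SO(3), of the ball
#' `{R : d(R, I) <= delta}` in the [rotation_distance()] metric:
#' `(2/pi) (asin(delta) - delta sqrt(1 - delta^2))`. Equals 1 at
#' `delta = 1` (the whole group).
#'
#' @param delta numeric in `[0, 1]` (vectorized).
#' @return normalized volume in `[0, 1]`.
#' @export
haar_ball_volume <- function(delta) {
  stopifnot(is.numeric(delta))
  if (any(!is.finite(delta)) || any(delta < 0) || any(delta > 1))
    stop("delta must lie in [0, 1]")
  (2 / pi) * (asin(delta) - delta * sqrt(1 - delta^2))
}

#' Haar-uniform random rotations
#'
#' Samples rotations uniformly with respect to the Haar measure via uniform
#' unit quaternions (normalized 4-dimensional Gaussians). Uses R's RNG.
#'
#' @param n number of rotations.
#' @param as `"quaternion"` for an n x 4 matrix of unit quaternions
#'   (scalar part first), `"matrix"` for a 3 x 3 x n array.
#' @return quaternion matrix or rotation array.
#' @export
haar_sample <- function(n, as = c("quaternion", "matrix")) {
  as <- match.arg(as)
  q <- matrix(stats::rnorm(4 * n), n, 4L)
  q <- q / sqrt(rowSums(q^2))
  if (as == "quaternion") return(q)
  out <- array(0, c(3L, 3L, n))
  for (i in seq_len(n)) out[, , i] <- .quat_to_rot(q[i, ])
  out
}

# rotation angle in [0, pi] from unit quaternions (vectorized)
.quat_angle <- function(q) 2 * acos(pmin(1, abs(q[, 1L])))

#' Haar volume of the two-tolerance closure region
#'
#' Monte Carlo estimate of the normalized Haar volume of the closure region
#' used by the tangent-angle/torsion-angle convention: rotations whose
#' tangent director deviates from vertical by less than `acos(1 - nu_eps)`
#' and whose twist about the tangent is below `tau_eps` in magnitude. For
#' small tolerances the volume approaches `nu_eps * tau_eps / (2*pi)`, which
#' ties the single-distance closure ball to that convention.
#'
#' @param nu_eps tolerance on `1 - cos(tangent angle)`, in `[0, 2]`.
#' @param tau_eps torsion tolerance, radians, in `[0, pi]`.
#' @param n_samples Haar sample count.
#' @return list with the Monte Carlo `estimate`, its standard error `se`,
#'   and the `leading_order` value `nu_eps * tau_eps / (2*pi)`.
#' @export
czapla_region_volume <- function(nu_eps, tau_eps, n_samples = 1e6) {
  stopifnot(is.finite(nu_eps), is.finite(tau_eps), nu_eps >= 0, tau_eps >= 0)
  if (nu_eps == 0 || tau_eps == 0)
    return(list(estimate = 0, se = 0, leading_order = 0))
  q <- haar_sample(n_samples)
  # 1 - R33 = 2 (x^2 + y^2); swing-twist decomposition: twist = 2 atan2(z, w)
  bend_ok <- 2 * (q[, 2L]^2 + q[, 3L]^2) < nu_eps
  tw <- 2 * atan2(q[, 4L], q[, 1L])
  tw <- tw - 2 * pi * round(tw / (2 * pi))
  inside <- bend_ok & abs(tw) < tau_eps
  p <- mean(inside)
  list(estimate = p,
       se = sqrt(p * (1 - p) / n_samples),
       leading_order = nu_eps * tau_eps / (2 * pi))
}
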