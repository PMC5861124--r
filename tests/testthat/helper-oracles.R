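# Independent oracles used across the test files. These deliberately avoid
# the package's own quaternion/Cayley code paths.

# Rodrigues rotation about a unit axis by a given angle
rodrigues <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# closed-form origins of the intrinsic helix, in axis-aligned coordinates
# (helix axis parallel to y through (-(l/2) cos(a)/sin(psi), 0, 0)); the
# composed chain reproduces these after the fixed rotation Rx(alpha) that
# maps the helix-adapted start tangent (0, sin a, cos a) onto e3
helix_origin_closed_form <- function(alpha, psi, ell, i) {
  rho <- (ell / 2) * cos(alpha) / sin(psi)
  cbind(-rho * (1 - cos(2 * (i - 1) * psi)),
        (i - 1) * ell * sin(alpha),
        rho * sin(2 * (i - 1) * psi))
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)

# all-pairs closing-pair count, fully vectorized (the O(M^2) oracle for the
# cube-binned counter); quaternion scalar part of q1 * q2 tests the SO(3) ball
brute_force_pairs <- function(first, second, tol) {
  p1 <- first$pos; p2 <- second$pos
  d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
  wtot <- first$quat %*% t(second$quat * rep(c(1, -1, -1, -1), each = nrow(second$quat)))
  sum(d2 <= tol$eps^2 & wtot^2 >= 1 - tol$delta^2) + 0
}

# energy as an explicit scalar loop (oracle for the vectorized version)
energy_scalar_loop <- function(steps, spec) {
  shape <- build_intrinsic_shape(spec)
  k <- spec$stiffness
  E <- 0
  for (i in seq_len(spec$N)) {
    for (j in 1:3) {
      E <- E + k$scale_beta * k$K[j] * (steps$theta[j, i] - shape$theta[j, i])^2 / 2
      E <- E + k$scale_beta * k$A[j] * (steps$trans[j, i] - shape$trans[j, i])^2 / 2
    }
  }
  E
}
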