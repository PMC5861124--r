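# Rigid-basepair frames and Cayley/midframe step composition.
#
# Conventions (pinned by the helix-origin oracle in the test suite):
#   * a step rotation is parameterized by a Cayley vector theta with
#     |theta| = 2 tan(phi/2), axis theta/|theta|;
#   * directors compose on the right, R_{i+1} = R_i Q(theta);
#   * the step translation is expressed in the midframe, i.e. frame i rotated
#     by half the step rotation about the same axis.

.quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), 3L, 3L, byrow = TRUE)
}

.is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Rotation matrix from a Cayley vector
#'
#' Maps a Cayley (rotation) vector to the rotation about axis `theta/|theta|`
#' by the angle `phi` satisfying `|theta| = 2 tan(phi/2)`. This is the scaling
#' used for the roll/tilt/twist step angles of the rigid-basepair model: in the
#' straight-segment limit the intrinsic twist step is `(0, 0, 2 tan(beta/2))`
#' for a per-basepair twist angle `beta`.
#'
#' @param theta numeric length-3 Cayley vector (dimensionless).
#' @return 3x3 rotation matrix.
#' @export
cayley_rotation <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 3L)
  if (!all(is.finite(theta))) stop("non-finite Cayley vector")
  .quat_to_rot(c(1, theta / 2))
}

# rotation by half the Cayley angle about the same axis (the midframe rotation);
# quaternion midpoint between the identity and the step quaternion
.cayley_half_rotation <- function(theta) {
  nt <- sqrt(sum(theta^2))
  if (nt < .Machine$double.xmin) return(diag(3))
  phi <- 2 * atan(nt / 2)
  .quat_to_rot(c(cos(phi / 4), sin(phi / 4) * theta / nt))
}

#' Basepair frame
#'
#' A rigid frame attached to one basepair: an origin (in Angstrom) and an
#' orthonormal director triad stored as the columns of a rotation matrix.
#' Frame 1 of a molecule is always the identity frame at the origin.
#'
#' @param origin numeric length-3, Angstrom.
#' @param directors 3x3 orthogonal matrix with determinant +1 (columns d1, d2, d3).
#' @return object of class `basepair_frame`.
#' @export
basepair_frame <- function(origin = c(0, 0, 0), directors = diag(3)) {
  stopifnot(is.numeric(origin), length(origin) == 3L, all(is.finite(origin)))
  if (!.is_rotation(directors, tol = 1e-10))
    stop("directors must be orthonormal with determinant +1")
  structure(list(origin = as.numeric(origin), directors = directors),
            class = "basepair_frame")
}

#' Step coordinates
#'
#' The six internal coordinates between consecutive basepair frames: a Cayley
#' rotation vector (roll, tilt, twist) and a midframe translation
#' (shift, slide, rise) in Angstrom.
#'
#' @param theta numeric length-3 Cayley components; the implied rotation angle
#'   must be below pi (always true for finite input).
#' @param trans numeric length-3 translation, Angstrom.
#' @return object of class `step_coords`.
#' @export
step_coords <- function(theta, trans) {
  stopifnot(is.numeric(theta), length(theta) == 3L,
            is.numeric(trans), length(trans) == 3L)
  if (!all(is.finite(theta)) || !all(is.finite(trans)))
    stop("step coordinates must be finite")
  structure(list(theta = as.numeric(theta), trans = as.numeric(trans)),
            class = "step_coords")
}

#' Advance a frame by one step
#'
#' Composes a basepair frame with one set of step coordinates: the directors
#' are rotated by the Cayley rotation of `theta`, and the origin is displaced
#' by the translation expressed in the midframe (the current directors rotated
#' by half the step rotation).
#'
#' @param frame a [basepair_frame()].
#' @param step a [step_coords()].
#' @return the next `basepair_frame`.
#' @export
compose_step <- function(frame, step) {
  stopifnot(inherits(frame, "basepair_frame"), inherits(step, "step_coords"))
  Rmid <- frame$directors %*% .cayley_half_rotation(step$theta)
  basepair_frame(
    origin    = frame$origin + as.numeric(Rmid %*% step$trans),
    directors = frame$directors %*% cayley_rotation(step$theta)
  )
}

#' Helix parameters
#'
#' The four parameters of an intrinsically helical segment: `alpha` (helicity;
#' its sign sets handedness, 0 gives a planar circular arc), `psi` (half the
#' bend angle per basepair for small angles), `beta_twist` (intrinsic twist per
#' basepair, 2*pi/helical repeat) and `ell` (basepair spacing, Angstrom).
#' Setting `alpha = psi = 0` gives a straight twisted segment.
#'
#' @param alpha radians, `|alpha| < pi/2`.
#' @param psi radians, `|psi| < pi/2`.
#' @param beta_twist radians per basepair.
#' @param ell Angstrom, positive; default 3.4.
#' @return object of class `helix_params`.
#' @export
helix_params <- function(alpha, psi, beta_twist, ell = 3.4) {
  stopifnot(is.numeric(alpha), is.numeric(psi), is.numeric(beta_twist),
            is.numeric(ell), length(alpha) == 1L, length(psi) == 1L,
            length(beta_twist) == 1L, length(ell) == 1L)
  if (!all(is.finite(c(alpha, psi, beta_twist, ell))))
    stop("helix parameters must be finite")
  if (ell <= 0) stop("basepair spacing ell must be positive")
  if (abs(psi) >= pi / 2) stop("|psi| must be below pi/2")
  if (abs(alpha) >= pi / 2) stop("|alpha| must be below pi/2")
  structure(list(alpha = alpha, psi = psi, beta_twist = beta_twist, ell = ell),
            class = "helix_params")
}

#' Intrinsic step coordinates of a helical segment
#'
#' Closed-form minimum-energy step coordinates of a uniform helical (or, for
#' `alpha = 0`, circular-arc; for `alpha = psi = 0`, straight) segment. Only
#' the in-plane components depend on the step index `i`, through the twist
#' phase `(2i - 1) beta/2`; the twist components are constant along the
#' segment.
#'
#' @param helix a [helix_params()].
#' @param i step index within the segment, `i >= 1`.
#' @return a [step_coords()].
#' @export
intrinsic_step <- function(helix, i) {
  stopifnot(inherits(helix, "helix_params"), i >= 1)
  st <- .intrinsic_step_matrices(helix, i)
  step_coords(st$theta[, 1L], st$trans[, 1L])
}

# vectorized over step indices; returns 3 x length(i) matrices
.intrinsic_step_matrices <- function(helix, i) {
  al <- helix$alpha; ps <- helix$psi; be <- helix$beta_twist; ell <- helix$ell
  D <- 1 + cos(ps) * cos(be / 2) + sin(ps) * sin(be / 2) * sin(al)
  if (abs(D - 1) < 1e-14 && (abs(ps) > 0 || abs(be) > 0))
    stop("degenerate helix parameters: D - 1 = 0")
  ph <- (2 * i - 1) * be / 2
  brk <- 1 + tan(ps / 2) * tan(be / 4) * sin(al)
  a1 <- -(ell / D) * cos(al) * sin(ps) * sin(be / 2) * sin(ph) * brk
  a2 <- -(ell / D) * cos(al) * sin(ps) * sin(be / 2) * cos(ph) * brk
  a3 <- (ell / D) * cos(al)^2 * (cos(ps) + cos(be / 2)) +
    (ell / D) * sin(al) * (sin(ps) * sin(be / 2) + sin(al) +
                             sin(al) * cos(ps) * cos(be / 2))
  if (abs(D - 1) < 1e-14) {
    # straight untwisted limit: psi = beta = 0
    t1 <- t2 <- t3 <- rep(0, length(i))
  } else {
    t1 <- -(2 / (D - 1)) * sin(ps) * sin(ph) * cos(al)
    t2 <- -(2 / (D - 1)) * sin(ps) * cos(ph) * cos(al)
    t3 <- rep((2 / (D - 1)) * (cos(ps) * sin(be / 2) -
                                 sin(ps) * cos(be / 2) * sin(al)), length(i))
  }
  list(theta = rbind(t1, t2, t3, deparse.level = 0),
       trans = rbind(a1, a2, a3 + 0 * ph, deparse.level = 0))
}

#' Solve helix parameters from bend and non-planarity
#'
#' Inverts the two geometric relations of the intrinsic helix —
#' `cos(bend per bp) = cos^2(alpha) cos(2 psi) + sin^2(alpha)` and
#' `Pitch/Circumference = tan(alpha) sin(psi)/psi` — for `(alpha, psi)`,
#' given the bend angle per basepair and the signed pitch-to-circumference
#' ratio. The sign of `alpha` follows the sign of the ratio. The intrinsic
#' twist is set from the helical repeat, `beta_twist = 2*pi/repeat`.
#'
#' @param bend_per_bp radians per basepair, in (0, pi).
#' @param pitch_over_circumf dimensionless signed ratio (0 = planar arc).
#' @param helical_repeat basepairs per full turn of intrinsic twist.
#' @param ell basepair spacing, Angstrom.
#' @return a [helix_params()] satisfying both relations to < 1e-12.
#' @export
solve_helix_params <- function(bend_per_bp, pitch_over_circumf, helical_repeat,
                               ell = 3.4) {
  stopifnot(is.finite(bend_per_bp), is.finite(pitch_over_circumf),
            is.finite(helical_repeat), helical_repeat > 0)
  if (bend_per_bp <= 0 || bend_per_bp >= pi)
    stop("bend_per_bp must lie in (0, pi)")
  beta <- 2 * pi / helical_repeat
  s <- sin(bend_per_bp / 2)     # = cos(alpha) sin(psi)
  rho <- abs(pitch_over_circumf)
  if (rho == 0)
    return(helix_params(0, bend_per_bp / 2, beta, ell))
  # reduce to one equation in alpha: rho(alpha) = tan(alpha) * s / (cos(alpha) asin(s/cos(alpha)))
  g <- function(al) {
    sp <- s / cos(al)
    tan(al) * sp / asin(sp) - rho
  }
  a_max <- acos(s) * (1 - 1e-12)
  if (g(a_max) < 0)
    stop("no helix in the chart: |pitch_over_circumf| too large for this bend")
  root <- stats::uniroot(g, c(1e-14, a_max), tol = 1e-15)
  alpha <- sign(pitch_over_circumf) * root$root
  psi <- asin(s / cos(alpha))
  helix_params(alpha, psi, beta, ell)
}

#' Intrinsic shape of a molecule
#'
#' Concatenates the closed-form intrinsic steps of each segment of a molecule
#' specification into the full list of N minimum-energy step coordinates
#' (step N connects frame N to the fictitious closure frame N + 1). Within a
#' segment, the twist phase uses the local step index, so a bend placed
#' mid-molecule enters with the twist register accumulated by the preceding
#' steps. A trailing straight segment is filled in implicitly when the listed
#' segments cover fewer than N steps.
#'
#' @param spec a [molecule_spec()].
#' @return object of class `intrinsic_shape`: list with 3 x N matrices
#'   `theta` and `trans`, plus `N` and `ell`.
#' @export
build_intrinsic_shape <- function(spec) {
  stopifnot(inherits(spec, "molecule_spec"))
  beta <- 2 * pi / spec$helical_repeat
  ell <- spec$ell
  th <- matrix(0, 3L, 0L); tr <- matrix(0, 3L, 0L)
  used <- 0L
  for (seg in spec$segments) {
    if (used + seg$n_bp > spec$N)
      stop("segment basepair counts exceed N")
    hp <- switch(seg$kind,
      straight = helix_params(0, 0, beta, ell),
      arc      = ,
      helix    = solve_helix_params(seg$bend_total * pi / 180 / seg$n_bp,
                                    seg$pitch_over_circumf,
                                    spec$helical_repeat, ell),
      stop("unknown segment kind: ", seg$kind)
    )
    st <- .intrinsic_step_matrices(hp, seq_len(seg$n_bp))
    th <- cbind(th, st$theta); tr <- cbind(tr, st$trans)
    used <- used + seg$n_bp
  }
  if (used < spec$N) {
    st <- .intrinsic_step_matrices(helix_params(0, 0, beta, ell),
                                   seq_len(spec$N - used))
    th <- cbind(th, st$theta); tr <- cbind(tr, st$trans)
  }
  structure(list(theta = th, trans = tr, N = spec$N, ell = ell),
            class = "intrinsic_shape")
}

#' Frames along a chain
#'
#' Composes a sequence of step coordinates from a starting frame (default the
#' identity frame) and returns all N + 1 frames: origins as an (N+1) x 3
#' matrix and director triads as a 3 x 3 x (N+1) array.
#'
#' @param steps an `intrinsic_shape`, or a list with 3 x N matrices `theta`
#'   and `trans`.
#' @param start a [basepair_frame()] for frame 1.
#' @return list with `origins` and `directors`.
#' @export
chain_frames <- function(steps, start = basepair_frame()) {
  th <- steps$theta; tr <- steps$trans
  n <- ncol(th)
  origins <- matrix(0, n + 1L, 3L)
  directors <- array(0, c(3L, 3L, n + 1L))
  r <- start$origin; R <- start$directors
  origins[1L, ] <- r; directors[, , 1L] <- R
  for (i in seq_len(n)) {
    theta <- th[, i]
    Rmid <- R %*% .cayley_half_rotation(theta)
    r <- r + as.numeric(Rmid %*% tr[, i])
    R <- R %*% cayley_rotation(theta)
    origins[i + 1L, ] <- r
    directors[, , i + 1L] <- R
  }
  list(origins = origins, directors = directors)
}

#' Export the intrinsic shape of a molecule as CSV
#'
#' Writes one row per frame: index, origin (Angstrom) and tangent director d3.
#'
#' @param spec a [molecule_spec()].
#' @param file path of the CSV to write.
#' @return the data frame, invisibly.
#' @export
export_shape <- function(spec, file) {
  fr <- chain_frames(build_intrinsic_shape(spec))
  d3 <- t(fr$directors[, 3L, ])
  df <- data.frame(i = seq_len(nrow(fr$origins)),
                   x = fr$origins[, 1L], y = fr$origins[, 2L], z = fr$origins[, 3L],
                   d3x = d3[, 1L], d3y = d3[, 2L], d3z = d3[, 3L])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
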