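test_that("cayley_rotation has the 2 tan(phi/2) normalization", {
  expect_equal(cayley_rotation(c(0, 0, 0)), diag(3))

  # twist limit: theta = (0, 0, 2 tan(beta/2)) is a rotation by beta about d3
  beta <- 2 * pi / 10.5
  expect_equal(cayley_rotation(c(0, 0, 2 * tan(beta / 2))),
               rodrigues(c(0, 0, 1), beta), tolerance = 1e-12)

  # random vectors: angle 2 atan(|theta|/2) about theta/|theta| (Rodrigues oracle)
  set.seed(101)
  for (i in 1:20) {
    th <- rnorm(3, sd = 1.5)
    R <- cayley_rotation(th)
    expect_equal(R, rodrigues(th, 2 * atan(sqrt(sum(th^2)) / 2)),
                 tolerance = 1e-12)
  }
  expect_error(cayley_rotation(c(0, 0, Inf)), "finite")
})

test_that("compose_step displaces along the midframe", {
  f0 <- basepair_frame()
  f1 <- compose_step(f0, step_coords(c(0, 0, 0), c(0, 0, 3.4)))
  expect_equal(f1$origin, c(0, 0, 3.4))
  expect_equal(f1$directors, diag(3))

  # pure twist step: origin advances along d3 regardless of the twist
  f2 <- compose_step(f0, step_coords(c(0, 0, 2 * tan(pi / 10.5)), c(0, 0, 3.4)))
  expect_equal(f2$origin, c(0, 0, 3.4), tolerance = 1e-12)

  # pure bend: chord of the arc, tilted by half the bend (midframe geometry)
  psi <- 0.1
  f3 <- compose_step(f0, step_coords(c(0, -2 * tan(psi), 0), c(0, 0, 3.4)))
  expect_equal(f3$origin, 3.4 * c(-sin(psi), 0, cos(psi)), tolerance = 1e-12)
})

test_that("composed intrinsic steps reproduce the closed-form helix origins", {
  # pins the Cayley/midframe convention: 100 random (alpha, psi, beta) in the
  # chart, composed origins match the closed form (in axis-aligned coordinates,
  # i.e. after the fixed Rx(alpha) relating the identity start frame to the
  # helix-adapted one) to 1e-8 Angstrom
  set.seed(7)
  for (trial in 1:100) {
    alpha <- runif(1, -0.7, 0.7)
    psi <- runif(1, 0.005, 0.6)
    beta <- runif(1, 0.05, 1.2)
    ell <- 3.4
    hp <- helix_params(alpha, psi, beta, ell)
    n <- 40L
    steps <- lapply(seq_len(n), function(i) intrinsic_step(hp, i))
    fr <- chain_frames(list(
      theta = vapply(steps, function(s) s$theta, numeric(3)),
      trans = vapply(steps, function(s) s$trans, numeric(3))
    ))
    want <- helix_origin_closed_form(alpha, psi, ell, seq_len(n + 1L)) %*% t(rot_x(alpha))
    expect_lt(max(abs(fr$origins - want)), 1e-8)
  }
})

test_that("helix tangents satisfy the bend-per-bp identity", {
  # d3^{i+1} . d3^i = cos^2(alpha) cos(2 psi) + sin^2(alpha) at every step
  set.seed(8)
  for (trial in 1:10) {
    alpha <- runif(1, -0.6, 0.6); psi <- runif(1, 0.01, 0.5)
    hp <- helix_params(alpha, psi, 2 * pi / 10.5)
    steps <- lapply(1:25, function(i) intrinsic_step(hp, i))
    fr <- chain_frames(list(
      theta = vapply(steps, function(s) s$theta, numeric(3)),
      trans = vapply(steps, function(s) s$trans, numeric(3))
    ))
    d3 <- fr$directors[, 3L, ]
    dots <- colSums(d3[, -26L] * d3[, -1L])
    expect_equal(dots, rep(cos(alpha)^2 * cos(2 * psi) + sin(alpha)^2, 25L),
                 tolerance = 1e-10)
  }
})

test_that("intrinsic_step limits match the closed forms", {
  beta <- 2 * pi / 10.5
  # straight: theta = (0, 0, 2 tan(beta/2)), a = (0, 0, ell)
  st <- intrinsic_step(helix_params(0, 0, beta), 5L)
  expect_equal(st$theta, c(0, 0, 2 * tan(beta / 2)), tolerance = 1e-14)
  expect_equal(st$trans, c(0, 0, 3.4), tolerance = 1e-14)

  # planar arc: twist and rise components from the alpha = 0 formulas
  psi <- 0.02
  st <- intrinsic_step(helix_params(0, psi, beta), 3L)
  D <- 1 + cos(psi) * cos(beta / 2)
  expect_equal(st$trans[3], (3.4 / D) * (cos(psi) + cos(beta / 2)), tolerance = 1e-14)
  expect_equal(st$theta[3], 2 * cos(psi) * sin(beta / 2) / (D - 1), tolerance = 1e-14)
})

test_that("solve_helix_params inverts the bend/non-planarity relations", {
  # planar: bend angle per bp is exactly 2 psi
  hp <- solve_helix_params((pi / 2) / 63, 0, 10.5)
  expect_equal(hp$alpha, 0)
  expect_equal(hp$psi, (pi / 2) / (2 * 63))
  expect_equal(hp$beta_twist, 2 * pi / 10.5)

  # round trip: forward relations as the oracle
  set.seed(9)
  for (trial in 1:25) {
    bend <- runif(1, 0.005, 0.4)
    ratio <- runif(1, -1.2, 1.2)
    hp <- solve_helix_params(bend, ratio, 10.5)
    expect_equal(cos(hp$alpha)^2 * cos(2 * hp$psi) + sin(hp$alpha)^2,
                 cos(bend), tolerance = 1e-12)
    expect_lt(abs(tan(hp$alpha) * sin(hp$psi) / hp$psi - ratio), 1e-9)
    expect_equal(sign(hp$alpha), sign(ratio))
  }

  # small-angle reading (both psi and alpha small): ratio ~ tan(alpha),
  # bend per bp ~ 2 psi
  hp <- solve_helix_params(0.01, 0.05, 10.5)
  expect_equal(tan(hp$alpha), 0.05, tolerance = 0.01)
  expect_equal(2 * hp$psi, 0.01, tolerance = 5e-3)

  # out-of-chart ratio
  expect_error(solve_helix_params(1.5, 5, 10.5), "no helix")
})

test_that("build_intrinsic_shape concatenates segments", {
  beta <- 2 * pi / 10.5
  # all-straight molecule: every step identical
  sh <- build_intrinsic_shape(molecule_spec(list(segment_spec("straight", 20L)), N = 20L))
  expect_equal(dim(sh$theta), c(3L, 20L))
  expect_equal(sh$theta, matrix(c(0, 0, 2 * tan(pi / 10.5)), 3, 20), tolerance = 1e-14)
  expect_equal(sh$trans, matrix(c(0, 0, 3.4), 3, 20), tolerance = 1e-14)

  # canonical 90-degrees-over-63-bp bend, then implicit straight filler
  spec <- bent_molecule(147)
  sh <- build_intrinsic_shape(spec)
  expect_equal(ncol(sh$theta), 147L)
  psi <- (pi / 2) / (2 * 63)
  bend_dots <- cos(2 * psi)
  fr <- chain_frames(sh)
  d3 <- fr$directors[, 3L, ]
  dots <- colSums(d3[, 1:63] * d3[, 2:64])
  expect_equal(dots, rep(bend_dots, 63), tolerance = 1e-12)
  # total bend over the arc is 90 degrees
  expect_equal(acos(sum(d3[, 1] * d3[, 64])), pi / 2, tolerance = 1e-10)
  # straight tail
  expect_equal(sh$theta[, 64:147], matrix(c(0, 0, 2 * tan(pi / 10.5)), 3, 84),
               tolerance = 1e-14)

  # two-bend molecule with a gap (60 deg over 42 bp, 21 bp gap, 30 deg over 21 bp)
  spec2 <- molecule_spec(list(
    segment_spec("arc", 42L, bend_total = 60),
    segment_spec("straight", 21L),
    segment_spec("arc", 21L, bend_total = 30)
  ), N = 147L)
  sh2 <- build_intrinsic_shape(spec2)
  fr2 <- chain_frames(sh2)
  d3 <- fr2$directors[, 3L, ]
  expect_equal(acos(sum(d3[, 1] * d3[, 43])), 60 * pi / 180, tolerance = 1e-10)
  expect_lt(acos(pmin(1, sum(d3[, 43] * d3[, 64]))), 1e-6)
  expect_equal(acos(sum(d3[, 64] * d3[, 85])), 30 * pi / 180, tolerance = 1e-10)

  expect_error(molecule_spec(list(segment_spec("straight", 200L)), N = 147L),
               "exceed")
})

test_that("rigid rotation of frame 1 rotates the whole chain", {
  spec <- bent_molecule(100, bend_deg = 75, pitch_over_circumf = 0.4)
  sh <- build_intrinsic_shape(spec)
  fr <- chain_frames(sh)
  Q <- rodrigues(c(1, 2, -1), 0.83)
  frQ <- chain_frames(sh, start = basepair_frame(c(0, 0, 0), Q))
  expect_equal(frQ$origins, fr$origins %*% t(Q), tolerance = 1e-10)
  for (i in c(1L, 50L, 101L))
    expect_equal(frQ$directors[, , i], Q %*% fr$directors[, , i], tolerance = 1e-10)
})
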