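test_that("half-ensemble end states reduce to the intrinsic sub-chain at zero temperature", {
  # stiffness -> infinity: every sample equals the minimum-energy sub-chain
  spec <- bent_molecule(60, bend_deg = 80, bend_bp = 40,
                        stiffness = stiffness_set(scale_beta = 1e14))
  m <- 31L
  sh <- generate_half_ensemble(spec, "second", split_m = m, M = 5L, seed = 1)
  shape <- build_intrinsic_shape(spec)
  fr <- chain_frames(list(theta = shape$theta[, m:60], trans = shape$trans[, m:60]))
  want <- fr$origins[nrow(fr$origins), ]
  for (i in 1:5) expect_equal(sh$pos[i, ], want, tolerance = 1e-5)
  Rend <- fr$directors[, , dim(fr$directors)[3]]
  q <- sh$quat[1, ]
  Rq <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)))
  expect_equal(Rq, Rend, tolerance = 1e-5)

  # first half stores -T^{-1} r of the intrinsic sub-chain end state
  fh <- generate_half_ensemble(spec, "first", split_m = m, M = 3L, seed = 2)
  fr1 <- chain_frames(list(theta = shape$theta[, 1:(m - 1)], trans = shape$trans[, 1:(m - 1)]))
  T1 <- fr1$directors[, , m]
  r1 <- fr1$origins[m, ]
  expect_equal(fh$pos[1, ], as.numeric(-t(T1) %*% r1), tolerance = 1e-5)
})

test_that("stored half end states reconstruct full-molecule closure geometry", {
  spec <- bent_molecule(101, bend_deg = 90)
  m <- 51L
  fh <- generate_half_ensemble(spec, "first", split_m = m, M = 100L, seed = 11)
  sh <- generate_half_ensemble(spec, "second", split_m = m, M = 100L, seed = 12)
  quat2rot <- function(q) rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)))
  for (k in 1:100) {
    T1 <- quat2rot(fh$quat[k, ])
    r1 <- as.numeric(-T1 %*% fh$pos[k, ])      # invert the stored transform
    r2 <- sh$pos[k, ]
    # reconstructed end-to-end vector of the composed molecule
    r_tot <- r1 + as.numeric(T1 %*% r2)
    # the pairing distance equals |r_tot|: rotations preserve the norm
    expect_equal(sqrt(sum((r2 - fh$pos[k, ])^2)), sqrt(sum(r_tot^2)),
                 tolerance = 1e-9)
  }
})

test_that("cube-binned pair counting equals the all-pairs brute force", {
  spec <- bent_molecule(147)
  fh <- generate_half_ensemble(spec, "first", M = 2000L, seed = 5)
  sh <- generate_half_ensemble(spec, "second", M = 2000L, seed = 6)
  for (tt in list(c(120, 0.9), c(150, 0.8), c(200, 1.0), c(100, 0.5),
                  c(80, 0.25))) {
    tol <- closure_tolerances(tt[1], tt[2])
    expect_identical(pair_and_count(fh, sh, tol),
                     brute_force_pairs(fh, sh, tol))
  }
  # delta = 1 covers the whole rotation group: criterion is translational only
  tol1 <- closure_tolerances(150, 1)
  d2 <- outer(rowSums(fh$pos^2), rowSums(sh$pos^2), "+") - 2 * fh$pos %*% t(sh$pos)
  expect_identical(pair_and_count(fh, sh, tol1), sum(d2 <= 150^2) + 0)
  # a grid forced below eps is rejected rather than silently undercounting
  expect_error(pair_and_count(fh, sh, closure_tolerances(100, 0.5),
                              bin_grid(xy_bin_width = 50)), "bin width")
  # identical seeds reproduce identical hit counts
  fh2 <- generate_half_ensemble(spec, "first", M = 2000L, seed = 5)
  expect_identical(fh2$pos, fh$pos)
})

test_that("estimate_J recovers a planted uniform density", {
  # synthetic ensembles: first-half positions uniform in an L-box, second-half
  # positions uniform in a larger (L + 4 eps) box so that every eps-ball lies
  # inside the second support; orientations Haar on both sides. The planted
  # closure density is then exactly 1/(L + 4 eps)^3 x (normalized Haar), and
  # the estimator must recover it within Monte Carlo error.
  set.seed(55)
  M <- 12000L; L <- 200; eps <- 8; delta <- 0.5
  L2 <- L + 4 * eps
  fake <- function(Lbox, M) {
    structure(list(pos = matrix(runif(3 * M, -Lbox / 2, Lbox / 2), M, 3L),
                   quat = haar_sample(M), which = "first", M = M,
                   split_m = 2L, N = 3L, seed = 0), class = "half_ensemble")
  }
  fh <- fake(L, M); sh <- fake(L2, M); sh$which <- "second"
  tol <- closure_tolerances(eps, delta)
  hits <- pair_and_count(fh, sh, tol, bin_grid(n_z_bins = 16L))
  est <- estimate_J(hits, M, tol)
  J_planted <- 1 / L2^3 * 1e36 / 6.02214076e23
  # 3 sigma in log10 (hits are nearly independent here, Poisson applies)
  expect_lt(abs(est$log10J - log10(J_planted)), 3 * est$stderr_log10)

  # zero-eps limit and zero-hit censoring
  expect_identical(pair_and_count(fh, sh, closure_tolerances(1e-12, 0.5)), 0)
  z <- estimate_J(0, M, tol)
  expect_true(z$upper_bound)
  expect_equal(z$J_nM, 0)
  expect_gt(z$J_upper_nM, 0)
})

test_that("J is invariant to the split point within stochastic error", {
  # the estimator is unbiased for any split, but an unbalanced split leaves
  # one half short and stiff, which sharply reduces effective pair diversity:
  # single runs at the one-third split scatter by ~0.3-0.5 in log10 J at this
  # M (super-Poisson, shared-half correlations). Pool hits over three seeds
  # per split and compare at a band set by that measured scatter.
  spec <- bent_molecule(147)
  tol <- closure_tolerances(45, 0.45)
  vol <- (4 / 3) * pi * tol$eps^3 * haar_ball_volume(tol$delta)
  pooled <- function(m, seeds) {
    hs <- vapply(seeds, function(s)
      jfactor(spec, M = 2^16, tol = tol, seed = s, split_m = m)$hits, 0)
    log10(sum(hs) / (length(seeds) * (2^16)^2 * vol) * 1e36 / 6.02214076e23)
  }
  l_half <- pooled(74L, 21:23)
  l_third <- pooled(ceiling(148 / 3), 24:26)
  expect_lt(abs(l_half - l_third), 0.4)
})

test_that("tolerance halving flags coarse tolerances and passes converged ones", {
  spec <- bent_molecule(147)
  seeds <- dnacyclize:::.half_seeds(31)
  fh <- generate_half_ensemble(spec, "first", M = 2^17, seed = seeds[1])
  sh <- generate_half_ensemble(spec, "second", M = 2^17, seed = seeds[2])
  # (60, 0.6) is far outside the small-ball regime: halving shifts log10 J
  # by many combined standard errors
  cv_coarse <- tolerance_convergence(fh, sh, closure_tolerances(60, 0.6))
  expect_false(cv_coarse$converged)
  expect_lt(cv_coarse$shift, 0)   # coarse tolerances overestimate J at a peak
})
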