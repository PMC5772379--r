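test_that("the beta grid is log-spaced with exact endpoints", {
  g <- beta_grid()
  expect_length(g, 100)
  expect_identical(g[1], 0.0037)
  expect_identical(g[100], 1.33)
  expect_equal(g[2], 0.0039266, tolerance = 1e-4)
  ratios <- g[-1] / g[-100]
  expect_lt(diff(range(ratios)), 1e-10)
})

test_that("fit weights are inverse-variance with a positivity floor", {
  fs <- frame_schedule(c(0, 15, 30, 60), c(15, 15, 30, 30))
  # gamma = 0, constant TAC: weights proportional to frame duration
  w <- weights_from_variance(tissue_tac(fs, rep(50, 4)), gamma = 0)
  expect_equal(w / w[1], fs$dur / fs$dur[1], tolerance = 1e-12)
  # equal values, different durations: longer frame weighs more
  expect_gt(w[3], w[2])
  # a frame below the floor still gets a finite weight
  w2 <- weights_from_variance(tissue_tac(fs, c(-5, 0.0001, 100, 100)),
                              gamma = 0)
  expect_true(all(is.finite(w2) & w2 > 0))
  expect_equal(w2[1], w2[2])  # equal-duration frames, both at the floor
})

test_that("the weighted NNLS engine matches the exhaustive subset oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    p <- sample(2:5, 1)
    X <- matrix(stats::rnorm(n * p)^2, n, p)  # collinear-ish, non-negative
    y <- X %*% runif(p, -0.5, 1.5) + stats::rnorm(n, 0, 0.2)
    got <- leupet:::wnnls(X, as.numeric(y), rep(1, n))
    want <- nnls_oracle(X, as.numeric(y))
    expect_equal(got, want, tolerance = 1e-8)
  }
  # weighted case: row scaling by sqrt(w) is equivalent to the oracle on
  # pre-scaled rows
  set.seed(202)
  X <- matrix(stats::rexp(8 * 3), 8, 3)
  y <- as.numeric(X %*% c(1, -0.2, 0.5) + stats::rnorm(8, 0, 0.1))
  w <- runif(8, 0.2, 3)
  expect_equal(leupet:::wnnls(X, y, w),
               nnls_oracle(X * sqrt(w), y * sqrt(w)), tolerance = 1e-8)
})

test_that("BFM recovers on-grid homogeneous kinetics exactly", {
  inp <- fx_input(); fs <- fx_schedule(); dict <- fx_dict()
  h <- fx_ongrid_params()
  tac <- homogeneous_tac(h, inp, fs)
  f <- bfm_fit(tac, dict)
  expect_equal(f$beta_hat, h$beta, tolerance = 1e-12)
  expect_equal(f$K1, h$K1, tolerance = 1e-6)
  expect_equal(f$lambda, lambda_from_rates(h$k2k3, h$k4), tolerance = 1e-6)
  expect_equal(f$rcps, rcps_from_rates(h$K1, h$k2k3, h$k4, 120),
               tolerance = 1e-6)
  expect_equal(f$Vb, 0.05, tolerance = 1e-6)
  expect_false(f$outlier)
})

test_that("BFM handles pure-blood and trap-heavy voxels non-negatively", {
  inp <- fx_input(); fs <- fx_schedule(); dict <- fx_dict()
  blood_only <- homogeneous_tac(homogeneous_params(0, 0.1, 0.04, Vb = 0.05),
                                inp, fs)
  f <- bfm_fit(blood_only, dict)
  expect_lt(f$K1, 1e-6)
  expect_lt(f$rcps, 1e-4)
  expect_equal(f$Vb, 0.05, tolerance = 1e-4)
  # all-zero TAC: zero parameters, no error
  f0 <- bfm_fit(tissue_tac(fs, rep(0, fs$n)), dict)
  expect_equal(c(f0$K1, f0$rcps), c(0, 0))
  # a TAC crafted to drive the unconstrained trap coefficient negative:
  # blood-plus-equilibrating signal minus a multiple of the running integral
  y <- 0.1 * dict$blood + 0.5 * dict$B[, 50] - 0.005 * dict$trap
  f2 <- bfm_fit(tissue_tac(fs, y), dict)
  expect_true(all(c(f2$K1, f2$lambda, f2$rcps, f2$Vb) >= 0))
})

test_that("SAIF recovers homogeneous and two-subregion kinetics noise-free", {
  inp <- fx_input(); fs <- fx_schedule(); dict <- fx_dict()
  h <- homogeneous_params(0.05, 0.1, 0.04, 0.05)   # beta 0.14, in band
  f <- saif_fit(homogeneous_tac(h, inp, fs), dict)
  expect_equal(f$n_components, 1L)
  expect_equal(f$K1, h$K1, tolerance = 0.02)
  expect_equal(f$lambda, lambda_from_rates(h$k2k3, h$k4), tolerance = 0.02)
  expect_equal(f$rcps, rcps_from_rates(h$K1, h$k2k3, h$k4, 120),
               tolerance = 0.02)
  # noise-free in-model data is reproduced with WRSS ~ 0
  expect_lt(f$wrss, 1e-8 * sum(homogeneous_tac(h, inp, fs)$values^2))
  # two well-separated subregions, both betas inside the band
  mix <- derive_heterogeneous(h)  # betas 0.2333 and 0.04667
  fh <- saif_fit(heterogeneous_tac(mix, inp, fs), dict)
  expect_equal(fh$n_components, 2L)
  expect_equal(fh$rcps, rcps_from_rates(h$K1, h$k2k3, h$k4, 120),
               tolerance = 0.02)
  # trap-only tissue: degenerate, lambda 0
  trap <- homogeneous_tac(homogeneous_params(0.05, 0, 0.04, 0.05), inp, fs)
  ft <- saif_fit(trap, dict)
  expect_true(ft$degenerate)
  expect_equal(ft$lambda, 0)
  expect_error(saif_fit(trap, dict, band = c(2, 3)), "empty bandpass")
})

test_that("component counting merges adjacent grid points", {
  th <- numeric(46)
  expect_equal(leupet:::count_components(th), 0L)
  th[10] <- 1
  expect_equal(leupet:::count_components(th), 1L)
  th[11] <- 0.5                       # adjacent: same component
  expect_equal(leupet:::count_components(th), 1L)
  th[13] <- 2                         # one empty point away: distinct
  expect_equal(leupet:::count_components(th), 2L)
  th[30] <- 1
  expect_equal(leupet:::count_components(th), 3L)
})

test_that("delay estimation recovers simulated tracer delays", {
  inp <- fx_input(); fs <- fx_schedule()
  h <- homogeneous_params(0.05, 0.1, 0.04, 0.05)
  # no shift: delay 0
  tac0 <- homogeneous_tac(h, inp, fs)
  d0 <- fit_delay(tac0, inp, candidates_s = seq(0, 20, by = 2))
  expect_equal(d0$delay_s, 0)
  # TAC generated from a 10-s-delayed input: 10 s recovered
  tac10 <- homogeneous_tac(h, shift_input(inp, 10), fs)
  d10 <- fit_delay(tac10, inp)
  expect_equal(d10$delay_s, 10)
  # the returned delay minimizes WRSS over the candidates
  expect_equal(min(d10$wrss), d10$wrss[which(d10$candidates_s == 10)])
})

test_that("the bootstrap classifier is calibrated on noise-free voxels", {
  inp <- fx_input(); fs <- fx_schedule(); dict <- fx_dict()
  # on-grid kinetics: the dictionary spans the data, residuals are ~0
  h <- fx_ongrid_params()
  tac <- homogeneous_tac(h, inp, fs)
  b1 <- bootstrap_heterogeneity(tac, dict, n_boot = 30, seed = 11)
  # residuals are ~0: every replicate refits one component
  expect_lt(b1$probability, 0.1)
  expect_false(b1$heterogeneous)
  # determinism under a fixed seed
  b2 <- bootstrap_heterogeneity(tac, dict, n_boot = 30, seed = 11)
  expect_identical(b1$probability, b2$probability)
  # threshold 0 flags any nonzero probability
  het <- heterogeneous_tac(derive_heterogeneous(h), inp, fs)
  b3 <- bootstrap_heterogeneity(het, dict, n_boot = 20, threshold = 0,
                                seed = 12)
  expect_true(b3$heterogeneous == (b3$probability > 0) ||
                b3$probability == 0)
  expect_error(bootstrap_heterogeneity(tac, dict, n_boot = 0), "n_boot")
})

test_that("both estimators report only non-negative estimates under noise", {
  inp <- fx_input(); fs <- fx_schedule(); dict <- fx_dict()
  nm <- calibrate_alpha("voxel", inp, fs)
  tac0 <- homogeneous_tac(reference_library()[[5]], inp, fs)
  reps <- add_noise(tac0, nm, 30, seed = 17)
  for (r in seq_len(ncol(reps))) {
    t <- tissue_tac(fs, reps[, r])
    for (f in list(bfm_fit(t, dict), saif_fit(t, dict))) {
      expect_true(all(c(f$K1, f$lambda, f$rcps, f$Vb) >= 0))
    }
  }
})
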