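test_that("lambda and rCPS follow the macro-parameter algebra", {
  expect_equal(lambda_from_rates(0.1, 0.05), 2 / 3, tolerance = 1e-12)
  expect_equal(lambda_from_rates(0.2, 0), 1)
  expect_equal(lambda_from_rates(0.157, 0.053), 0.7476, tolerance = 1e-4)
  expect_error(lambda_from_rates(0, 0), "undefined")

  expect_equal(rcps_from_rates(0.05, 0.1, 0.05, 120), 3)
  expect_equal(rcps_from_rates(0.07, 0.12, 0, 120), 0)
  expect_error(rcps_from_rates(0.05, 0, 0.05, 120), "degenerate")
  # rCPS via the lambda form is the same quantity
  lam <- lambda_from_rates(0.1, 0.04)
  expect_equal(lam, 0.7143, tolerance = 1e-4)
  expect_equal(rcps_from_rates(0.05, 0.1, 0.04, 120),
               0.05 * (1 - lam) / lam * 120, tolerance = 1e-12)
})

test_that("basis curves match closed forms and a fine-grid quadrature oracle", {
  fs <- frame_schedule(seq(0, 225, by = 15), rep(15, 16))  # first 4 min
  # linear ramp cp = c*t: conv = c*(t/beta - (1 - exp(-beta t))/beta^2),
  # exact for the piecewise-analytic recurrence
  tm <- seq(0, 4, by = 1 / 60)
  cc <- 30
  inp_lin <- input_function_set(tm, cc * tm, cc * tm, cp_unlabeled = 120)
  for (beta in c(0.05, 0.5, 5)) {
    got <- basis_curve(beta, inp_lin, fs)$values
    conv <- cc * (tm / beta - (1 - exp(-beta * tm)) / beta^2)
    want <- vapply(seq_len(fs$n), function(i) {
      sel <- tm >= fs$start[i] - 1e-12 & tm <= fs$end[i] + 1e-12
      x <- tm[sel]; y <- conv[sel]
      sum((y[-1] + y[-length(y)]) / 2 * diff(x)) / fs$dur[i]
    }, 0)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # beta = 0 is the frame-averaged running integral of cp*
  inp <- make_input_functions(t_end = 4.01)
  run_int <- basis_curve(0, inp, fs)$values
  expect_true(all(diff(run_int) > 0))
  # brute-force trapezoidal oracle on a 0.1-s grid, arbitrary input
  tg <- seq(0, 3.75, by = 0.1 / 60)
  cp_g <- stats::approx(inp$time, inp$cp_star, tg)$y
  for (beta in c(0, 0.12, 1.33)) {
    conv_g <- vapply(seq_along(tg), function(k) {
      if (k == 1) return(0)
      x <- tg[1:k]
      y <- cp_g[1:k] * exp(-beta * (tg[k] - x))
      sum((y[-1] + y[-k]) / 2 * diff(x))
    }, 0)
    want <- vapply(seq_len(15), function(i) {
      sel <- tg >= fs$start[i] - 1e-12 & tg <= fs$end[i] + 1e-12
      x <- tg[sel]; y <- conv_g[sel]
      sum((y[-1] + y[-length(y)]) / 2 * diff(x)) / fs$dur[i]
    }, 0)
    got <- basis_curve(beta, inp, fs)$values[1:15]
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("degenerate blood-volume and zero-input cases reduce correctly", {
  fs <- fx_schedule()
  tm <- seq(0, 91, by = 1 / 60)
  zero <- input_function_set(tm, 0 * tm, 0 * tm, cp_unlabeled = 120)
  h <- homogeneous_params(0.05, 0.1, 0.04, 0.05)
  expect_equal(homogeneous_tac(h, zero, fs)$values, rep(0, fs$n))
  # Vb = 1: the TAC is the frame-averaged whole-blood curve
  inp <- fx_input()
  pure_blood <- homogeneous_params(0, 0.1, 0.04, Vb = 1)
  got <- homogeneous_tac(pure_blood, inp, fs)$values
  want <- vapply(seq_len(fs$n), function(i) {
    sel <- inp$time >= fs$start[i] - 1e-12 & inp$time <= fs$end[i] + 1e-12
    x <- inp$time[sel]; y <- inp$cb_star[sel]
    sum((y[-1] + y[-length(y)]) / 2 * diff(x)) / fs$dur[i]
  }, 0)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("a mixture reduces to and recomposes from homogeneous tissues", {
  inp <- fx_input(); fs <- fx_schedule()
  h <- homogeneous_params(0.05, 0.1, 0.04, 0.05)
  hom <- homogeneous_tac(h, inp, fs)
  # n = 1 reduction is exact
  mix1 <- subregion_mixture(list(h), 1, Vb = h$Vb)
  expect_identical(heterogeneous_tac(mix1, inp, fs)$values, hom$values)
  # two identical subregions with weights 0.5/0.5 are the same tissue
  mix2 <- subregion_mixture(list(h, h), c(0.5, 0.5), Vb = h$Vb)
  expect_equal(heterogeneous_tac(mix2, inp, fs)$values, hom$values,
               tolerance = 1e-12)
  # generic 2-subregion mixture equals the weighted sum of the two
  # independently computed tissue parts plus one shared blood term
  a <- homogeneous_params(0.08, 0.17, 0.07)
  b <- homogeneous_params(0.02, 0.03, 0.012)
  w <- c(0.3, 0.7); Vb <- 0.05
  mix <- subregion_mixture(list(a, b), w, Vb = Vb)
  got <- heterogeneous_tac(mix, inp, fs)$values
  tissue_only <- function(p) {
    p0 <- homogeneous_params(p$K1, p$k2k3, p$k4, Vb = 0)
    homogeneous_tac(p0, input_function_set(inp$time, inp$cp_star,
                                           0 * inp$time, cp_unlabeled = 120),
                    fs)$values
  }
  blood <- homogeneous_tac(homogeneous_params(0, 1, 1, Vb = Vb), inp, fs)$values
  want <- (1 - Vb) / 1 * (w[1] * tissue_only(a) + w[2] * tissue_only(b)) + blood
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(subregion_mixture(list(a, b), c(0.4, 0.7)), "sum to 1")
})

test_that("frame averages are converged at the 1-s internal grid", {
  fs <- fx_schedule()
  h <- homogeneous_params(0.05, 0.1, 0.04, 0.05)
  v1 <- homogeneous_tac(h, make_input_functions(dt = 1 / 60), fs)$values
  v2 <- homogeneous_tac(h, make_input_functions(dt = 1 / 120), fs)$values
  expect_lt(max(abs(v1 - v2) / pmax(abs(v2), 1e-12)), 5e-4)
})

test_that("macro parameters recover the generating rate constants", {
  m <- macros_from_spectrum(
    spectral_representation(0.01, 0.02, 0.1, Vb = 0.05), cp = 120)
  expect_equal(m$K1, 0.031579, tolerance = 1e-5)
  expect_equal(m$lambda, 2 / 3, tolerance = 1e-12)
  expect_equal(m$rcps, 1.8947, tolerance = 1e-4)
  # no trapping: lambda 1, rCPS 0
  m0 <- macros_from_spectrum(
    spectral_representation(0, 0.02, 0.1, Vb = 0.05), cp = 120)
  expect_equal(m0$lambda, 1)
  expect_equal(m0$rcps, 0)
  # spectrum built from rate constants round-trips K1, lambda, rCPS
  for (h in fx_library()[c(1, 10, 19)]) {
    spec <- spectrum_from_mixture(subregion_mixture(list(h), 1, Vb = h$Vb))
    m <- macros_from_spectrum(spec, 120)
    expect_equal(m$K1, h$K1, tolerance = 1e-12)
    expect_equal(m$lambda, lambda_from_rates(h$k2k3, h$k4), tolerance = 1e-12)
    expect_equal(m$rcps, rcps_from_rates(h$K1, h$k2k3, h$k4, 120),
                 tolerance = 1e-12)
  }
  expect_error(
    macros_from_spectrum(spectral_representation(0.01, 0.02, 0.1, Vb = 1), 120),
    "Vb >= 1")
  deg <- macros_from_spectrum(spectral_representation(0, numeric(), numeric(),
                                                      Vb = 0.05), 120)
  expect_true(deg$degenerate)
  expect_equal(deg$rcps, 0)
})
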