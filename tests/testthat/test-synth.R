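test_that("the reference library spans the physiologic ranges with Vb fixed", {
  lib <- fx_library()
  expect_length(lib, 19)
  K1 <- vapply(lib, `[[`, 0, "K1")
  k2k3 <- vapply(lib, `[[`, 0, "k2k3")
  k4 <- vapply(lib, `[[`, 0, "k4")
  expect_equal(range(K1), c(0.025, 0.062))
  expect_equal(range(k2k3), c(0.054, 0.157))
  expect_equal(range(k4), c(0.027, 0.053))
  expect_true(all(vapply(lib, `[[`, 0, "Vb") == 0.05))
  # deterministic
  expect_identical(reference_library(), lib)
})

test_that("the heterogeneous construction satisfies its five constraints", {
  # closed-form spot check
  mix <- derive_heterogeneous(homogeneous_params(0.05, 0.1, 0.04))
  a <- mix$subregions[[1]]; b <- mix$subregions[[2]]
  expect_equal(c(a$K1, a$k2k3, a$k4),
               c(0.083333, 0.166667, 0.066667), tolerance = 1e-4)
  expect_equal(c(b$K1, b$k2k3, b$k4),
               c(0.016667, 0.033333, 0.013333), tolerance = 1e-4)
  for (h in fx_library()) {
    mix <- derive_heterogeneous(h)
    a <- mix$subregions[[1]]; b <- mix$subregions[[2]]
    # equal weights, shared Vb
    expect_identical(mix$weights, c(0.5, 0.5))
    expect_equal(mix$Vb, 0.05)
    # lambda equal in the two subregions (and equal to the homogeneous one)
    lam <- lambda_from_rates(h$k2k3, h$k4)
    expect_equal(lambda_from_rates(a$k2k3, a$k4), lam, tolerance = 1e-12)
    expect_equal(lambda_from_rates(b$k2k3, b$k4), lam, tolerance = 1e-12)
    # weighted K1 preserved
    expect_equal(0.5 * a$K1 + 0.5 * b$K1, h$K1, tolerance = 1e-12)
    # 5x turnover ratio and 25x K1(k2+k3) product ratio
    expect_equal(a$beta / b$beta, 5, tolerance = 1e-12)
    expect_equal((a$K1 * a$k2k3) / (b$K1 * b$k2k3), 25, tolerance = 1e-12)
    # weighted rCPS preserved
    rc <- function(p) rcps_from_rates(p$K1, p$k2k3, p$k4, 120)
    expect_equal(0.5 * rc(a) + 0.5 * rc(b), rc(h), tolerance = 1e-12)
  }
  expect_error(derive_heterogeneous(homogeneous_params(0.05, 0, 0.04)),
               "degenerate")
})

test_that("frame noise follows the variance model and is seed-reproducible", {
  fs <- frame_schedule(c(0, 15, 30, 45), rep(15, 4))
  tac <- tissue_tac(fs, rep(100, 4))
  # alpha = 1, gamma = 0, CT = 100, dt = 0.25 min -> variance 400 (SD 20)
  nm <- noise_model(alpha = 1, gamma = 0)
  reps <- add_noise(tac, nm, 4000, seed = 99)
  expect_equal(apply(reps, 1, stats::sd), rep(20, 4), tolerance = 0.06)
  # alpha = 0 reproduces the noise-free TAC exactly
  expect_equal(add_noise(tac, noise_model(0), 3, seed = 1),
               matrix(100, 4, 3))
  # reproducibility and law-of-large-numbers consistency
  a <- add_noise(tac, nm, 200, seed = 7)
  b <- add_noise(tac, nm, 200, seed = 7)
  expect_identical(a, b)
  expect_true(all(abs(rowMeans(a) - 100) < 3 * 20 / sqrt(200)))
})

test_that("alpha calibration hits the target relative SD at the peak frame", {
  inp <- fx_input(); fs <- fx_schedule()
  tac <- homogeneous_tac(reference_library()[[10]], inp, fs)
  i <- which.max(tac$values)
  targets <- c(voxel = 0.25, roi = 0.05)
  for (lv in names(targets)) {
    nm <- calibrate_alpha(lv, inp, fs)
    sd_peak <- sqrt(nm$alpha * exp(nm$gamma * fs$mid[i]) *
                      tac$values[i] / fs$dur[i])
    expect_equal(sd_peak / tac$values[i], unname(targets[lv]),
                 tolerance = 1e-9)
  }
})

test_that("the phantom is homogeneous by construction with ordered class rCPS", {
  inp <- fx_input(); fs <- fx_schedule()
  sp <- phantom_spec(dim = c(16, 16, 8))
  expect_setequal(unique(as.integer(sp$labels)), c(0L, 1L, 2L))
  ph <- build_phantom(sp, inp, fs)
  # a noise-free gray voxel carries exactly the gray-class TAC
  g <- which(sp$labels == 1L, arr.ind = TRUE)[1, ]
  expect_equal(ph$img[g[1], g[2], g[3], ], ph$class_tacs$gray$values)
  # every brain voxel is kinetically homogeneous: its TAC is one class TAC
  expect_true(all(ph$truth$class %in% c("gray", "white")))
  # white-matter rCPS below gray-matter rCPS with the library-extreme classes
  expect_lt(mean(ph$truth$rcps[ph$truth$class == "white"]),
            mean(ph$truth$rcps[ph$truth$class == "gray"]))
  # noisy phantom reproducible under seed
  nm <- noise_model(0.5)
  p1 <- build_phantom(sp, inp, fs, noise = nm, seed = 3)
  p2 <- build_phantom(sp, inp, fs, noise = nm, seed = 3)
  expect_identical(p1$img, p2$img)
  # default dimensions
  expect_equal(phantom_spec()$dim, c(48L, 48L, 24L))
})
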