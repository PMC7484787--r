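test_that("mean lifetime is the amplitude-weighted mean and stays in [tau1, tau2]", {
  expect_equal(mean_lifetime(0, 999, 1, 2289), 2289)
  expect_equal(mean_lifetime(1.5, 533, 1, 2289), 1235.4)
  expect_equal(mean_lifetime(1, 500, 1, 1500), 1000)
  expect_error(mean_lifetime(0, 500, 0, 1500), "a1 \\+ a2")
  set.seed(42)
  for (i in 1:50) {
    a <- runif(2, 0.01, 5)
    tau <- sort(runif(2, 50, 5000))
    tm <- mean_lifetime(a[1], tau[1], a[2], tau[2])
    expect_gte(tm, tau[1])
    expect_lte(tm, tau[2])
  }
})

test_that("amplitude ratio and asymmetry", {
  expect_equal(amplitude_ratios(2, 2), list(ratio = 1, asym = 0))
  expect_equal(amplitude_ratios(3, 1), list(ratio = 3, asym = 0.5))
  expect_equal(amplitude_ratios(1.5, 1), list(ratio = 1.5, asym = 0.2))
  expect_error(amplitude_ratios(1, 0), "a2")
})

test_that("model decay: mono-exponential limit under a delta IRF", {
  m <- model_decay(3, 700, 0, 900, delta1, 256, DW)
  expect_equal(m / m[1], exp(-(0:255) * DW / 700), tolerance = 1e-10)
  expect_error(model_decay(1, -5, 1, 100, delta1), "positive")
})

test_that("model decay sum matches the continuous closed form", {
  # midpoint-sampled decay: sum ~= a * tau/dt * (1 - exp(-T/tau))
  for (pars in list(c(2, 400, 1, 2000), c(1.5, 533, 1, 2289),
                    c(1, 1000, 0.5, 3000))) {
    m <- model_decay(pars[1], pars[2], pars[3], pars[4], delta1, 256, DW)
    closed <- pars[1] * pars[2] / DW * (1 - exp(-12500 / pars[2])) +
      pars[3] * pars[4] / DW * (1 - exp(-12500 / pars[4]))
    expect_lt(abs(sum(m) - closed) / closed, 1e-3)
  }
})

test_that("Gaussian-IRF model equals brute-force oversampled convolution", {
  # 10x oversampled numeric convolution, then box-averaged per channel
  os <- 10
  dt <- DW / os
  tfine <- (seq_len(256 * os) - 0.5) * dt
  sigma <- 150 / (2 * sqrt(2 * log(2)))
  mu <- (10 - 0.5) * DW
  irf_fine <- exp(-0.5 * ((tfine - mu) / sigma)^2)
  irf_fine <- irf_fine / sum(irf_fine)
  dec_fine <- 2 * exp(-tfine / 500) + 1 * exp(-tfine / 2200)
  conv_fine <- stats::convolve(irf_fine, rev(dec_fine),
                               type = "open")[seq_len(256 * os)]
  # kernel indexed from channel leading edge: shift by half a coarse
  # channel before box-averaging to the coarse grid
  shift <- os / 2
  conv_shift <- c(conv_fine[-seq_len(shift)], rep(0, shift))
  coarse <- colSums(matrix(conv_shift, os))
  m <- model_decay(2, 500, 1, 2200, girf, 256, DW)
  scale <- sum(coarse[20:200]) / sum(m[20:200])
  expect_lt(max(abs(m - coarse / scale)[20:200] / max(m)), 0.005)
})

test_that("spatial binning: identity at b = 0, 49x kernel sum at b = 3", {
  cube <- uniform_cube(n = 9, photons = 490)
  expect_identical(bin_decays(cube, 0)$counts, cube$counts)
  b3 <- bin_decays(cube, 3)
  # interior pixel aggregates center + 48 neighbors
  expect_equal(b3$counts[5, 5, ], 49 * cube$counts[5, 5, ])
  # corner kernel truncated to the 4x4 in-bounds block
  expect_equal(b3$counts[1, 1, ], 16 * cube$counts[1, 1, ])
  # photon totals conserved up to border truncation (here: interior only)
  inner <- b3$counts[4:6, 4:6, , drop = FALSE]
  expect_equal(sum(inner), 49 * 9 * sum(cube$counts[1, 1, ]))
})

test_that("binning a random integer cube matches a direct neighborhood sum", {
  set.seed(7)
  counts <- array(rpois(6 * 6 * 4, 5), c(6, 6, 4))
  cube <- make_cube(counts, DW, 1, delta_irf(4, 1), 0.3)
  b <- bin_decays(cube, 1)
  for (i in c(1, 3, 6)) for (j in c(1, 4, 6)) {
    ii <- max(1, i - 1):min(6, i + 1)
    jj <- max(1, j - 1):min(6, j + 1)
    expect_equal(b$counts[i, j, ], apply(counts[ii, jj, , drop = FALSE], 3, sum))
  }
})

test_that("noiseless bi-exponential round-trips through the fitter within 1%", {
  curve <- biexp_hist(2, 400, 1, 2000, 1e4, delta1)
  fp <- fit_pixel(curve, delta1, fit_config(intensity_threshold = 1), 1, DW)
  expect_true(fp$valid)
  expect_equal(fp$tau1, 400, tolerance = 0.01)
  expect_equal(fp$tau2, 2000, tolerance = 0.01)
  expect_equal(fp$a1 / fp$a2, 2, tolerance = 0.01)
  expect_lte(fp$tau1, fp$tau2)
})

test_that("pixels below the intensity threshold are masked, not fitted", {
  curve <- biexp_hist(2, 400, 1, 2000, 100, girf)
  fp <- fit_pixel(curve, girf, fit_config(intensity_threshold = 200), 1, DW)
  expect_false(fp$valid)
  expect_true(is.na(fp$tau_m))
})

test_that("fit is invariant to amplitude rescaling of the input", {
  curve <- biexp_hist(1.5, 533, 1, 2289, 5e3, girf)
  cfg <- fit_config(intensity_threshold = 1, weight_scheme = "neyman")
  f1 <- fit_pixel(curve, girf, cfg, 1, DW)
  f2 <- fit_pixel(curve * 10, girf, cfg, 1, DW)
  expect_equal(f2$tau1, f1$tau1, tolerance = 1e-4)
  expect_equal(f2$tau2, f1$tau2, tolerance = 1e-4)
  expect_equal(f2$a1 / f1$a1, 10, tolerance = 1e-3)
  expect_equal(f2$a2 / f1$a2, 10, tolerance = 1e-3)
})

test_that("Poisson replicates at the resting-MC operating point recover tau_m unbiasedly", {
  # 5e3 photons, tau1 533 / tau2 2289 / a1:a2 = 1.5 (tau_m 1235.4)
  shape <- biexp_hist(0.6, 533, 0.4, 2289, 5e3)
  cfg <- fit_config(intensity_threshold = 1)
  set.seed(101)
  tm <- replicate(60, fit_pixel(rpois(256, shape), girf, cfg, 1, DW)$tau_m)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1235.4), 3 * se)
})

test_that("fit_image: all-zero cube fully masked; uniform scene homogeneous", {
  zero <- make_cube(array(0, c(4, 4, 256)), DW, 1, girf, 0.3)
  fmz <- fit_image(zero, config = fit_config(binning = 0))
  expect_false(any(fmz$valid))

  set.seed(8)
  shape <- biexp_hist(1, 1200, 0, 1200, 800)
  counts <- array(rpois(6 * 6 * 256, rep(shape, each = 36)), c(6, 6, 256))
  cube <- make_cube(counts, DW, 1, girf, 0.3)
  fm <- fit_image(cube, config = fit_config(binning = 1,
                                            intensity_threshold = 10))
  tm <- fm$maps$tau_m[fm$valid]
  expect_gt(length(tm), 30)
  expect_lt(sd(tm) / mean(tm), 0.05)
  expect_error(fit_image(make_cube(counts, DW, 0 + 0, girf, 0.3)$counts))
})

test_that("fit_image separates a two-region scene by > 10 SDs", {
  set.seed(9)
  s1 <- biexp_hist(1, 600, 0, 600, 2e4)  # short-lifetime half
  s2 <- biexp_hist(1, 1600, 0, 1600, 2e4) # elastin-like half
  counts <- array(0, c(6, 12, 256))
  counts[, 1:6, ] <- rpois(6 * 6 * 256, rep(s1, each = 36))
  counts[, 7:12, ] <- rpois(6 * 6 * 256, rep(s2, each = 36))
  cube <- make_cube(counts, DW, 1, girf, 0.3)
  fm <- fit_image(cube, config = fit_config(binning = 0,
                                            intensity_threshold = 10))
  a <- fm$maps$tau_m[, 1:6][fm$valid[, 1:6]]
  b <- fm$maps$tau_m[, 7:12][fm$valid[, 7:12]]
  pooled_sd <- sqrt((var(a) + var(b)) / 2)
  expect_gt(abs(mean(b) - mean(a)), 10 * pooled_sd)
})
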