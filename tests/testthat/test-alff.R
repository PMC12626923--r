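test_that("amplitude_spectrum matches the direct projection oracle", {
  tr <- 2.17; n <- 176
  tt <- (seq_len(n) - 1) * tr
  f20 <- 20 / (n * tr)                       # exact bin, ~0.052 Hz
  x <- 3 * sin(2 * pi * f20 * tt + 0.7)
  sp <- amplitude_spectrum(x, tr)
  expect_equal(max(sp$amplitudes), 3, tolerance = 1e-9)
  expect_equal(sp$frequencies_hz[which.max(sp$amplitudes)], f20)
  # full-spectrum agreement with the sin/cos projection oracle
  set.seed(8)
  y <- rnorm(60)
  o <- oracle_spectrum(y, tr)
  expect_equal(amplitude_spectrum(y, tr)$amplitudes, o$amplitudes,
               tolerance = 1e-10)
  expect_equal(max(amplitude_spectrum(rep(4, 32), tr)$amplitudes[-1]), 0,
               tolerance = 1e-12)
  # linearity: two in-band sinusoids give two peaks of the right height
  f10 <- 10 / (n * tr)
  x2 <- 2 * sin(2 * pi * f10 * tt) + 5 * sin(2 * pi * f20 * tt)
  sp2 <- amplitude_spectrum(x2, tr)
  expect_equal(sp2$amplitudes[11], 2, tolerance = 1e-9)
  expect_equal(sp2$amplitudes[21], 5, tolerance = 1e-9)
  expect_error(amplitude_spectrum(c(1, NA, 2, 3), tr), "finite")
})

test_that("alff equals the brute-force bin enumeration oracle", {
  tr <- 2.17; band <- spectrum_band(0.01, 0.08)
  set.seed(11)
  for (n in c(64, 100, 176)) {
    x <- rnorm(n)
    expect_equal(alff(x, tr, band), oracle_alff(x, tr, 0.01, 0.08),
                 tolerance = 1e-12)
  }
  # pure in-band sinusoid at one bin, amplitude A, B in-band bins -> A/B
  n <- 176
  tt <- (seq_len(n) - 1) * tr
  x <- 4 * sin(2 * pi * (20 / (n * tr)) * tt)
  B <- length(alffr:::band_bin_indices(n, tr, band))
  expect_equal(B, 27)    # true bin count at this length/TR/band
  expect_equal(alff(x, tr, band), 4 / B, tolerance = 1e-9)
  expect_equal(alff(rep(0, 64), tr, band), 0)
  y <- rnorm(100)
  expect_equal(alff(2 * y, tr, band), 2 * alff(y, tr, band), tolerance = 1e-12)
  expect_equal(alff(y + 100, tr, band), alff(y, tr, band), tolerance = 1e-9)
  # printed denominator variant divides by N2 - N1 instead of bin count
  expect_equal(alff(x, tr, band, denominator = "printed") * (B - 1),
               alff(x, tr, band) * B, tolerance = 1e-9)
  expect_error(alff(rnorm(16), 2.17, spectrum_band(0.011, 0.012)), "no DFT bins")
})

test_that("band amplitude sum equals least-squares projection (Parseval-style)", {
  tr <- 2; band <- spectrum_band(0.02, 0.2)
  set.seed(12)
  for (n in c(32, 48, 64)) {
    x <- rnorm(n)
    idx <- alffr:::band_bin_indices(n, tr, band)
    sp <- amplitude_spectrum(x, tr)
    # oracle: least-squares amplitude of a sin+cos pair fitted at each bin
    tt <- seq_len(n) - 1
    proj <- vapply(idx - 1, function(k) {
      X <- cbind(cos(2 * pi * k * tt / n), sin(2 * pi * k * tt / n))
      cf <- qr.solve(X, x)
      sqrt(sum(cf^2))
    }, numeric(1))
    expect_equal(sum(sp$amplitudes[idx]), sum(proj), tolerance = 1e-8)
  }
})

test_that("alff_map agrees voxelwise with alff() and flags empty masks", {
  s <- noise_series(13, n = 64, dims = c(3, 3, 2))
  band <- spectrum_band(0.01, 0.08)
  m <- alff_map(s, band)
  per_voxel <- apply(matrix(s$values, ncol = 64), 1,
                     function(v) alff(v, s$tr_s, band))
  expect_equal(as.vector(m$values), per_voxel, tolerance = 1e-12)
  s$mask[] <- FALSE
  expect_error(alff_map(s, band), "empty mask")
})

test_that("noiseless planted oscillation lights up only its ROI", {
  cfg <- simulation_config(grid_dims = c(10, 10, 8), n_volumes = 64,
                           noise = list(ar1_coef = 0, sigma = 0),
                           smooth_fwhm_mm = 0,
                           planted_signals = list(list(
                             roi = list(shape = "box", center = c(5, 5, 4), half = 1),
                             frequency_hz = 0.04, amplitude = 2,
                             amplitude_sd = 0, group_scope = "all")),
                           delta_links = list(), seed = 2,
                           cohort = alffr:::default_cohort(3, 2))
  sim <- simulate_cohort(cfg)
  s <- sim$series[[1]]
  m <- alff_map(s, spectrum_band())
  roi <- sim$truth$rois[[1]]
  in_roi <- m$values[roi]
  out_roi <- m$values[setdiff(which(s$mask), roi)]
  expect_true(all(in_roi > 0.01))
  expect_equal(max(abs(out_roi)), 0, tolerance = 1e-9)
})

test_that("white-noise ALFF maps are spatially near-uniform", {
  # coefficient of variation of the map, averaged over 100 seeds, < 20%
  cv <- vapply(1:100, function(sd) {
    s <- noise_series(sd, n = 176, dims = c(4, 4, 2))
    m <- alff_map(s, spectrum_band())
    v <- m$values[m$mask]
    sd(v) / mean(v)
  }, numeric(1))
  expect_lt(mean(cv), 0.20)
})

test_that("global-mean normalization yields mean 1 and scale invariance", {
  s <- noise_series(14, n = 64)
  m <- normalize_by_global_mean(alff_map(s, spectrum_band()))
  expect_equal(mean(m$values[m$mask]), 1, tolerance = 1e-12)
  expect_identical(m$kind, "malff")
  # {1,3} -> {0.5, 1.5}
  vm <- voxel_map(array(c(1, 3), c(2, 1, 1)), kind = "alff")
  expect_equal(as.vector(normalize_by_global_mean(vm)$values), c(0.5, 1.5))
  u <- voxel_map(array(7, c(3, 3, 1)), kind = "alff")
  expect_equal(unique(as.vector(normalize_by_global_mean(u)$values)), 1)
  # invariance to global rescaling of the series
  s2 <- s; s2$values <- 5 * s2$values
  m2 <- normalize_by_global_mean(alff_map(s2, spectrum_band()))
  expect_equal(m2$values, m$values, tolerance = 1e-10)
  z <- voxel_map(array(0, c(2, 2, 1)), kind = "alff")
  expect_error(normalize_by_global_mean(z), "positive")
})

test_that("canonical fALFF is a ratio in [0,1] and distinct from mALFF", {
  s <- noise_series(15, n = 96)
  f <- falff_map(s, spectrum_band())
  expect_true(all(f$values[f$mask] >= 0 & f$values[f$mask] <= 1))
  m <- normalize_by_global_mean(alff_map(s, spectrum_band()))
  expect_false(isTRUE(all.equal(f$values, m$values)))
})
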