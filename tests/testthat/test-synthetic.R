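test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(simulation_config(tr_s = 2.17, planted_signals = list(
    list(roi = list(shape = "box", center = c(5, 5, 5), half = 1),
         frequency_hz = 0.3, amplitude = 1, group_scope = "all"))),
    "frequency")
  expect_error(simulation_config(planted_signals = list(
    list(roi = list(shape = "box", center = c(5, 5, 5), half = 1),
         frequency_hz = 0.04, amplitude = -1, group_scope = "all"))),
    "amplitudes")
  expect_error(simulation_config(delta_links = list(
    list(roi = 1, clinical_index = "dst_score", target_r = 1.2))), "target_r")
  expect_error(simulation_config(noise = list(ar1_coef = 1, sigma = 1)), "ar1")
  expect_error(simulation_config(delta_links = list(
    list(roi = 9, clinical_index = "dst_score", target_r = 0.5))),
    "non-existent")
})

test_that("cohort shape: one series per subject-session, fully reproducible", {
  cfg <- simulation_config(grid_dims = c(8, 8, 6), n_volumes = 24,
                           smooth_fwhm_mm = 0,
                           cohort = alffr:::default_cohort(4, 3),
                           planted_signals = list(), delta_links = list(),
                           seed = 5)
  sim <- simulate_cohort(cfg)
  expect_length(sim$series, 4 + 2 * 3)
  expect_equal(nrow(sim$subjects), 10)
  expect_equal(table(sim$subjects$session)[["single"]], 4)
  expect_equal(table(sim$subjects$session)[["pre"]], 3)
  # series order matches the subjects table
  expect_identical(vapply(sim$series, `[[`, "", "subject_id"), sim$subjects$id)
  # healthy controls carry no laboratory values
  hc <- sim$subjects[sim$subjects$group == "HC", ]
  expect_true(all(is.na(hc$ammonia_umol_l)) && all(is.na(hc$child_pugh_points)))
  pat <- sim$subjects[sim$subjects$group == "MHE", ]
  expect_true(all(pat$ammonia_umol_l > 0) && all(pat$prothrombin_time_s > 0))
  # determinism: same seed -> bit-identical; different seed -> different
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim2$series[[1]]$values, sim$series[[1]]$values)
  expect_identical(sim2$subjects, sim$subjects)
  cfg7 <- cfg; cfg7$seed <- 7L
  expect_false(identical(simulate_cohort(cfg7)$series[[1]]$values,
                         sim$series[[1]]$values))
})

test_that("default cohort matches the emulated study dimensions", {
  cfg <- simulation_config()
  expect_equal(cfg$cohort$n_hc, 32L)
  expect_equal(cfg$cohort$n_patients, 27L)
  expect_equal(cfg$n_volumes, 186L)
  expect_equal(cfg$tr_s, 2.17)
  plan <- alffr:::plan_cohort(cfg)
  expect_equal(nrow(plan$subjects), 32 + 2 * 27)   # 86 subject-sessions
})

test_that("zero-noise cases produce exact constructions", {
  cfg <- simulation_config(grid_dims = c(8, 8, 6), n_volumes = 50,
                           noise = list(ar1_coef = 0, sigma = 0),
                           smooth_fwhm_mm = 0,
                           planted_signals = list(), delta_links = list(),
                           cohort = alffr:::default_cohort(2, 2), seed = 9)
  sim <- simulate_cohort(cfg)
  expect_equal(range(sim$series[[1]]$values), c(100, 100))  # pure baseline
  # one planted oscillation, sigma 0: exact sinusoid inside, constant outside
  cfg$planted_signals <- list(list(
    roi = list(shape = "box", center = c(4, 4, 3), half = 1),
    frequency_hz = 0.04, amplitude = 2, amplitude_sd = 0, group_scope = "all"))
  cfg <- simulation_config(grid_dims = cfg$grid_dims, n_volumes = 50,
                           noise = cfg$noise, smooth_fwhm_mm = 0,
                           planted_signals = cfg$planted_signals,
                           delta_links = list(),
                           cohort = alffr:::default_cohort(2, 2), seed = 9)
  sim <- simulate_cohort(cfg)
  s <- sim$series[[1]]
  roi <- sim$truth$rois[[1]]
  v <- arrayInd(roi[1], dim(s$mask))
  ts_in <- s$values[v[1], v[2], v[3], ] - 100
  # fit amplitude and phase: residual must vanish
  tt <- (seq_len(50) - 1) * cfg$tr_s
  X <- cbind(sin(2 * pi * 0.04 * tt), cos(2 * pi * 0.04 * tt))
  cf <- qr.solve(X, ts_in)
  expect_equal(sqrt(sum(cf^2)), 2, tolerance = 1e-9)
  expect_lt(max(abs(ts_in - X %*% cf)), 1e-9)
  out_v <- arrayInd(setdiff(which(s$mask), roi)[1], dim(s$mask))
  expect_equal(unique(s$values[out_v[1], out_v[2], out_v[3], ]), 100)
})

test_that("spectral and AR(1) fidelity of the generator", {
  # sigma = 0: band energy of a planted-ROI voxel concentrates at the
  # planted bin (exactly for an on-bin frequency, +-1 bin with leakage)
  fidelity <- function(freq_hz) {
    cfg <- simulation_config(grid_dims = c(6, 6, 4), n_volumes = 176,
                             noise = list(ar1_coef = 0, sigma = 0),
                             smooth_fwhm_mm = 0,
                             planted_signals = list(list(
                               roi = list(shape = "box", center = c(3, 3, 2), half = 1),
                               frequency_hz = freq_hz, amplitude = 1,
                               amplitude_sd = 0, group_scope = "all")),
                             delta_links = list(),
                             cohort = alffr:::default_cohort(2, 2), seed = 4)
    sim <- simulate_cohort(cfg)
    s <- sim$series[[1]]
    v <- arrayInd(sim$truth$rois[[1]][1], dim(s$mask))
    sp <- amplitude_spectrum(s$values[v[1], v[2], v[3], ] - 100, s$tr_s)
    k_star <- which.min(abs(sp$frequencies_hz - freq_hz))
    band_idx <- alffr:::band_bin_indices(176, s$tr_s, spectrum_band())
    in_peak <- sum(sp$amplitudes[intersect(band_idx, (k_star - 1):(k_star + 1))]^2)
    in_peak / sum(sp$amplitudes[band_idx]^2)
  }
  expect_gt(fidelity(16 / (176 * 2.17)), 1 - 1e-9)   # exact bin
  expect_gt(fidelity(0.04), 0.9)                     # non-integer cycles
  # AR(1): lag-1 autocorrelation of a long noise-only series within 0.02
  cfgA <- simulation_config(grid_dims = c(5, 5, 4), n_volumes = 6000,
                            noise = list(ar1_coef = 0.45, sigma = 2),
                            smooth_fwhm_mm = 0, planted_signals = list(),
                            delta_links = list(),
                            cohort = alffr:::default_cohort(1, 1), seed = 12)
  simA <- simulate_cohort(cfgA)
  x <- simA$series[[1]]$values[3, 3, 2, ]
  expect_lt(abs(acf(x, plot = FALSE)$acf[2] - 0.45), 0.02)
  expect_lt(abs(sd(x) - 2), 0.15)
})

test_that("plant_delta_correlation hits its target", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3.5)
  y1 <- plant_delta_correlation(x, "dst_score", 1, seed = 2)
  expect_equal(cor(x, as.numeric(y1)), 1, tolerance = 1e-12)
  ym <- plant_delta_correlation(x, "dst_score", -1, seed = 2)
  expect_equal(cor(x, as.numeric(ym)), -1, tolerance = 1e-12)
  set.seed(3)
  big <- rnorm(10000)
  y0 <- plant_delta_correlation(big, "dst_score", 0, seed = 4)
  expect_lt(abs(cor(big, as.numeric(y0))), 0.05)
  expect_error(plant_delta_correlation(rep(1, 10), "dst_score", 0.5, seed = 1),
               "degenerate")
  expect_error(plant_delta_correlation(x, "dst_score", 1.5, seed = 1), "target_r")
  expect_error(plant_delta_correlation(c(1, 2), "dst_score", 0.5, seed = 1),
               "at least 3")
})

test_that("planted clinical deltas correlate with the amplitude change", {
  cfg <- recovery_sim_config(seed = 21)
  plan <- alffr:::plan_cohort(cfg)
  pd <- plan$planted_deltas[[1]]
  expect_identical(pd$clinical_index, "dst_score")
  # the realized delta stored in the subjects table equals the sidecar's
  pre <- plan$subjects[plan$pre_rows, ]
  post <- plan$subjects[plan$post_rows, ]
  expect_equal(post$dst_score - pre$dst_score, pd$clinical_delta,
               tolerance = 1e-9)
  expect_gt(cor(pd$clinical_delta, pd$amplitude_delta), 0.5)
})

test_that("write_cohort emits readable NIfTI, TSV and ground truth", {
  cfg <- simulation_config(grid_dims = c(8, 8, 6), n_volumes = 16,
                           smooth_fwhm_mm = 0, planted_signals = list(),
                           delta_links = list(),
                           cohort = alffr:::default_cohort(2, 1), seed = 6)
  sim <- simulate_cohort(cfg)
  d <- file.path(tempdir(), "cohort_out")
  write_cohort(sim, d)
  expect_true(file.exists(file.path(d, "subjects.tsv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  expect_true(file.exists(file.path(d, "hc01_single.nii.gz")))
  back <- read_nifti(file.path(d, "hc01_single.nii.gz"), as = "series")
  expect_equal(back$values, sim$series[[1]]$values, tolerance = 1e-4)
  tab <- read.delim(file.path(d, "subjects.tsv"))
  expect_equal(nrow(tab), 4)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_equal(gt$seed, 6)
})
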