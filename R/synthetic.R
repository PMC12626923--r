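# Synthetic BOLD cohort generator. Emulates the study design the inference
# stages assume: 32 healthy controls (one session) and 27 patients scanned
# pre and post treatment, TR 2.17 s, 186 volumes, band-limited oscillatory
# signal planted in chosen regions on top of AR(1) noise that is spatially
# smoothed so the true field smoothness is known, plus a clinical covariate
# table with the cohort's published summary statistics and planted
# delta-correlations. Everything is reproducible from one integer seed.

#' Simulation configuration
#'
#' Defaults describe a desk-scale version of the emulated study: 24x24x16
#' grid at 3 mm (kept small so tests run in seconds; scale up via
#' `grid_dims`), TR 2.17 s, 186 volumes, AR(1) noise (phi = 0.3, sigma = 1)
#' smoothed at 6 mm, an ellipsoidal brain mask, two planted 5x5x5 regions
#' (one longitudinal amplitude change in patients, one tonic group
#' difference), and one planted ROI-to-clinical delta-correlation
#' (Digit Symbol Test, target r = 0.8).
#'
#' @param grid_dims integer 3-vector, voxels per axis.
#' @param voxel_size_mm voxel edge (mm).
#' @param tr_s repetition time (s).
#' @param n_volumes timepoints per run.
#' @param noise list `(ar1_coef in [0,1), sigma >= 0)`.
#' @param smooth_fwhm_mm spatial smoothing applied to the noise field; this
#'   is the true smoothness recovered by the random-field stage.
#' @param baseline constant signal offset (arbitrary units).
#' @param planted_signals list of signals; each a list with `roi`
#'   (`list(shape = "box", center, half)`), `frequency_hz`, `amplitude`,
#'   optional `amplitude_post` (defaults to `amplitude`), `amplitude_sd`
#'   (between-subject SD of amplitude and of the pre-to-post change) and
#'   `group_scope` in `"hc"`, `"patients"`, `"all"`.
#' @param cohort list with `n_hc`, `n_patients` and `clinical`, a list of
#'   per-index distribution parameters (see `default_clinical()`).
#' @param delta_links list of `(roi = signal index, clinical_index,
#'   target_r)`; the named clinical index's delta is generated with the
#'   target correlation against that signal's per-patient amplitude change.
#' @param seed integer master seed.
#' @return validated object of class `simulation_config`.
#' @export
simulation_config <- function(grid_dims = c(24, 24, 16), voxel_size_mm = 3,
                              tr_s = 2.17, n_volumes = 186,
                              noise = list(ar1_coef = 0.3, sigma = 1),
                              smooth_fwhm_mm = 6, baseline = 100,
                              planted_signals = default_planted_signals(),
                              cohort = default_cohort(),
                              delta_links = list(list(roi = 1,
                                                      clinical_index = "dst_score",
                                                      target_r = 0.8)),
                              seed = 1L) {
  cfg <- structure(list(grid_dims = as.integer(grid_dims),
                        voxel_size_mm = as.numeric(voxel_size_mm),
                        tr_s = tr_s, n_volumes = as.integer(n_volumes),
                        noise = noise, smooth_fwhm_mm = smooth_fwhm_mm,
                        baseline = baseline,
                        planted_signals = planted_signals, cohort = cohort,
                        delta_links = delta_links, seed = as.integer(seed)),
                   class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

default_planted_signals <- function() {
  list(list(roi = list(shape = "box", center = c(9, 9, 8), half = 2),
            frequency_hz = 0.04, amplitude = 1.0, amplitude_post = 1.6,
            amplitude_sd = 0.25, group_scope = "patients"),
       list(roi = list(shape = "box", center = c(16, 16, 9), half = 2),
            frequency_hz = 0.05, amplitude = 1.2, amplitude_post = 1.2,
            amplitude_sd = 0.2, group_scope = "hc"))
}

# per-index generative parameters: normal (mean, sd) or lognormal
# (meanlog, sdlog), with physiologic lower truncation
default_clinical <- function() {
  list(age = list(hc = c(45.8, 8.5), pre = c(46.9, 9.1), min = 18, max = 60),
       education = list(hc = c(9.5, 2.0), pre = c(10.0, 2.0), min = 1),
       male_frac = list(hc = 25 / 32, pre = 21 / 27),
       nct_a_s = list(hc = c(43.7, 8.3), pre = c(76.6, 10.6),
                      post = c(51.1, 5.0), min = 10),
       dst_score = list(hc = c(47.7, 7.9), pre = c(33.4, 8.3),
                        post = c(43.3, 5.5), min = 0),
       prothrombin_time_s = list(pre = c(log(14.5), 0.25),
                                 post = c(log(12.4), 0.15), lognormal = TRUE),
       albumin = list(pre = c(33.3, 7.2), post = c(38.9, 4.2), min = 10),
       total_bilirubin = list(pre = c(log(33.8), 1.0),
                              post = c(log(13.1), 0.45), lognormal = TRUE),
       ammonia_umol_l = list(pre = c(145.6, 32.3), post = c(46.2, 10.4),
                             min = 5),
       child_pugh_probs = c(A = 2, B = 5, C = 20) / 27)
}

default_cohort <- function(n_hc = 32, n_patients = 27) {
  list(n_hc = as.integer(n_hc), n_patients = as.integer(n_patients),
       clinical = default_clinical())
}

validate_simulation_config <- function(cfg) {
  fail <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 4L))
    fail("grid_dims must be 3 integers >= 4")
  if (cfg$tr_s <= 0) fail("tr_s must be positive")
  if (cfg$n_volumes < 4L) fail("n_volumes must be >= 4")
  if (cfg$noise$ar1_coef < 0 || cfg$noise$ar1_coef >= 1)
    fail("noise ar1_coef must lie in [0, 1)")
  if (cfg$noise$sigma < 0) fail("noise sigma must be >= 0")
  if (cfg$smooth_fwhm_mm < 0) fail("smooth_fwhm_mm must be >= 0")
  nyq <- 1 / (2 * cfg$tr_s)
  for (s in cfg$planted_signals) {
    if (!(s$frequency_hz > 0 && s$frequency_hz < nyq))
      fail(sprintf("planted frequency %.4f Hz must lie strictly inside (0, %.4f)",
                   s$frequency_hz, nyq))
    if (s$amplitude < 0 || (!is.null(s$amplitude_post) && s$amplitude_post < 0))
      fail("planted amplitudes must be >= 0")
    if (!s$group_scope %in% c("hc", "patients", "all"))
      fail("group_scope must be hc, patients or all")
    if (any(s$roi$center - s$roi$half < 1) ||
        any(s$roi$center + s$roi$half > cfg$grid_dims))
      fail(sprintf("planted ROI box (center %s, half %d) exceeds the grid %s",
                   paste(s$roi$center, collapse = ","), s$roi$half,
                   paste(cfg$grid_dims, collapse = "x")))
  }
  for (l in cfg$delta_links) {
    if (abs(l$target_r) > 1) fail("target_r must lie in [-1, 1]")
    if (l$roi < 1 || l$roi > length(cfg$planted_signals))
      fail("delta link refers to a non-existent planted signal")
  }
  invisible(cfg)
}

# ellipsoidal "brain" mask inscribed in the grid
ellipsoid_mask <- function(dims, shrink = 0.92) {
  ctr <- (dims + 1) / 2
  semi <- shrink * (dims - 1) / 2
  ix <- slice.index(array(0, dims), 1)
  iy <- slice.index(array(0, dims), 2)
  iz <- slice.index(array(0, dims), 3)
  ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
    ((iz - ctr[3]) / semi[3])^2 <= 1
}

roi_indices <- function(roi, dims) {
  if (!identical(roi$shape, "box")) stop("only box ROIs are implemented")
  ctr <- roi$center; h <- roi$half
  rng <- lapply(1:3, function(d) max(1, ctr[d] - h):min(dims[d], ctr[d] + h))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  sort(g[, 1] + (g[, 2] - 1L) * dims[1] + (g[, 3] - 1L) * dims[1] * dims[2])
}

#' Generate clinical deltas with a planted correlation
#'
#' Constructs standard-scale deltas `y = r * z(x) + sqrt(1 - r^2) * eps`
#' with `z(x)` the standardized ROI deltas and `eps` fresh standard normal
#' noise, so the population correlation with `x` is `target_r` and the
#' sample correlation converges to it as n grows. At `|target_r| = 1` the
#' output is an exact affine function of `x`.
#'
#' @param roi_deltas per-patient metric deltas (length >= 3, non-constant).
#' @param clinical_index name carried through as an attribute.
#' @param target_r desired correlation in `[-1, 1]`.
#' @param seed RNG seed for the noise component.
#' @return numeric vector of standard-scale clinical deltas.
#' @export
plant_delta_correlation <- function(roi_deltas, clinical_index = "dst_score",
                                    target_r, seed = 1L) {
  n <- length(roi_deltas)
  if (n < 3L) stop("need at least 3 patients")
  if (abs(target_r) > 1) stop("target_r must lie in [-1, 1]")
  s <- stats::sd(roi_deltas)
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) roi_deltas")
  z <- (roi_deltas - mean(roi_deltas)) / s
  set.seed(seed)
  eps <- stats::rnorm(n)
  y <- target_r * z + sqrt(1 - target_r^2) * eps
  attr(y, "clinical_index") <- clinical_index
  y
}

rtrunc_norm <- function(n, mean, sd, min = -Inf, max = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, min), max)
}

# cohort-level draws: demographics, clinical scores, per-subject planted
# amplitudes and phases, per-session noise seeds
plan_cohort <- function(cfg) {
  set.seed(cfg$seed)
  ch <- cfg$cohort
  cl <- ch$clinical
  n_hc <- ch$n_hc; n_pat <- ch$n_patients
  hc_ids <- sprintf("hc%02d", seq_len(n_hc))
  pat_ids <- sprintf("pat%02d", seq_len(n_pat))

  # per-subject realized amplitudes for each planted signal
  sig_amp <- lapply(cfg$planted_signals, function(s) {
    sd_a <- if (is.null(s$amplitude_sd)) 0 else s$amplitude_sd
    a_post <- if (is.null(s$amplitude_post)) s$amplitude else s$amplitude_post
    pre <- pmax(0, s$amplitude + sd_a * stats::rnorm(n_hc + n_pat))
    delta <- (a_post - s$amplitude) + sd_a * stats::rnorm(n_hc + n_pat)
    list(pre = pre, post = pmax(0, pre + delta), delta = delta)
  })
  phases <- matrix(stats::runif((n_hc + 2 * n_pat) * length(cfg$planted_signals),
                                0, 2 * pi),
                   ncol = max(1L, length(cfg$planted_signals)))

  hc <- data.frame(id = hc_ids, group = "HC", session = "single",
                   age = round(rtrunc_norm(n_hc, cl$age$hc[1], cl$age$hc[2],
                                           cl$age$min, cl$age$max)),
                   sex = stats::rbinom(n_hc, 1, cl$male_frac$hc),
                   education = round(rtrunc_norm(n_hc, cl$education$hc[1],
                                                 cl$education$hc[2],
                                                 cl$education$min)),
                   nct_a_s = rtrunc_norm(n_hc, cl$nct_a_s$hc[1], cl$nct_a_s$hc[2],
                                         cl$nct_a_s$min),
                   dst_score = rtrunc_norm(n_hc, cl$dst_score$hc[1],
                                           cl$dst_score$hc[2], cl$dst_score$min),
                   prothrombin_time_s = NA_real_, albumin = NA_real_,
                   total_bilirubin = NA_real_, ammonia_umol_l = NA_real_,
                   child_pugh_points = NA_integer_, stringsAsFactors = FALSE)

  age_p <- round(rtrunc_norm(n_pat, cl$age$pre[1], cl$age$pre[2],
                             cl$age$min, cl$age$max))
  sex_p <- stats::rbinom(n_pat, 1, cl$male_frac$pre)
  edu_p <- round(rtrunc_norm(n_pat, cl$education$pre[1], cl$education$pre[2],
                             cl$education$min))
  cp_class <- sample(c("A", "B", "C"), n_pat, replace = TRUE,
                     prob = cl$child_pugh_probs)
  cp_points <- vapply(cp_class, function(k)
    switch(k, A = sample(5:6, 1), B = sample(7:9, 1), C = sample(10:15, 1)),
    integer(1))

  draw_idx <- function(par, n) {
    if (isTRUE(par$lognormal)) stats::rlnorm(n, par[[1]][1], par[[1]][2])
    else rtrunc_norm(n, par[[1]][1], par[[1]][2],
                     if (is.null(par$min)) -Inf else par$min)
  }
  pre_vals <- list(
    nct_a_s = rtrunc_norm(n_pat, cl$nct_a_s$pre[1], cl$nct_a_s$pre[2],
                          cl$nct_a_s$min),
    dst_score = rtrunc_norm(n_pat, cl$dst_score$pre[1], cl$dst_score$pre[2],
                            cl$dst_score$min),
    prothrombin_time_s = stats::rlnorm(n_pat, cl$prothrombin_time_s$pre[1],
                                       cl$prothrombin_time_s$pre[2]),
    albumin = rtrunc_norm(n_pat, cl$albumin$pre[1], cl$albumin$pre[2],
                          cl$albumin$min),
    total_bilirubin = stats::rlnorm(n_pat, cl$total_bilirubin$pre[1],
                                    cl$total_bilirubin$pre[2]),
    ammonia_umol_l = rtrunc_norm(n_pat, cl$ammonia_umol_l$pre[1],
                                 cl$ammonia_umol_l$pre[2], cl$ammonia_umol_l$min))
  post_vals <- list(
    nct_a_s = rtrunc_norm(n_pat, cl$nct_a_s$post[1], cl$nct_a_s$post[2],
                          cl$nct_a_s$min),
    dst_score = rtrunc_norm(n_pat, cl$dst_score$post[1], cl$dst_score$post[2],
                            cl$dst_score$min),
    prothrombin_time_s = stats::rlnorm(n_pat, cl$prothrombin_time_s$post[1],
                                       cl$prothrombin_time_s$post[2]),
    albumin = rtrunc_norm(n_pat, cl$albumin$post[1], cl$albumin$post[2],
                          cl$albumin$min),
    total_bilirubin = stats::rlnorm(n_pat, cl$total_bilirubin$post[1],
                                    cl$total_bilirubin$post[2]),
    ammonia_umol_l = rtrunc_norm(n_pat, cl$ammonia_umol_l$post[1],
                                 cl$ammonia_umol_l$post[2], cl$ammonia_umol_l$min))

  # planted delta-correlations override the linked index's post values:
  # the delta is generated with the target correlation against the signal's
  # per-patient amplitude change and added to the pre value
  planted_deltas <- list()
  pat_rows <- n_hc + seq_len(n_pat)
  for (l in cfg$delta_links) {
    amp_delta <- sig_amp[[l$roi]]$delta[pat_rows]
    std <- plant_delta_correlation(amp_delta, l$clinical_index, l$target_r,
                                   seed = sample.int(2^31 - 1, 1))
    par <- cl[[l$clinical_index]]
    if (isTRUE(par$lognormal)) {
      mu_d <- exp(par$post[1]) - exp(par$pre[1]); sd_d <- exp(par$post[1]) * par$post[2]
    } else {
      mu_d <- par$post[1] - par$pre[1]; sd_d <- par$post[2]
    }
    delta <- mu_d + sd_d * as.numeric(std)
    post_vals[[l$clinical_index]] <- pre_vals[[l$clinical_index]] + delta
    if (!is.null(par$min))
      post_vals[[l$clinical_index]] <- pmax(post_vals[[l$clinical_index]], par$min)
    planted_deltas[[length(planted_deltas) + 1L]] <-
      list(roi = l$roi, clinical_index = l$clinical_index,
           target_r = l$target_r, clinical_delta = delta,
           amplitude_delta = amp_delta)
  }

  mk_pat <- function(session, vals) {
    data.frame(id = pat_ids, group = "MHE", session = session,
               age = age_p, sex = sex_p, education = edu_p,
               nct_a_s = vals$nct_a_s, dst_score = vals$dst_score,
               prothrombin_time_s = vals$prothrombin_time_s,
               albumin = vals$albumin, total_bilirubin = vals$total_bilirubin,
               ammonia_umol_l = vals$ammonia_umol_l,
               child_pugh_points = cp_points, stringsAsFactors = FALSE)
  }
  subjects <- rbind(hc, mk_pat("pre", pre_vals), mk_pat("post", post_vals))
  rownames(subjects) <- NULL

  n_sessions <- n_hc + 2L * n_pat
  session_seeds <- sample.int(2^31 - 2, n_sessions)
  mask <- ellipsoid_mask(cfg$grid_dims)
  rois <- lapply(cfg$planted_signals, function(s) roi_indices(s$roi, cfg$grid_dims))
  list(config = cfg, subjects = subjects, sig_amp = sig_amp, phases = phases,
       session_seeds = session_seeds, mask = mask, rois = rois,
       planted_deltas = planted_deltas,
       hc_rows = seq_len(n_hc), pre_rows = n_hc + seq_len(n_pat),
       post_rows = n_hc + n_pat + seq_len(n_pat))
}

# one subject-session 4D series; `row` indexes plan$subjects
simulate_session <- function(plan, row) {
  cfg <- plan$config
  dims <- cfg$grid_dims; nt <- cfg$n_volumes
  set.seed(plan$session_seeds[row])
  nvox <- prod(dims)
  vals <- array(cfg$baseline, c(dims, nt))
  if (cfg$noise$sigma > 0) {
    phi <- cfg$noise$ar1_coef
    innov_sd <- cfg$noise$sigma * sqrt(1 - phi^2)
    e <- matrix(stats::rnorm(nt * nvox, sd = innov_sd), nrow = nvox)
    if (phi > 0) {
      e[, 1] <- e[, 1] / sqrt(1 - phi^2)      # exact stationary start
      for (tp in 2:nt) e[, tp] <- e[, tp] + phi * e[, tp - 1L]
    }
    noise <- array(e, c(dims, nt))
    if (cfg$smooth_fwhm_mm > 0)
      noise <- smooth_gaussian(noise, cfg$smooth_fwhm_mm,
                               voxel_size_mm = cfg$voxel_size_mm)
    vals <- vals + noise
  }
  subj <- plan$subjects[row, ]
  # which amplitude applies to this subject-session
  for (si in seq_along(cfg$planted_signals)) {
    s <- cfg$planted_signals[[si]]
    applies <- switch(s$group_scope,
                      hc = subj$group == "HC",
                      patients = subj$group == "MHE",
                      all = TRUE)
    if (!applies) next
    amp <- if (subj$session == "post") plan$sig_amp[[si]]$post[subj_index(plan, row)]
           else plan$sig_amp[[si]]$pre[subj_index(plan, row)]
    if (amp <= 0) next
    ph <- plan$phases[row, si]
    wave <- amp * sin(2 * pi * s$frequency_hz * (seq_len(nt) - 1) * cfg$tr_s + ph)
    roi <- plan$rois[[si]]
    lin <- outer(roi, (seq_len(nt) - 1L) * nvox, "+")
    vals[lin] <- vals[lin] + rep(wave, each = length(roi))
  }
  bold_series(vals, voxel_size_mm = cfg$voxel_size_mm, tr_s = cfg$tr_s,
              mask = plan$mask, subject_id = subj$id, session = subj$session)
}

# map a subjects-table row to the per-subject amplitude index (patients
# share one index across their pre/post rows)
subj_index <- function(plan, row) {
  n_hc <- plan$config$cohort$n_hc
  n_pat <- plan$config$cohort$n_patients
  if (row <= n_hc + n_pat) row else row - n_pat
}

#' Simulate a full cohort
#'
#' One [bold_series] per subject-session (controls: one session; patients:
#' pre and post), the subjects table, and a ground-truth sidecar recording
#' every planted effect for recovery tests. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `series` (list of [bold_series]), `subjects`
#'   (data.frame), `truth` (list: ROI indices, per-subject amplitudes,
#'   planted clinical deltas, mask, seeds).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  plan <- plan_cohort(config)
  series <- lapply(seq_len(nrow(plan$subjects)), function(i)
    simulate_session(plan, i))
  list(series = series, subjects = plan$subjects, truth = cohort_truth(plan))
}

cohort_truth <- function(plan) {
  list(seed = plan$config$seed,
       rois = plan$rois,
       mask_voxels = sum(plan$mask),
       signals = lapply(seq_along(plan$config$planted_signals), function(si)
         list(spec = plan$config$planted_signals[[si]],
              amplitude_pre = plan$sig_amp[[si]]$pre,
              amplitude_post = plan$sig_amp[[si]]$post,
              amplitude_delta = plan$sig_amp[[si]]$delta)),
       planted_deltas = plan$planted_deltas,
       session_seeds = plan$session_seeds)
}

#' Write a simulated cohort to disk
#'
#' One gzipped NIfTI per subject-session, a UTF-8 TSV subjects table and a
#' JSON ground-truth sidecar.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @param dtype NIfTI storage type (default float32 to halve disk use).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, dtype = "float32") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$series)
    write_nifti(s, file.path(dir, sprintf("%s_%s.nii.gz", s$subject_id,
                                          s$session)), dtype = dtype)
  utils::write.table(sim$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mask_map <- voxel_map(array(as.numeric(sim$series[[1]]$mask),
                              dim(sim$series[[1]]$mask)),
                        voxel_size_mm = sim$series[[1]]$voxel_size_mm,
                        affine = sim$series[[1]]$affine)
  write_nifti(mask_map, file.path(dir, "mask.nii.gz"), dtype = "float32")
  invisible(dir)
}
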