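# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's own code paths.

# direct projection of a signal onto sin/cos at each one-sided DFT bin;
# brute-force alternative to the FFT-based amplitude spectrum
oracle_spectrum <- function(x, tr_s) {
  n <- length(x)
  half <- floor(n / 2)
  tt <- seq_len(n) - 1
  amps <- vapply(0:half, function(k) {
    c_ <- sum(x * cos(2 * pi * k * tt / n))
    s_ <- sum(x * sin(2 * pi * k * tt / n))
    a <- sqrt(c_^2 + s_^2)
    if (k == 0 || (n %% 2 == 0 && k == half)) a / n else 2 * a / n
  }, numeric(1))
  list(frequencies_hz = (0:half) / (n * tr_s), amplitudes = amps)
}

# brute-force band ALFF: enumerate bins, closed band, mean over bins
oracle_alff <- function(x, tr_s, f_low, f_high) {
  sp <- oracle_spectrum(x, tr_s)
  keep <- sp$frequencies_hz >= f_low & sp$frequencies_hz <= f_high &
    sp$frequencies_hz > 0
  mean(sp$amplitudes[keep])
}

# textbook pooled-variance two-sample t
oracle_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# min-label propagation connected components (independent of the BFS in
# the package); returns a canonical sorted list of sorted index vectors
oracle_components <- function(supra, connectivity) {
  dims <- dim(supra)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(connectivity),
                      "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3), ]
  lab <- array(Inf, dims)
  lab[supra] <- seq_len(sum(supra))
  shift_arr <- function(a, dx, dy, dz) {
    out <- array(Inf, dims)
    xs <- max(1, 1 + dx):min(dims[1], dims[1] + dx)
    ys <- max(1, 1 + dy):min(dims[2], dims[2] + dy)
    zs <- max(1, 1 + dz):min(dims[3], dims[3] + dz)
    out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
    out
  }
  repeat {
    new_lab <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- shift_arr(lab, offs$dx[r], offs$dy[r], offs$dz[r])
      new_lab <- pmin(new_lab, sh)
    }
    new_lab[!supra] <- Inf
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  ids <- unique(lab[supra])
  comps <- lapply(sort(ids), function(i) sort(which(lab == i & supra)))
  comps[order(vapply(comps, `[`, numeric(1), 1))]
}

canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, numeric(1), 1))]
}

# quick builders -------------------------------------------------------

sinusoid_series <- function(freq_hz, amp = 1, n = 176, tr = 2.17, phase = 0,
                            dims = c(4, 4, 3)) {
  tt <- (seq_len(n) - 1) * tr
  wave <- amp * sin(2 * pi * freq_hz * tt + phase)
  arr <- array(rep(wave, each = prod(dims)), c(dims, n))
  bold_series(arr, voxel_size_mm = 3, tr_s = tr)
}

noise_series <- function(seed, n = 176, tr = 2.17, dims = c(4, 4, 3), sd = 1) {
  set.seed(seed)
  bold_series(array(rnorm(prod(dims) * n, sd = sd), c(dims, n)),
              voxel_size_mm = 3, tr_s = tr)
}

random_maps <- function(n, dims = c(8, 8, 6), seed = 1, smooth_mm = 0) {
  set.seed(seed)
  arr <- array(rnorm(prod(dims) * n), c(dims, n))
  if (smooth_mm > 0) arr <- smooth_gaussian(arr, smooth_mm, voxel_size_mm = 3)
  lapply(seq_len(n), function(i) voxel_map(arr[, , , i], voxel_size_mm = 3))
}

# the scaled-down stated-world config used by the end-to-end tests: one
# planted longitudinal amplitude change and one planted delta-correlation,
# on a grid small enough for repeated runs (documented in the vignette)
recovery_sim_config <- function(seed) {
  simulation_config(
    grid_dims = c(16, 16, 12),
    planted_signals = list(
      list(roi = list(shape = "box", center = c(8, 8, 7), half = 2),
           frequency_hz = 0.04, amplitude = 1, amplitude_post = 1.6,
           amplitude_sd = 0.25, group_scope = "patients")),
    delta_links = list(list(roi = 1, clinical_index = "dst_score",
                            target_r = 0.8)),
    seed = seed)
}

dice <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))
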