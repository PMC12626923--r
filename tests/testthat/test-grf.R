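test_that("resel counts match the closed form on cuboid masks", {
  mask <- array(TRUE, c(6, 5, 4))
  f <- c(2, 2, 2)
  r <- resel_counts(mask, f)
  # cuboid closed form: counts of vertices/edges/faces/cubes of the lattice
  a <- 6; b <- 5; c_ <- 4
  expect_equal(unname(r[1]), 1)                                   # EC
  expect_equal(unname(r[2]), ((a - 1) + (b - 1) + (c_ - 1)) / 2)
  expect_equal(unname(r[3]),
               ((a - 1) * (b - 1) + (a - 1) * (c_ - 1) + (b - 1) * (c_ - 1)) / 4)
  expect_equal(unname(r[4]), (a - 1) * (b - 1) * (c_ - 1) / 8)
  # a disconnected mask has EC = number of components
  m2 <- array(FALSE, c(7, 3, 3)); m2[1:2, , ] <- TRUE; m2[6:7, , ] <- TRUE
  expect_equal(unname(resel_counts(m2, f)[1]), 2)
  expect_error(resel_counts(mask, c(0, 2, 2)), "positive")
})

test_that("smoothness estimate scales with voxel size and with smoothing", {
  dims <- c(16, 16, 12); mask <- array(TRUE, dims)
  set.seed(41)
  n <- 12
  raw <- array(rnorm(prod(dims) * n), c(dims, n))
  sm <- smooth_gaussian(raw, 6, voxel_size_mm = 3)
  R_raw <- sweep(t(matrix(raw, ncol = n)), 2, colMeans(t(matrix(raw, ncol = n))))
  R_sm <- sweep(t(matrix(sm, ncol = n)), 2, colMeans(t(matrix(sm, ncol = n))))
  e_raw <- estimate_smoothness(R_raw, mask, 3, df = n - 1)
  e_sm <- estimate_smoothness(R_sm, mask, 3, df = n - 1)
  expect_true(all(e_sm$fwhm_mm > e_raw$fwhm_mm))      # ordering
  expect_true(all(e_raw$fwhm_mm < 6))                  # near voxel scale
  # doubling voxel size doubles FWHM in mm for the same lattice data
  e2 <- estimate_smoothness(R_sm, mask, 6, df = n - 1)
  expect_equal(e2$fwhm_mm, 2 * e_sm$fwhm_mm, tolerance = 1e-12)
  expect_error(estimate_smoothness(R_sm * 0, mask, 3, df = n - 1), "zero")
  expect_error(estimate_smoothness(R_sm, mask, 3, df = 0), "df")
})

test_that("cluster labeling handles the canonical connectivity cases", {
  dims <- c(8, 8, 8)
  z <- array(0, dims)
  z[2, 2, 2] <- 5; z[3, 3, 3] <- 5        # corner touch
  zm <- voxel_map(z, kind = "zstat")
  expect_length(label_clusters(zm, 0.001, "+", connectivity = 26), 1)
  expect_length(label_clusters(zm, 0.001, "+", connectivity = 6), 2)
  expect_length(label_clusters(zm, 0.001, "-"), 0)
  z2 <- array(0, dims); z2[2:6, 2:6, 2:6] <- 4
  cl <- label_clusters(voxel_map(z2, kind = "zstat"), 0.001, "+")
  expect_length(cl, 1)
  expect_length(cl[[1]], 125)
  expect_length(label_clusters(voxel_map(array(0, dims), kind = "zstat"),
                               0.001, "+"), 0)
  expect_error(label_clusters(zm, 1.5, "+"), "voxel_p")
})

test_that("cluster labeling agrees with the brute-force oracle", {
  # smaller sweep here; the acceptance suite runs the full 100-map version
  set.seed(42)
  for (rep in 1:15) {
    supra <- array(runif(10^3) < 0.25, c(10, 10, 10))
    zm <- voxel_map(array(ifelse(supra, 6, 0), c(10, 10, 10)), kind = "zstat")
    for (conn in c(6, 18, 26)) {
      got <- canon_components(label_clusters(zm, 0.001, "+", connectivity = conn))
      want <- oracle_components(supra, conn)
      expect_identical(got, want)
    }
  }
})

test_that("corrected cluster p is monotone in extent and smoothness", {
  mask <- array(TRUE, c(20, 20, 16))
  mk_sm <- function(fwhm_vox) structure(
    list(fwhm_mm = fwhm_vox * 3, fwhm_vox = rep(fwhm_vox, 3),
         resels = resel_counts(mask, rep(fwhm_vox, 3)), df = 30),
    class = "smoothness_estimate")
  sm2 <- mk_sm(2)
  p_k <- vapply(c(1, 5, 10, 20, 50, 100), cluster_p_grf, numeric(1),
                smoothness = sm2, z_threshold = 3.09,
                mask_volume_voxels = sum(mask))
  expect_true(all(diff(p_k) <= 0))
  expect_true(all(p_k > 0 & p_k <= 1))
  # at fixed extent, a smoother field makes the same cluster less surprising
  p_smooth <- vapply(c(1.5, 2, 3, 4), function(f)
    cluster_p_grf(20, mk_sm(f), 3.09, sum(mask)), numeric(1))
  expect_true(all(diff(p_smooth) >= 0))
  expect_error(cluster_p_grf(0, sm2, 3.09, 100), "cluster_size")
  expect_error(cluster_p_grf(5, sm2, -1, 100), "positive")
})

test_that("make_cluster_table reports peaks, coordinates and atlas labels", {
  dims <- c(12, 12, 10)
  mask <- array(TRUE, dims)
  set.seed(43)
  n <- 16
  arr <- array(rnorm(prod(dims) * n, sd = 0.5), c(dims, n))
  arr[4:6, 4:6, 4:6, 1:8] <- arr[4:6, 4:6, 4:6, 1:8] + 3   # strong block in group A
  maps <- lapply(seq_len(n), function(i) voxel_map(arr[, , , i], voxel_size_mm = 3))
  tr <- two_sample_t(maps[1:8], maps[9:16])
  sm <- estimate_smoothness(tr$residuals, tr$mask, 3, tr$df)
  atlas <- voxel_map(array(0, dims), voxel_size_mm = 3)
  atlas$values[4:6, 4:6, 4:6] <- 7
  labels <- data.frame(id = 7, name = "planted_block")
  tab <- suppressMessages(make_cluster_table(tr, sm, voxel_p = 0.001,
                                             atlas = atlas, atlas_labels = labels))
  expect_gt(nrow(tab), 0)
  top <- tab[1, ]
  expect_identical(top$metric_sign, "+")
  expect_identical(top$region_label, "planted_block")
  expect_true(top$significant)
  # peak coordinate equals affine * 0-based index
  aff <- maps[[1]]$affine
  ijk <- arrayInd(top$peak_index, dims) - 1L
  expect_equal(c(top$mni_x, top$mni_y, top$mni_z),
               drop(aff %*% c(ijk, 1))[1:3])
  # the peak lies inside the planted block
  expect_true(all(arrayInd(top$peak_index, dims) >= 4 &
                  arrayInd(top$peak_index, dims) <= 6))
  # null map -> empty table
  null_tr <- two_sample_t(random_maps(8, dims = dims, seed = 44),
                          random_maps(8, dims = dims, seed = 45))
  sm0 <- estimate_smoothness(null_tr$residuals, null_tr$mask, 3, null_tr$df)
  tab0 <- suppressMessages(make_cluster_table(null_tr, sm0, voxel_p = 1e-8))
  expect_equal(nrow(tab0), 0)
})
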