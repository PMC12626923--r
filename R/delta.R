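# Longitudinal delta analysis: ROI extraction from suprathreshold cluster
# masks, post-minus-pre differences, Pearson correlation of metric deltas
# against clinical-index deltas with Bonferroni correction, plus the
# clinical scoring utilities (Child-Pugh classing, 2-SD psychometric
# impairment rule).

#' Mean of a map over a region of interest
#'
#' @param map a [voxel_map].
#' @param roi_mask logical 3D array or integer vector of linear voxel
#'   indices; must be non-empty and lie within the map's mask.
#' @return scalar arithmetic mean.
#' @export
extract_roi_mean <- function(map, roi_mask) {
  stopifnot(inherits(map, "voxel_map"))
  idx <- if (is.logical(roi_mask)) which(roi_mask) else as.integer(roi_mask)
  if (length(idx) == 0L) stop("empty ROI")
  if (!all(map$mask[idx])) stop("ROI extends outside the analysis mask")
  mean(map$values[idx])
}

#' Pearson correlation with two-sided p
#'
#' `p` is obtained from `t = r * sqrt((n-2)/(1-r^2))` against Student-t with
#' `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors, length >= 3, both non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE), n = n)
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m size of the test family (`>= length(p_values)` not required when
#'   the family is defined per index; `m >= 1`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m) {
  if (m < 1) stop("m must be >= 1")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  pmin(1, m * p_values)
}

#' Child-Pugh class from points
#'
#' Class A for 5-6 points, B for 7-9, C for 10-15.
#'
#' @param points integer vector in 5..15.
#' @return character vector of "A"/"B"/"C".
#' @export
child_pugh_class <- function(points) {
  points <- as.integer(points)
  if (any(points < 5L | points > 15L, na.rm = TRUE))
    stop("Child-Pugh points must lie in 5..15")
  ifelse(points <= 6L, "A", ifelse(points <= 9L, "B", "C"))
}

#' Flag minimal hepatic encephalopathy by the 2-SD rule
#'
#' A subject is flagged when performance deviates by more than 2 SD from the
#' healthy-control normative mean toward impairment on at least one test:
#' Number Connection Test A time above `mean + 2*SD` (slower is worse) or
#' Digit Symbol Test score below `mean - 2*SD` (lower is worse).
#'
#' @param nct_a_s subject's NCT-A completion time (seconds).
#' @param dst_score subject's DST score (points).
#' @param hc_norms list with `nct_a = c(mean, sd)` and `dst = c(mean, sd)`
#'   from the healthy-control group; SDs must be positive.
#' @return logical.
#' @export
flag_mhe <- function(nct_a_s, dst_score, hc_norms) {
  if (is.null(hc_norms$nct_a) || is.null(hc_norms$dst))
    stop("hc_norms must provide nct_a and dst as c(mean, sd)")
  if (hc_norms$nct_a[2] <= 0 || hc_norms$dst[2] <= 0)
    stop("normative SDs must be positive")
  if (any(is.na(c(nct_a_s, dst_score)))) stop("missing test values")
  (nct_a_s > hc_norms$nct_a[1] + 2 * hc_norms$nct_a[2]) |
    (dst_score < hc_norms$dst[1] - 2 * hc_norms$dst[2])
}

CLINICAL_DELTA_INDICES <- c("nct_a_s", "dst_score", "prothrombin_time_s",
                            "albumin", "total_bilirubin", "ammonia_umol_l")

#' Longitudinal delta-correlation analysis
#'
#' For each ROI (a suprathreshold cluster mask from the paired contrast) the
#' per-patient metric delta (post - pre ROI mean) is correlated against each
#' clinical-index delta; p-values are Bonferroni-adjusted with family size
#' `m_tests` applied per clinical index (the number of contributing ROIs by
#' default; pass `m_tests = length(rois) * 6` for the conservative
#' whole-table family).
#'
#' @param pre_maps,post_maps lists of [voxel_map]s, same patients, same
#'   order.
#' @param cluster_rois named list of ROI masks (logical arrays or index
#'   vectors).
#' @param subjects_pre,subjects_post data.frames with one row per patient
#'   (matching order and `id`) carrying the columns named in
#'   `CLINICAL_DELTA_INDICES`.
#' @param m_tests Bonferroni family size; default `length(cluster_rois)`.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame with columns `roi, index, r, p, p_adjusted,
#'   significant`, ROIs varying fastest (full cross).
#' @export
run_delta_analysis <- function(pre_maps, post_maps, cluster_rois,
                               subjects_pre, subjects_post,
                               m_tests = length(cluster_rois), alpha = 0.05) {
  if (length(pre_maps) != length(post_maps))
    stop("session mismatch: pre and post map lists differ in length")
  if (!identical(subjects_pre$id, subjects_post$id))
    stop("session mismatch: subject ids differ between sessions")
  if (length(cluster_rois) == 0L) stop("no ROIs supplied")
  n <- length(pre_maps)
  roi_names <- names(cluster_rois)
  if (is.null(roi_names)) roi_names <- paste0("roi_", seq_along(cluster_rois))
  d_metric <- sapply(cluster_rois, function(roi)
    vapply(seq_len(n), function(i)
      extract_roi_mean(post_maps[[i]], roi) - extract_roi_mean(pre_maps[[i]], roi),
      numeric(1)))
  d_metric <- matrix(d_metric, nrow = n)
  idxs <- intersect(CLINICAL_DELTA_INDICES, colnames(subjects_pre))
  if (length(idxs) == 0L) stop("no clinical index columns found")
  rows <- list()
  for (ci in idxs) {
    d_clin <- as.numeric(subjects_post[[ci]]) - as.numeric(subjects_pre[[ci]])
    for (ri in seq_along(cluster_rois)) {
      pr <- tryCatch(pearson_r(d_metric[, ri], d_clin),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi_names[ri], index = ci, r = pr$r, p = pr$p,
        note = if (is.null(pr$error)) "" else pr$error,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- bonferroni(tab$p, m_tests)
  tab$significant <- !is.na(tab$p_adjusted) & tab$p_adjusted < alpha
  tab
}
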