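# Voxelwise general linear model: covariate-adjusted two-sample contrasts
# and paired (one-sample-on-differences) contrasts, fitted by ordinary
# least squares simultaneously at every in-mask voxel. Residual maps are
# retained for random-field smoothness estimation.

# stack a list of voxel_maps into an n x V matrix over a common mask
stack_maps <- function(maps, mask) {
  do.call(rbind, lapply(maps, function(m) m$values[mask]))
}

common_mask <- function(maps) {
  mask <- maps[[1]]$mask
  for (m in maps[-1]) {
    if (!identical(dim(m$mask), dim(mask))) stop("mismatched map masks")
    mask <- mask & m$mask
  }
  mask
}

fit_glm_voxelwise <- function(Y, X, contrast_vec) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("rank-deficient design matrix")
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast_vec) %*% XtXinv %*% contrast_vec)
  est <- drop(t(contrast_vec) %*% beta)
  se <- sqrt(sigma2 * cvar)
  tval <- ifelse(se > 0, est / se, sign(est) * Inf)
  tval[se == 0 & est == 0] <- 0
  list(t = tval, res = res, df = df)
}

new_tstat_result <- function(tvals, res, df, mask, template, contrast,
                             dropped = 0L) {
  # zero-variance shifts give t -> infinity (possibly a huge finite value
  # through rounding); censor them to a fixed reported maximum
  cens <- !is.finite(tvals) | abs(tvals) > 1e7
  tvals[cens] <- sign(tvals[cens]) * 1e6
  tm <- array(0, dim(template$values))
  tm[mask] <- tvals
  t_map <- voxel_map(tm, mask = mask, kind = "tstat",
                     voxel_size_mm = template$voxel_size_mm,
                     affine = template$affine,
                     meta = list(df = df, contrast = contrast))
  structure(list(t_map = t_map, df = df, residuals = res, mask = mask,
                 contrast = contrast, n_censored = sum(cens),
                 n_zero_variance_dropped = dropped),
            class = "tstat_result")
}

#' Voxelwise two-sample t contrast with covariates
#'
#' Fits, at every voxel, `value ~ intercept + group + covariates` by OLS and
#' returns the t statistic for the group coefficient; positive t means group
#' A > group B. Covariates are mean-centered so the contrast is evaluated at
#' covariate means. Voxels whose values have zero variance across all
#' subjects are dropped from the analysis mask (count reported in the
#' result).
#'
#' @param maps_a,maps_b lists of [voxel_map]s (>= 2 each) on a common grid.
#' @param covariates optional data.frame with one row per map, rows of
#'   `maps_a` first; all columns are used as numeric covariates (e.g. age,
#'   sex coded 0/1, education).
#' @param contrast_name label stored in the result.
#' @return a `tstat_result`: `t_map` (kind `"tstat"`), `df`, per-subject
#'   residuals, the analysis mask.
#' @export
two_sample_t <- function(maps_a, maps_b, covariates = NULL,
                         contrast_name = "A_gt_B") {
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need at least 2 maps per group")
  maps <- c(maps_a, maps_b)
  n <- length(maps)
  if (!is.null(covariates) && nrow(covariates) != n)
    stop("covariate rows must align with the maps (group A rows first)")
  mask <- common_mask(maps)
  Y <- stack_maps(maps, mask)
  keep <- matrixStats_colSds(Y) > 0
  dropped <- sum(!keep)
  if (dropped > 0) {
    mask[mask] <- keep
    Y <- Y[, keep, drop = FALSE]
  }
  g <- c(rep(1, length(maps_a)), rep(0, length(maps_b)))
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    C <- as.matrix(data.frame(lapply(covariates, as.numeric)))
    C <- sweep(C, 2, colMeans(C))
    constant <- apply(C, 2, function(x) all(x == 0))
    if (any(constant))
      message("dropping constant covariate(s): ",
              paste(colnames(C)[constant], collapse = ", "))
    X <- cbind(X, C[, !constant, drop = FALSE])
  }
  fit <- fit_glm_voxelwise(Y, X, c(0, 1, rep(0, ncol(X) - 2)))
  new_tstat_result(fit$t, fit$res, fit$df, mask, maps[[1]], contrast_name,
                   dropped)
}

# population-free column SDs without extra deps
matrixStats_colSds <- function(Y) {
  n <- nrow(Y)
  sqrt(pmax(colSums(Y^2) / n - colMeans(Y)^2, 0))
}

#' Voxelwise paired t contrast
#'
#' Computed as a one-sample t on per-subject difference maps (post - pre);
#' positive t means post > pre; `df = n - 1`. Voxels with a zero-variance
#' non-zero shift are censored to a large finite value and counted in
#' `n_censored`. Covariates that are constant within subject cancel in the
#' differences and are not entered by default; pass `covariates` to adjust
#' the differences anyway.
#'
#' @param maps_pre,maps_post lists of [voxel_map]s, same subjects in the same
#'   order (>= 2 pairs).
#' @param covariates optional data.frame, one row per subject.
#' @param contrast_name label stored in the result.
#' @return a `tstat_result`.
#' @export
paired_t <- function(maps_pre, maps_post, covariates = NULL,
                     contrast_name = "post_gt_pre") {
  if (length(maps_pre) != length(maps_post))
    stop("unpaired lengths: pre and post lists differ")
  n <- length(maps_pre)
  if (n < 2L) stop("need at least 2 pairs")
  mask <- common_mask(c(maps_pre, maps_post))
  D <- stack_maps(maps_post, mask) - stack_maps(maps_pre, mask)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    if (nrow(covariates) != n) stop("covariate rows must match the pairs")
    C <- as.matrix(data.frame(lapply(covariates, as.numeric)))
    C <- sweep(C, 2, colMeans(C))
    X <- cbind(X, C)
  }
  fit <- fit_glm_voxelwise(D, X, c(1, rep(0, ncol(X) - 1)))
  new_tstat_result(fit$t, fit$res, fit$df, mask, maps_pre[[1]], contrast_name)
}

#' Convert a t map to a Gaussianized z map
#'
#' `z = qnorm(pt(t, df))` evaluated tail-stably with two-sided symmetry
#' preserved (`sign(z) = sign(t)`); random-field cluster inference operates
#' on the z field.
#'
#' @param t_result a `tstat_result` (or a [voxel_map] of kind `"tstat"` plus
#'   `df`).
#' @param df degrees of freedom, taken from `t_result` when available.
#' @return a [voxel_map] of kind `"zstat"`.
#' @export
t_to_z <- function(t_result, df = NULL) {
  if (inherits(t_result, "tstat_result")) {
    tm <- t_result$t_map; df <- t_result$df
  } else {
    tm <- t_result
    if (is.null(df)) stop("df required when passing a bare map")
  }
  if (df < 1) stop("df must be >= 1")
  tv <- tm$values[tm$mask]
  a <- abs(tv)
  z <- -stats::qnorm(stats::pt(a, df, lower.tail = FALSE, log.p = TRUE),
                     log.p = TRUE)
  z[!is.finite(z)] <- 40          # censored beyond double-precision tails
  z <- pmin(z, 40) * sign(tv)
  out <- tm
  out$values[tm$mask] <- z
  out$kind <- "zstat"
  out$meta$df <- df
  out
}
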