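#' Pixel-wise T2 mapping by log-linear fitting
#'
#' Fits `log S(TE) = log S0 - TE/T2` per voxel by ordinary least squares over
#' the echo times. Voxels with any nonpositive echo are flagged invalid (the
#' logarithm is undefined and offsetting would bias T2), as are voxels whose
#' fitted slope is nonnegative (T2 undefined).
#'
#' @param echoes a magnitude `multiecho_volume` with >= 2 distinct echo times.
#' @return a `t2_map_result`: `t2_ms`, `s0`, `r2` (coefficient of
#'   determination of the log-linear fit), `valid` mask.
#' @export
fit_t2_map <- function(echoes) {
  stopifnot(inherits(echoes, "multiecho_volume"))
  te <- echoes$te_ms
  if (length(te) < 2L || anyDuplicated(te)) stopf("need >= 2 distinct echo times")
  dm <- dim(echoes$data)
  ne <- dm[4]
  S <- matrix(echoes$data, ncol = ne)        # voxels x echoes
  valid <- rowSums(S > 0) == ne
  Y <- log(pmax(S, .Machine$double.xmin))
  tec <- te - mean(te)
  sxx <- sum(tec^2)
  slope <- as.vector(Y %*% tec) / sxx
  intercept <- rowMeans(Y) - slope * mean(te)
  fitted_rss <- rowSums((Y - outer(intercept, rep(1, ne)) -
                           outer(slope, te))^2)
  tss <- rowSums((Y - rowMeans(Y))^2)
  r2 <- ifelse(tss > 0, 1 - fitted_rss / tss, NA_real_)
  valid <- valid & is.finite(slope) & slope < 0
  t2 <- ifelse(valid, -1 / slope, NA_real_)
  s0 <- ifelse(valid, exp(intercept), NA_real_)
  if (!any(valid)) stopf("no voxel produced a valid T2 fit")
  dm3 <- dm[1:3]
  structure(list(t2_ms = array(t2, dm3), s0 = array(s0, dm3),
                 r2 = array(r2, dm3), valid = array(valid, dm3),
                 te_ms = te),
            class = "t2_map_result")
}

#' ROI-mean T2 over the largest slices
#'
#' Mean of valid T2 voxels inside the ROI, restricted to the `n_slices`
#' slices with the largest ROI cross sections.
#'
#' @param t2map a [fit_t2_map()] result.
#' @param roi logical 3D array (e.g. the posterior-muscle label mask).
#' @param n_slices number of largest slices averaged (3 by convention).
#' @return mean T2, ms.
#' @export
roi_mean_t2 <- function(t2map, roi, n_slices = 3L) {
  stopifnot(inherits(t2map, "t2_map_result"))
  if (!any(roi)) stopf("empty ROI")
  sl <- largest_slices(roi, n_slices)
  keep <- array(FALSE, dim(roi)); keep[, , sl] <- TRUE
  m <- roi & keep & t2map$valid
  if (!any(m)) stopf("no valid T2 voxels in ROI on the selected slices")
  mean(t2map$t2_ms[m])
}
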