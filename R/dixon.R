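#' Three-point Dixon water/fat separation
#'
#' Algebraic separation from an in/opposed/in echo triplet. The field-offset
#' phase accrued between consecutive echoes is estimated per voxel from the
#' two in-phase echoes, `phi = Arg(Conj(S1) * S3) / 2` (assumed within
#' (-pi/2, pi/2]; no spatial unwrapping), the opposed echo is demodulated by
#' that phase plus the first-echo phase, and
#' `W = (|S1| + S2c) / 2`, `F = (|S1| - S2c) / 2` with `S2c` the
#' phase-corrected opposed-echo real part.
#'
#' The raw `water`/`fat` maps keep noise-driven negative values (so that ROI
#' means stay unbiased); `fat_fraction` is clamped to `[0, 1]` and the number
#' of clamped voxels is reported.
#'
#' @param echoes a Dixon `multiecho_volume` (3 complex echoes with phase
#'   labels `in`, `opposed`, `in`).
#' @return a `fat_water_result`: `water`, `fat`, `fat_fraction` (clamped),
#'   `field_phase` (rad between consecutive echoes), `mask` (nonzero signal),
#'   `n_clamped`.
#' @export
separate_fat_water <- function(echoes) {
  stopifnot(inherits(echoes, "multiecho_volume"))
  if (is.null(echoes$phase_labels)) stopf("echo phase metadata (in/opposed) missing")
  if (dim(echoes$data)[4] != 3L) stopf("3-point Dixon requires exactly 3 echoes")
  if (!identical(echoes$phase_labels, c("in", "opposed", "in")))
    stopf("unsupported phase scheme: %s", paste(echoes$phase_labels, collapse = ","))
  s1 <- echoes$data[, , , 1]; s2 <- echoes$data[, , , 2]; s3 <- echoes$data[, , , 3]
  phi <- Arg(Conj(s1) * s3) / 2
  s2c <- Re(s2 * exp(-1i * (phi + Arg(s1))))
  a1 <- Mod(s1)
  W <- (a1 + s2c) / 2
  Fa <- (a1 - s2c) / 2
  tot <- W + Fa
  ff <- ifelse(tot > 0, Fa / tot, NA_real_)
  n_clamped <- sum(ff < 0 | ff > 1, na.rm = TRUE)
  ff <- pmin(pmax(ff, 0), 1)
  structure(list(water = W, fat = Fa, fat_fraction = array(ff, dim(W)),
                 field_phase = phi, mask = a1 > 0, n_clamped = n_clamped),
            class = "fat_water_result")
}

#' Intramuscular fat percentage over a region of interest
#'
#' Mean over the masked voxels of `100 * F / (F + W)` per voxel, restricted to
#' the `n_slices` slices on which the mask has the largest cross sections.
#' Raw (unclamped) water/fat values are used so that zero-mean noise does not
#' bias the average.
#'
#' @param result a [separate_fat_water()] result.
#' @param mask logical 3D array selecting muscle voxels.
#' @param n_slices how many of the largest-mask slices to average over.
#' @return percentage (scalar).
#' @export
fat_percentage <- function(result, mask, n_slices = 4L) {
  stopifnot(inherits(result, "fat_water_result"))
  if (!any(mask)) stopf("empty mask")
  sl <- largest_slices(mask, n_slices)
  keep <- array(FALSE, dim(mask)); keep[, , sl] <- TRUE
  m <- mask & keep
  W <- result$water[m]; Fa <- result$fat[m]
  tot <- W + Fa
  ok <- is.finite(tot) & tot > 0
  if (!any(ok)) stopf("no voxels with positive total signal in mask")
  mean(100 * Fa[ok] / tot[ok])
}

#' Muscle cross-sectional areas and hindlimb volume from a water image
#'
#' The muscle is segmented by thresholding the water image at a configurable
#' fraction of the median bright-voxel intensity and keeping the 6-connected
#' components that are at least `min_component_frac` of the largest one (the
#' hindlimb comprises several muscle bellies, so more than one substantial
#' component is anatomical; isolated noise voxels are discarded). CSA per
#' slice is the voxel count times the in-plane voxel area; the maximal CSA is
#' taken over slices, and the volume is the sum of the `n_slices` consecutive
#' largest CSAs times the slice thickness.
#'
#' @param water numeric 3D water image.
#' @param voxel_dims_mm voxel dimensions `(dx, dy, dz)`, mm.
#' @param n_slices number of consecutive slices summed into the volume.
#' @param threshold_frac segmentation threshold as a fraction of the median
#'   intensity of bright voxels (those above 25% of the maximum).
#' @param min_component_frac keep connected components whose voxel count is
#'   at least this fraction of the largest component's.
#' @return an `anatomy_result`: `csa_per_slice` (mm^2), `max_csa_mm2`,
#'   `volume_mm3`, `slices_used`, `mask`.
#' @export
measure_anatomy <- function(water, voxel_dims_mm, n_slices = 4L,
                            threshold_frac = 0.5, min_component_frac = 0.5) {
  bright <- water > 0.25 * max(water)
  if (!any(bright)) stopf("segmentation failed: no signal in water image")
  thr <- threshold_frac * stats::median(water[bright])
  mask <- water >= thr
  if (!any(mask)) stopf("segmentation failed: empty mask at threshold %.3g", thr)
  mask <- significant_components(mask, min_component_frac)
  vox_area <- voxel_dims_mm[1] * voxel_dims_mm[2]
  csa <- apply(mask, 3, sum) * vox_area
  sl <- largest_slices(mask, n_slices, consecutive = TRUE)
  structure(list(csa_per_slice = csa,
                 max_csa_mm2 = max(csa),
                 volume_mm3 = sum(csa[sl]) * voxel_dims_mm[3],
                 slices_used = sl, mask = mask),
            class = "anatomy_result")
}

# union of 6-connected components of a 3D logical array at least `min_frac`
# of the largest component's size; labelling by iterative min-label
# propagation (converges in O(component diameter) sweeps)
significant_components <- function(mask, min_frac = 0.5) {
  dm <- dim(mask)
  lab <- array(0, dm)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(a, d, by) {
    out <- array(Inf, dim(a))
    idx_src <- idx_dst <- lapply(dim(a), seq_len)
    n <- dim(a)[d]
    if (n <= abs(by)) return(out)
    if (by > 0) { idx_dst[[d]] <- (1 + by):n; idx_src[[d]] <- 1:(n - by) }
    else { idx_dst[[d]] <- 1:(n + by); idx_src[[d]] <- (1 - by):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  lab[!mask] <- Inf
  repeat {
    new <- lab
    for (d in 1:3) for (by in c(-1L, 1L)) new <- pmin(new, shift(lab, d, by))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  sizes <- table(lab[mask])
  keep <- as.numeric(names(sizes)[sizes >= min_frac * max(sizes)])
  mask & array(lab %in% keep, dim(mask))
}
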