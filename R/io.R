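# On-disk interchange formats: NIfTI volumes with JSON sidecars, CSV FIDs
# and force traces with JSON metadata.

#' Write a multi-echo or diffusion volume as NIfTI + JSON sidecar
#'
#' Complex (Dixon) data are written as a pair of real/imaginary NIfTI files;
#' magnitude data as a single file. The sidecar records echo times (ms),
#' b-values (s/mm^2), the direction table, noise sigma and seed.
#'
#' @param vol a `multiecho_volume` or `diffusion_volume`.
#' @param path output path without extension (e.g. `"out/dixon"`).
#' @param voxel_dims_mm voxel dimensions for the NIfTI header.
#' @return invisibly, the sidecar path.
#' @export
write_volume <- function(vol, path, voxel_dims_mm = c(1, 1, 1)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  side <- list(kind = vol$kind %||% "dwi", noise_sigma = vol$noise_sigma,
               seed = vol$seed)
  if (!is.null(vol$te_ms)) side$te_ms <- vol$te_ms
  if (!is.null(vol$phase_labels)) side$phase_labels <- vol$phase_labels
  if (!is.null(vol$bvals)) side$bvals <- vol$bvals
  if (!is.null(vol$directions)) side$directions <- unname(as.matrix(vol$directions))
  if (!is.null(vol$n_b0)) side$n_b0 <- vol$n_b0
  if (is.complex(vol$data)) {
    side$complex <- TRUE
    RNifti::writeNifti(RNifti::asNifti(Re(vol$data), pixdim = voxel_dims_mm),
                       paste0(path, "_real.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(Im(vol$data), pixdim = voxel_dims_mm),
                       paste0(path, "_imag.nii.gz"))
  } else {
    side$complex <- FALSE
    RNifti::writeNifti(RNifti::asNifti(vol$data, pixdim = voxel_dims_mm),
                       paste0(path, ".nii.gz"))
  }
  jp <- paste0(path, ".json")
  jsonlite::write_json(side, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}

#' Read a volume written by [write_volume()]
#'
#' @param path the path stem used when writing.
#' @return a `multiecho_volume` or `diffusion_volume`.
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (isTRUE(side$complex)) {
    re <- RNifti::readNifti(paste0(path, "_real.nii.gz"))
    im <- RNifti::readNifti(paste0(path, "_imag.nii.gz"))
    dat <- array(complex(real = re, imaginary = im), dim(re))
  } else {
    img <- RNifti::readNifti(paste0(path, ".nii.gz"))
    dat <- array(as.numeric(img), dim(img))
  }
  if (identical(side$kind, "dwi")) {
    structure(list(data = dat, bvals = side$bvals,
                   directions = matrix(unlist(side$directions), ncol = 3),
                   n_b0 = side$n_b0, noise_sigma = side$noise_sigma,
                   seed = side$seed),
              class = "diffusion_volume")
  } else {
    structure(list(data = dat, te_ms = side$te_ms,
                   phase_labels = side$phase_labels, kind = side$kind,
                   noise_sigma = side$noise_sigma, seed = side$seed),
              class = "multiecho_volume")
  }
}

#' Write a spectrum series as per-bin CSV FIDs + JSON metadata
#'
#' Each bin becomes `<path>_bin<k>.csv` with columns `t_s`, `real`, `imag`;
#' the JSON records sweep width, point count, reference frequency and the bin
#' table (phase label, start, width in seconds).
#'
#' @param series a `spectrum_series`.
#' @param path output path stem.
#' @return invisibly, the metadata path.
#' @export
write_fids <- function(series, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  t_s <- (seq_len(series$npts) - 1L) / series$sw_hz
  for (i in seq_along(series$bins)) {
    utils::write.csv(data.frame(t_s = t_s, real = Re(series$bins[[i]]),
                                imag = Im(series$bins[[i]])),
                     sprintf("%s_bin%02d.csv", path, i), row.names = FALSE)
  }
  meta <- list(sw_hz = series$sw_hz, npts = series$npts,
               f0_mhz = series$f0_mhz,
               bins = series$meta[, c("phase", "n_fids", "t_start_s", "width_s",
                                      "t_mid_s")])
  jp <- paste0(path, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}

#' Read a spectrum series written by [write_fids()]
#' @param path the path stem used when writing.
#' @return a `spectrum_series`.
#' @export
read_fids <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bins_meta <- as.data.frame(meta$bins)
  bins <- lapply(seq_len(nrow(bins_meta)), function(i) {
    d <- utils::read.csv(sprintf("%s_bin%02d.csv", path, i))
    complex(real = d$real, imaginary = d$imag)
  })
  structure(list(bins = bins, meta = bins_meta, npts = meta$npts,
                 sw_hz = meta$sw_hz, f0_mhz = meta$f0_mhz, kin = NULL,
                 protocol = NULL),
            class = "spectrum_series")
}

#' Write a force recording as CSV trace + JSON stimulation schedule
#'
#' @param rec a `force_recording`.
#' @param path output path stem.
#' @return invisibly, the schedule path.
#' @export
write_force <- function(rec, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(t_s = rec$t_s, force_mN = rec$force_mN),
                   paste0(path, ".csv"), row.names = FALSE)
  sched <- rec$schedule
  sched$sample_rate_hz <- rec$sample_rate_hz
  jp <- paste0(path, ".json")
  jsonlite::write_json(sched, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}

#' Read a force recording written by [write_force()]
#' @param path the path stem used when writing.
#' @return a `force_recording`.
#' @export
read_force <- function(path) {
  d <- utils::read.csv(paste0(path, ".csv"))
  sched <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sr <- sched$sample_rate_hz
  sched$sample_rate_hz <- NULL
  if (!is.null(sched$trains)) sched$trains <- as.data.frame(sched$trains)
  structure(list(t_s = d$t_s, force_mN = d$force_mN, sample_rate_hz = sr,
                 schedule = sched, spec = NULL),
            class = "force_recording")
}
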