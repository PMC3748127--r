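# 31P spectral model shared by the simulator and the fitting routine.
#
# Chemical shifts are expressed in ppm relative to PCr = 0; at 4.7 T the 31P
# resonance frequency is 81.08 MHz, so 1 ppm = 81.08 Hz. ATP multiplets:
# gamma- and alpha-ATP are 1:1 doublets, beta-ATP a 1:2:1 triplet, all with
# J = 16.5 Hz. These are standard literature values for in vivo muscle.

F0_31P_MHZ <- 81.08
J_ATP_HZ <- 16.5

# Henderson-Hasselbalch calibration of the Pi-PCr chemical shift
PH_PKA <- 6.75
PH_DELTA_MIN <- 3.27   # ppm, acid endpoint
PH_DELTA_MAX <- 5.69   # ppm, base endpoint

#' Intracellular pH from the Pi chemical shift
#'
#' `pH = pKa + log10((d - d_min) / (d_max - d))` with pKa = 6.75,
#' d_min = 3.27 ppm and d_max = 5.69 ppm, `d` being the Pi shift relative to
#' PCr. Valid strictly inside the open interval (d_min, d_max).
#'
#' @param delta_pi_ppm Pi chemical shift relative to PCr, ppm.
#' @return pH (same length as input).
#' @export
compute_phi <- function(delta_pi_ppm) {
  if (any(delta_pi_ppm <= PH_DELTA_MIN | delta_pi_ppm >= PH_DELTA_MAX))
    stopf("Pi shift outside the calibration interval (%.2f, %.2f) ppm",
          PH_DELTA_MIN, PH_DELTA_MAX)
  PH_PKA + log10((delta_pi_ppm - PH_DELTA_MIN) / (PH_DELTA_MAX - delta_pi_ppm))
}

#' Pi chemical shift from intracellular pH (inverse calibration)
#'
#' Exact inverse of [compute_phi()].
#'
#' @param ph pH value(s).
#' @return Pi shift relative to PCr, ppm.
#' @export
phi_to_delta <- function(ph) {
  r <- 10^(ph - PH_PKA)
  (PH_DELTA_MIN + PH_DELTA_MAX * r) / (1 + r)
}

#' Prior knowledge for 31P spectral fitting
#'
#' One row per metabolite: nominal chemical shift (ppm vs PCr), search window
#' half-width, multiplet size (1 = singlet, 2 = 1:1 doublet, 3 = 1:2:1
#' triplet with J = 16.5 Hz spacing), and damping start/bounds (Hz). The Pi
#' window is wide enough to track the pH-driven shift over the physiological
#' range (pH ~6.4-7.3).
#'
#' @return data.frame of class `mrs_prior`.
#' @export
default_prior_31p <- function() {
  p <- data.frame(
    name = c("PCr", "Pi", "gATP", "aATP", "bATP"),
    ppm0 = c(0, 4.60, -2.48, -7.52, -16.26),
    ppm_window = c(0.2, 0.55, 0.2, 0.2, 0.2),
    mult = c(1L, 1L, 2L, 2L, 3L),
    damp0_hz = c(12, 18, 25, 25, 25),
    damp_min_hz = 1, damp_max_hz = 80,
    stringsAsFactors = FALSE)
  class(p) <- c("mrs_prior", class(p))
  p
}

# expand a metabolite (center frequency in Hz, total amplitude) into its
# multiplet lines; amplitude ratios 1 / 1:1 / 1:2:1, spacing J
expand_multiplet <- function(f_hz, amp, mult, j_hz = J_ATP_HZ) {
  if (mult == 1L) return(list(f = f_hz, a = amp))
  if (mult == 2L) return(list(f = f_hz + c(-0.5, 0.5) * j_hz, a = amp * c(0.5, 0.5)))
  if (mult == 3L) return(list(f = f_hz + c(-1, 0, 1) * j_hz, a = amp * c(0.25, 0.5, 0.25)))
  stopf("unsupported multiplet size %d", mult)
}

#' Synthesize a complex FID as a sum of damped sinusoids
#'
#' `FID(t) = sum_k a_k exp(-d_k t) exp(i (2 pi f_k t + phase))` sampled at
#' `npts` points with sweep width `sw_hz`.
#'
#' @param peaks data.frame with columns `f_hz`, `amp`, `damp_hz` (one row per
#'   spectral line, multiplets already expanded).
#' @param npts number of complex points.
#' @param sw_hz sweep width, Hz.
#' @param phase zero-order phase, rad.
#' @return complex vector of length `npts`.
#' @export
synth_fid <- function(peaks, npts = 2048L, sw_hz = 8000, phase = 0) {
  t <- (seq_len(npts) - 1L) / sw_hz
  fid <- complex(real = numeric(npts))
  for (k in seq_len(nrow(peaks))) {
    fid <- fid + peaks$amp[k] * exp(-peaks$damp_hz[k] * t) *
      exp(1i * (2 * pi * peaks$f_hz[k] * t + phase))
  }
  fid
}

# metabolite parameter set -> expanded line table
lines_from_pars <- function(prior, amp, f_hz, damp_hz) {
  fs <- numeric(0); as <- numeric(0); ds <- numeric(0)
  for (k in seq_len(nrow(prior))) {
    ex <- expand_multiplet(f_hz[k], amp[k], prior$mult[k])
    fs <- c(fs, ex$f); as <- c(as, ex$a); ds <- c(ds, rep(damp_hz[k], length(ex$f)))
  }
  data.frame(f_hz = fs, amp = as, damp_hz = ds)
}
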