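#' Dynamic 31P acquisition protocol
#'
#' The default mirrors the rest/stimulation/recovery layout the pipeline is
#' designed for: 256 FIDs at TR = 1.875 s (64 at rest summed into one bin,
#' then 192 during stimulation summed by packets of 32, i.e. ~60 s temporal
#' resolution) followed by 512 recovery FIDs (224 by packets of 32, 192 by
#' packets of 64, and the last 96 summed together). That yields 18 protocol
#' bins; a separate fully relaxed spectrum (12 accumulations, TR = 20 s) is
#' acquired at rest for the PCr/ATP ratio.
#'
#' @param tr_s repetition time of the dynamic run, s.
#' @return an `mrs_protocol`: `tr_s`, `bins` data.frame (phase, n_fids,
#'   fid_start, t_start_s, width_s, t_mid_s), `stim_start_s`, `stim_end_s`,
#'   `n_fids_total`, `fully_relaxed` (n_acq, tr_s).
#' @export
mrs_protocol <- function(tr_s = 1.875) {
  layout <- data.frame(
    phase = c("rest", rep("stim", 6), rep("recovery", 11)),
    n_fids = c(64, rep(32, 6), rep(32, 7), rep(64, 3), 96))
  fid_start <- cumsum(c(1, head(layout$n_fids, -1)))
  t_start <- (fid_start - 1) * tr_s
  width <- layout$n_fids * tr_s
  bins <- cbind(layout, fid_start = fid_start, t_start_s = t_start,
                width_s = width, t_mid_s = t_start + width / 2)
  structure(list(tr_s = tr_s, bins = bins,
                 stim_start_s = 64 * tr_s,
                 stim_end_s = 256 * tr_s,
                 n_fids_total = sum(bins$n_fids),
                 fully_relaxed = list(n_acq = 12L, tr_s = 20)),
            class = "mrs_protocol")
}

#' Metabolic kinetics driving the 31P simulator
#'
#' PCr is expressed as a fraction of its resting level: constant 1 at rest,
#' monoexponential depletion toward `pcr_end_stim_pct`/100 during stimulation
#' (time constant `tau_deplete_s`) and monoexponential recovery back to 1
#' with time constant `tau_recovery_s` (the tauPCr the recovery fit must
#' recover). Pi mirrors PCr so that PCr + Pi is constant in amplitude units.
#' pH falls linearly from `ph_rest` to `ph_end` during stimulation and
#' recovers exponentially with `tau_recovery_s`.
#'
#' @param pcr_end_stim_pct PCr at end of stimulation, % of rest (0-100].
#' @param tau_deplete_s depletion time constant, s.
#' @param tau_recovery_s recovery time constant tauPCr, s.
#' @param ph_rest,ph_end resting and end-stimulation pH.
#' @param pcr_atp_ratio resting PCr to (beta-)ATP amplitude ratio.
#' @param pi_rest_frac resting Pi amplitude as a fraction of resting PCr.
#' @param noise_sigma per-FID complex noise sd, in units where the resting
#'   per-FID PCr amplitude is 100 (so `100/SNR`).
#' @param rng_seed RNG seed.
#' @return an `mrs_kinetics` object.
#' @export
mrs_kinetics <- function(pcr_end_stim_pct = 60, tau_deplete_s = 50,
                         tau_recovery_s = 148, ph_rest = 7.06, ph_end = 6.80,
                         pcr_atp_ratio = 3.5, pi_rest_frac = 0.12,
                         noise_sigma = 0, rng_seed = 1L) {
  if (pcr_end_stim_pct <= 0 || pcr_end_stim_pct > 100)
    stopf("pcr_end_stim_pct must lie in (0, 100]")
  if (tau_deplete_s <= 0 || tau_recovery_s <= 0) stopf("time constants must be > 0")
  structure(list(pcr_rest = 100, pcr_end_stim_pct = pcr_end_stim_pct,
                 tau_deplete_s = tau_deplete_s, tau_recovery_s = tau_recovery_s,
                 ph_rest = ph_rest, ph_end = ph_end,
                 pcr_atp_ratio = pcr_atp_ratio, pi_rest_frac = pi_rest_frac,
                 noise_sigma = noise_sigma, rng_seed = rng_seed),
            class = "mrs_kinetics")
}

#' PCr level of the kinetic model at given times
#'
#' Evaluates the piecewise rest/depletion/recovery model of an
#' [mrs_kinetics()] object, as a fraction of the resting level. Used both by
#' the FID simulator (via its window average) and to generate point-sampled
#' recovery curves at the protocol bin midpoints.
#'
#' @param kin an [mrs_kinetics()].
#' @param t time(s), s (protocol clock: dynamic run starts at 0).
#' @param protocol an [mrs_protocol()] fixing the stimulation window.
#' @return PCr as a fraction of rest (vectorized over `t`).
#' @export
pcr_fraction <- function(kin, t, protocol = mrs_protocol()) {
  t0 <- protocol$stim_start_s; t1 <- protocol$stim_end_s
  e <- kin$pcr_end_stim_pct / 100
  f_end <- e + (1 - e) * exp(-(t1 - t0) / kin$tau_deplete_s)
  out <- rep(1, length(t))
  st <- t >= t0 & t < t1
  out[st] <- e + (1 - e) * exp(-(t[st] - t0) / kin$tau_deplete_s)
  rc <- t >= t1
  out[rc] <- 1 - (1 - f_end) * exp(-(t[rc] - t1) / kin$tau_recovery_s)
  out
}

# exact window average of pcr_fraction over [a, b] (never spans a phase
# boundary under the standard protocol layout)
pcr_fraction_avg <- function(kin, a, b, protocol) {
  t0 <- protocol$stim_start_s; t1 <- protocol$stim_end_s
  e <- kin$pcr_end_stim_pct / 100
  f_end <- e + (1 - e) * exp(-(t1 - t0) / kin$tau_deplete_s)
  w <- b - a
  if (b <= t0) return(1)
  if (a >= t0 && b <= t1) {
    td <- kin$tau_deplete_s
    return(e + (1 - e) * td / w * (exp(-(a - t0) / td) - exp(-(b - t0) / td)))
  }
  if (a >= t1) {
    tr <- kin$tau_recovery_s
    return(1 - (1 - f_end) * tr / w * (exp(-(a - t1) / tr) - exp(-(b - t1) / tr)))
  }
  stopf("acquisition window [%.1f, %.1f] spans a protocol phase boundary", a, b)
}

ph_at <- function(kin, t, protocol) {
  t0 <- protocol$stim_start_s; t1 <- protocol$stim_end_s
  out <- rep(kin$ph_rest, length(t))
  st <- t >= t0 & t < t1
  out[st] <- kin$ph_rest + (kin$ph_end - kin$ph_rest) * (t[st] - t0) / (t1 - t0)
  rc <- t >= t1
  out[rc] <- kin$ph_rest - (kin$ph_rest - kin$ph_end) * exp(-(t[rc] - t1) / kin$tau_recovery_s)
  out
}

#' Simulate a dynamic 31P spectrum series
#'
#' For each protocol bin a complex FID is synthesized as a sum of damped
#' sinusoids: PCr at 0 ppm, Pi at the pH-dependent shift given by the inverse
#' calibration ([phi_to_delta()]), gamma/alpha-ATP 1:1 doublets and the
#' beta-ATP 1:2:1 triplet (J = 16.5 Hz). Bin amplitudes are the exact time
#' average of the kinetic model over the bin's acquisition window, on the
#' coherent-sum scale (single-FID amplitude times the number of FIDs summed).
#' Noise, if any, is complex Gaussian with sd `noise_sigma * sqrt(n_fids)`.
#'
#' @param kin an [mrs_kinetics()].
#' @param protocol an [mrs_protocol()].
#' @param npts,sw_hz FID sampling (2048 points, 8 kHz by default).
#' @param seed RNG seed (default `kin$rng_seed`).
#' @return a `spectrum_series`: `bins` (list of complex FIDs), `meta`
#'   data.frame with bin timing plus ground-truth columns `pcr_pct_true`,
#'   `pi_pct_true`, `ph_true`, and sampling metadata.
#' @export
simulate_mrs_series <- function(kin, protocol = mrs_protocol(), npts = 2048L,
                                sw_hz = 8000, seed = NULL) {
  stopifnot(inherits(kin, "mrs_kinetics"), inherits(protocol, "mrs_protocol"))
  seed <- seed %||% kin$rng_seed
  prior <- default_prior_31p()
  meta <- protocol$bins
  pi0 <- kin$pcr_rest * kin$pi_rest_frac
  atp <- kin$pcr_rest / kin$pcr_atp_ratio
  nb <- nrow(meta)
  meta$pcr_pct_true <- meta$pi_pct_true <- meta$ph_true <- NA_real_
  bins <- vector("list", nb)
  with_seed(seed, {
    for (i in seq_len(nb)) {
      a <- meta$t_start_s[i]; b <- a + meta$width_s[i]
      f <- pcr_fraction_avg(kin, a, b, protocol)
      ph <- ph_at(kin, meta$t_mid_s[i], protocol)
      pcr_amp <- kin$pcr_rest * f
      pi_amp <- pi0 + kin$pcr_rest * (1 - f)
      meta$pcr_pct_true[i] <- 100 * f
      meta$pi_pct_true[i] <- 100 * pi_amp / pi0
      meta$ph_true[i] <- ph
      amps <- c(pcr_amp, pi_amp, atp, atp, atp) * meta$n_fids[i]
      f_hz <- c(0, phi_to_delta(ph) * F0_31P_MHZ,
                prior$ppm0[3:5] * F0_31P_MHZ)
      lines <- lines_from_pars(prior, amps, f_hz, prior$damp0_hz)
      fid <- synth_fid(lines, npts, sw_hz)
      if (kin$noise_sigma > 0)
        fid <- fid + cnoise(npts, kin$noise_sigma * sqrt(meta$n_fids[i]))
      bins[[i]] <- fid
    }
  })
  structure(list(bins = bins, meta = meta, npts = npts, sw_hz = sw_hz,
                 f0_mhz = F0_31P_MHZ, kin = kin, protocol = protocol),
            class = "spectrum_series")
}

#' Simulate the fully relaxed resting 31P spectrum
#'
#' Coherent sum of `n_acq` resting-state FIDs; used for the PCr/ATP ratio
#' (every metabolite at its resting amplitude, Pi at the resting pH shift).
#'
#' @inheritParams simulate_mrs_series
#' @param n_acq number of accumulations.
#' @param noise_sigma per-FID complex noise sd (default `kin$noise_sigma`).
#' @return a single-bin `spectrum_series`.
#' @export
simulate_rest_spectrum <- function(kin, n_acq = 12L, npts = 2048L, sw_hz = 8000,
                                   noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(kin, "mrs_kinetics"))
  noise_sigma <- noise_sigma %||% kin$noise_sigma
  seed <- seed %||% kin$rng_seed
  prior <- default_prior_31p()
  pi0 <- kin$pcr_rest * kin$pi_rest_frac
  atp <- kin$pcr_rest / kin$pcr_atp_ratio
  amps <- c(kin$pcr_rest, pi0, atp, atp, atp) * n_acq
  f_hz <- c(0, phi_to_delta(kin$ph_rest) * F0_31P_MHZ,
            prior$ppm0[3:5] * F0_31P_MHZ)
  lines <- lines_from_pars(prior, amps, f_hz, prior$damp0_hz)
  fid <- synth_fid(lines, npts, sw_hz)
  if (noise_sigma > 0)
    fid <- with_seed(seed, fid + cnoise(npts, noise_sigma * sqrt(n_acq)))
  meta <- data.frame(phase = "rest_fully_relaxed", n_fids = n_acq,
                     fid_start = NA, t_start_s = NA, width_s = NA,
                     t_mid_s = NA, pcr_pct_true = 100, pi_pct_true = 100,
                     ph_true = kin$ph_rest)
  structure(list(bins = list(fid), meta = meta, npts = npts, sw_hz = sw_hz,
                 f0_mhz = F0_31P_MHZ, kin = kin, protocol = NULL),
            class = "spectrum_series")
}
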