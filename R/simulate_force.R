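#' Specification of an evoked-force protocol
#'
#' Two modes: `force_frequency` (0.75 s tetanic trains at incremental
#' stimulation frequencies, 30 s rest between trains) and `fatigue` (repeated
#' single twitches at 1.7 Hz for 6 min). The tetanus waveform rises as
#' `F_peak(f) * (1 - exp(-k t))` during the train and relaxes exponentially
#' with time constant `relax_tau_s` afterwards; per-train peak amplitudes
#' follow a Hill force-frequency curve. Twitches are `A (t/tc) exp(1 - t/tc)`
#' pulses whose amplitude follows a configurable fatigue-decline schedule.
#'
#' @param mode `"force_frequency"` or `"fatigue"`.
#' @param frequencies_hz stimulation frequencies for force_frequency mode
#'   (positive, increasing).
#' @param train_duration_s,rest_interval_s tetanic train length and rest gap.
#' @param fatigue_duration_s,fatigue_rate_hz fatigue protocol length and
#'   twitch rate.
#' @param f_max_mN maximal (plateau) tetanic force of the Hill curve.
#' @param f50_hz,hill_n Hill curve half-frequency and exponent.
#' @param rise_k_per_s tetanic rise-rate constant k (1/s); the maximal rate
#'   of force development of a train of peak F is `F * k`.
#' @param relax_tau_s exponential relaxation time constant, s (half
#'   relaxation time = `relax_tau_s * log(2)`).
#' @param twitch_amplitude_mN unfatigued twitch peak force.
#' @param twitch_tc_s twitch time-to-peak.
#' @param fatigue_plateau_frac,fatigue_tau_s twitch-amplitude decline
#'   schedule: exponential decay to `plateau + (1-plateau) exp(-t/tau)`.
#' @param sample_rate_hz sampling rate (>= 1 kHz).
#' @param noise_sigma additive Gaussian noise sd, mN.
#' @param rng_seed RNG seed.
#' @return a `force_protocol_spec`.
#' @export
force_protocol_spec <- function(mode = c("force_frequency", "fatigue"),
                                frequencies_hz = c(1, 10, 20, 40, 60, 80, 100, 150),
                                train_duration_s = 0.75, rest_interval_s = 30,
                                fatigue_duration_s = 360, fatigue_rate_hz = 1.7,
                                f_max_mN = 300, f50_hz = 40, hill_n = 3,
                                rise_k_per_s = 10.5, relax_tau_s = 0.262 / log(2),
                                twitch_amplitude_mN = 60, twitch_tc_s = 0.020,
                                fatigue_plateau_frac = 0.5, fatigue_tau_s = 60,
                                sample_rate_hz = 10000, noise_sigma = 0,
                                rng_seed = 1L) {
  mode <- match.arg(mode)
  if (any(frequencies_hz <= 0) || is.unsorted(frequencies_hz, strictly = TRUE))
    stopf("frequencies must be positive and strictly increasing")
  if (sample_rate_hz < 1000) stopf("sample rate must be >= 1 kHz")
  if (f_max_mN <= 0 || rise_k_per_s <= 0 || relax_tau_s <= 0 ||
      twitch_amplitude_mN <= 0 || twitch_tc_s <= 0)
    stopf("waveform parameters must be positive")
  structure(as.list(environment()), class = "force_protocol_spec")
}

hill_force <- function(f, f_max, f50, n) f_max * f^n / (f^n + f50^n)

#' Simulate an evoked-force recording
#'
#' Generates the sampled force trace and the stimulation schedule for the
#' protocol in `spec`; Gaussian noise is added last.
#'
#' @param spec a [force_protocol_spec()].
#' @param seed RNG seed (default `spec$rng_seed`).
#' @return a `force_recording`: `t_s`, `force_mN`, `sample_rate_hz`, and
#'   `schedule` (for force_frequency: data.frame of trains with `frequency_hz`,
#'   `t_on_s`, `t_off_s`, `peak_true_mN`; for fatigue: `stim_times_s` plus the
#'   per-twitch true amplitudes).
#' @export
simulate_force_protocol <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "force_protocol_spec"))
  seed <- seed %||% spec$rng_seed
  sr <- spec$sample_rate_hz
  dt <- 1 / sr
  if (spec$mode == "force_frequency") {
    tail_s <- 6 * spec$relax_tau_s
    n_tr <- length(spec$frequencies_hz)
    t_on <- 0.1 + (seq_len(n_tr) - 1) * (spec$train_duration_s + spec$rest_interval_s)
    t_off <- t_on + spec$train_duration_s
    total <- t_off[n_tr] + tail_s + 0.1
    n <- ceiling(total * sr)
    tt <- (seq_len(n) - 1L) * dt
    force <- numeric(n)
    peaks <- hill_force(spec$frequencies_hz, spec$f_max_mN, spec$f50_hz, spec$hill_n)
    for (j in seq_len(n_tr)) {
      ramp <- tt >= t_on[j] & tt < t_off[j]
      force[ramp] <- peaks[j] * (1 - exp(-spec$rise_k_per_s * (tt[ramp] - t_on[j])))
      f_end <- peaks[j] * (1 - exp(-spec$rise_k_per_s * spec$train_duration_s))
      dec <- tt >= t_off[j] & tt < t_off[j] + tail_s
      force[dec] <- f_end * exp(-(tt[dec] - t_off[j]) / spec$relax_tau_s)
    }
    pulses <- lapply(seq_len(n_tr), function(j)
      seq(t_on[j], t_off[j] - 1e-12, by = 1 / spec$frequencies_hz[j]))
    schedule <- list(mode = "force_frequency",
                     trains = data.frame(train = seq_len(n_tr),
                                         frequency_hz = spec$frequencies_hz,
                                         t_on_s = t_on, t_off_s = t_off,
                                         peak_true_mN = peaks),
                     pulse_times_s = pulses)
  } else {
    n_tw <- floor(spec$fatigue_duration_s * spec$fatigue_rate_hz)
    stim <- 0.5 + (seq_len(n_tw) - 1) / spec$fatigue_rate_hz
    amp <- spec$twitch_amplitude_mN *
      (spec$fatigue_plateau_frac + (1 - spec$fatigue_plateau_frac) *
         exp(-(stim - stim[1]) / spec$fatigue_tau_s))
    total <- max(stim) + 0.5
    n <- ceiling(total * sr)
    tt <- (seq_len(n) - 1L) * dt
    force <- numeric(n)
    tc <- spec$twitch_tc_s
    sup <- seq(0, 15 * tc, by = dt)
    w <- (sup / tc) * exp(1 - sup / tc)       # unit-peak twitch waveform
    for (j in seq_len(n_tw)) {
      i0 <- round(stim[j] * sr) + 1L
      idx <- i0:min(n, i0 + length(w) - 1L)
      force[idx] <- force[idx] + amp[j] * w[seq_along(idx)]
    }
    schedule <- list(mode = "fatigue", stim_times_s = stim,
                     amp_true_mN = amp, rate_hz = spec$fatigue_rate_hz)
  }
  if (spec$noise_sigma > 0)
    force <- with_seed(seed, force + stats::rnorm(length(force), 0, spec$noise_sigma))
  structure(list(t_s = tt, force_mN = force, sample_rate_hz = sr,
                 schedule = schedule, spec = spec),
            class = "force_recording")
}
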