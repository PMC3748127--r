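#' Per-train tetanus metrics
#'
#' From one stimulation train: baseline-subtracted isometric peak force, the
#' maximal rate of force development (centered-difference derivative after a
#' short moving average), and the half relaxation time, i.e. the time from
#' the post-train force maximum to half of the decline toward baseline
#' (linear interpolation at the crossing). Baseline is the median of the
#' 50 ms preceding the train.
#'
#' @param rec a `force_recording`.
#' @param train train index in the schedule (force_frequency mode).
#' @param deriv_smooth_ms moving-average width for the derivative, ms
#'   (0 = none).
#' @param hrt_smooth_ms moving-average width for peak/half-relaxation
#'   detection, ms (0 = none; use ~5 ms on noisy traces).
#' @return a `train_metrics` list: `frequency_hz`, `peak_force_mN`,
#'   `max_dfdt_mN_per_ms`, `half_relaxation_ms`, `baseline_mN`.
#' @export
train_metrics <- function(rec, train = 1L, deriv_smooth_ms = 1,
                          hrt_smooth_ms = 0) {
  stopifnot(inherits(rec, "force_recording"))
  if (rec$schedule$mode != "force_frequency")
    stopf("train_metrics needs a force_frequency recording")
  tr <- rec$schedule$trains
  if (train < 1L || train > nrow(tr)) stopf("no train %d in schedule", train)
  sr <- rec$sample_rate_hz
  t_on <- tr$t_on_s[train]; t_off <- tr$t_off_s[train]
  pre <- rec$force_mN[rec$t_s >= t_on - 0.05 & rec$t_s < t_on]
  if (!length(pre)) stopf("window contains no pre-train baseline samples")
  baseline <- stats::median(pre)
  t_end <- if (train < nrow(tr)) tr$t_on_s[train + 1L] else max(rec$t_s)
  win <- rec$t_s >= t_on & rec$t_s < t_end
  if (!sum(win)) stopf("window contains no stimuli")
  tw <- rec$t_s[win]
  fw <- rec$force_mN[win]

  fs <- if (hrt_smooth_ms > 0) moving_average(fw, hrt_smooth_ms * sr / 1000) else fw
  # post-train maximum: the tetanic plateau is nearly flat, so the search
  # starts at the end of stimulation rather than inside the plateau (noise
  # would otherwise drag the detected peak time into the flat top)
  post <- tw >= t_off
  i_pk <- which(post)[which.max(fs[post])]
  f_pk <- fs[i_pk]
  peak <- max(fs) - baseline

  half <- baseline + 0.5 * (f_pk - baseline)
  below <- which(fs <= half & seq_along(fs) > i_pk)
  hrt <- NA_real_
  if (length(below)) {
    j <- below[1]
    # linear interpolation between samples j-1 and j
    f1 <- fs[j - 1L]; f2 <- fs[j]
    frac <- if (f1 == f2) 0 else (f1 - half) / (f1 - f2)
    t_half <- tw[j - 1L] + frac * (tw[j] - tw[j - 1L])
    hrt <- (t_half - tw[i_pk]) * 1000
  }

  w <- max(1L, round(deriv_smooth_ms * sr / 1000))
  fd <- if (w > 1L) moving_average(fw, w) else fw
  ramp <- which(tw >= t_on & tw <= t_off)
  d <- diff(fd[ramp]) * sr / 1000            # mN per ms, forward difference
  dfdt <- if (length(d) > 2) (d[-1] + d[-length(d)]) / 2 else d
  # discard samples whose smoothing window is incomplete at the ramp edges
  if (w > 1L && length(dfdt) > 2 * w) dfdt <- dfdt[-c(seq_len(w), length(dfdt) - seq_len(w) + 1L)]
  dfdt <- max(dfdt)

  structure(list(frequency_hz = tr$frequency_hz[train],
                 peak_force_mN = peak, max_dfdt_mN_per_ms = dfdt,
                 half_relaxation_ms = hrt, baseline_mN = baseline),
            class = "train_metrics")
}

#' Peak force of every train in a force-frequency recording
#'
#' @param rec a force_frequency `force_recording`.
#' @inheritParams train_metrics
#' @return data.frame with `frequency_hz` and `peak_force_mN`.
#' @export
train_peaks <- function(rec, hrt_smooth_ms = 0) {
  tr <- rec$schedule$trains
  peaks <- vapply(seq_len(nrow(tr)), function(j)
    train_metrics(rec, j, hrt_smooth_ms = hrt_smooth_ms)$peak_force_mN, 0)
  data.frame(frequency_hz = tr$frequency_hz, peak_force_mN = peaks)
}

#' Hill force-frequency fit
#'
#' Least-squares fit of `F(f) = F_max * f^n / (f^n + f50^n)` to per-frequency
#' peak forces (zero offset: f50 is by definition the frequency at half the
#' maximal force). Also returns the relative curve normalized to the response
#' at the highest tested frequency.
#'
#' @param peaks data.frame with `frequency_hz` and `peak_force_mN` (>= 4
#'   distinct frequencies spanning both sides of the half-maximum).
#' @return a `force_frequency_fit`: `f_max_mN`, `f50_hz`, `hill_n`,
#'   `residual_rms`, `flagged`, `peaks` (with fitted and relative columns).
#' @export
fit_force_frequency <- function(peaks) {
  f <- peaks$frequency_hz; y <- peaks$peak_force_mN
  if (length(unique(f)) < 4L) stopf("need >= 4 distinct frequencies")
  if (stats::sd(y) < 1e-9 * max(abs(y))) {
    return(structure(list(f_max_mN = NA_real_, f50_hz = NA_real_,
                          hill_n = NA_real_, residual_rms = NA_real_,
                          flagged = TRUE, peaks = peaks),
                     class = "force_frequency_fit"))
  }
  fmax0 <- max(y)
  i50 <- which(y >= fmax0 / 2)[1]
  f500 <- if (i50 > 1)
    stats::approx(y[c(i50 - 1, i50)], f[c(i50 - 1, i50)], xout = fmax0 / 2)$y
  else f[i50]
  df <- data.frame(f = f, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fmax * f^n / (f^n + f50^n), data = df,
                      start = list(fmax = fmax0, f50 = max(f500, 1e-3), n = 3),
                      lower = c(1e-9, 1e-3, 0.1), upper = c(Inf, max(f) * 10, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 300,
                                                           ftol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(f_max_mN = NA_real_, f50_hz = NA_real_,
                          hill_n = NA_real_, residual_rms = NA_real_,
                          flagged = TRUE, peaks = peaks),
                     class = "force_frequency_fit"))
  }
  cf <- stats::coef(fit)
  pk <- peaks
  pk$fitted_mN <- hill_force(f, cf["fmax"], cf["f50"], cf["n"])
  pk$relative <- y / y[which.max(f)]
  structure(list(f_max_mN = unname(cf["fmax"]), f50_hz = unname(cf["f50"]),
                 hill_n = unname(cf["n"]),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 flagged = FALSE, peaks = pk),
            class = "force_frequency_fit")
}

#' Fatigue-protocol summary
#'
#' Measures the amplitude of every peak twitch (baseline-subtracted maximum
#' in the window following each scheduled stimulus) and averages them over
#' consecutive 15 s bins of stimulation; optionally also normalized by muscle
#' volume (specific force).
#'
#' @param rec a fatigue-mode `force_recording`.
#' @param volume_mm3 hindlimb muscle volume for specific force (optional).
#' @param bin_s bin width, s.
#' @return a `fatigue_summary`: `twitch_peaks_mN`, `bin_means_mN`,
#'   `bin_means_specific` (mN/mm^3 or NULL), `n_bins`.
#' @export
fatigue_summary <- function(rec, volume_mm3 = NULL, bin_s = 15) {
  stopifnot(inherits(rec, "force_recording"))
  if (rec$schedule$mode != "fatigue" || is.null(rec$schedule$stim_times_s))
    stopf("fatigue_summary needs a fatigue recording with a stimulus schedule")
  stim <- rec$schedule$stim_times_s
  sr <- rec$sample_rate_hz
  gap <- if (length(stim) > 1) min(diff(stim)) else 0.5
  pre <- rec$force_mN[rec$t_s < stim[1]]
  baseline <- if (length(pre)) stats::median(pre) else 0
  peaks <- vapply(stim, function(s) {
    i0 <- floor(s * sr) + 1L
    i1 <- min(length(rec$force_mN), i0 + ceiling(gap * sr) - 1L)
    max(rec$force_mN[i0:i1]) - baseline
  }, 0)
  rel_t <- stim - stim[1]
  bin <- floor(rel_t / bin_s)
  means <- as.numeric(tapply(peaks, bin, mean))
  out <- list(twitch_peaks_mN = peaks, bin_means_mN = means,
              bin_means_specific = if (!is.null(volume_mm3))
                specific_force(means, volume_mm3) else NULL,
              n_bins = length(means), bin_s = bin_s)
  class(out) <- "fatigue_summary"
  out
}

#' Specific force (volume-normalized force)
#'
#' @param force_mN force value(s), mN.
#' @param volume_mm3 muscle volume, mm^3 (> 0).
#' @return force / volume, mN/mm^3.
#' @export
specific_force <- function(force_mN, volume_mm3) {
  if (length(volume_mm3) != 1L || !is.finite(volume_mm3) || volume_mm3 <= 0)
    stopf("volume must be a single positive number")
  force_mN / volume_mm3
}
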