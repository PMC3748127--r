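#' Sum raw FIDs into protocol bins
#'
#' Coherent complex summation of the 768 dynamic FIDs into the 18 protocol
#' bins (1 rest + 6 stimulation + 11 recovery); bin timestamps are packet
#' midpoints.
#'
#' @param raw_fids complex matrix, `npts` x 768 (one column per FID, in
#'   acquisition order).
#' @param protocol an [mrs_protocol()].
#' @param sw_hz sweep width of the FIDs, Hz.
#' @return a `spectrum_series` whose bins are packet sums.
#' @export
bin_fids <- function(raw_fids, protocol = mrs_protocol(), sw_hz = 8000) {
  stopifnot(inherits(protocol, "mrs_protocol"))
  raw_fids <- as.matrix(raw_fids)
  if (ncol(raw_fids) != protocol$n_fids_total)
    stopf("expected %d FIDs (64 rest + 192 stimulation + 512 recovery), got %d",
          protocol$n_fids_total, ncol(raw_fids))
  meta <- protocol$bins
  bins <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    idx <- meta$fid_start[i] + seq_len(meta$n_fids[i]) - 1L
    bins[[i]] <- rowSums(raw_fids[, idx, drop = FALSE])
  }
  structure(list(bins = bins, meta = meta, npts = nrow(raw_fids),
                 sw_hz = sw_hz, f0_mhz = F0_31P_MHZ, kin = NULL,
                 protocol = protocol),
            class = "spectrum_series")
}

#' Time-domain spectral fitting with prior knowledge
#'
#' Nonlinear least squares of a sum of damped sinusoids against a complex
#' FID. Multiplet structure (1:1 doublets, 1:2:1 triplet, J-spacing) is
#' imposed by parameterization: each metabolite contributes one amplitude,
#' one center frequency (bounded to its prior window), and one damping shared
#' across its multiplet lines; a single zero-order phase is common to all
#' peaks. The optimizer restarts from a few deterministically perturbed
#' initializations and keeps the best residual.
#'
#' @param fid complex FID vector.
#' @param sw_hz sweep width, Hz.
#' @param prior a [default_prior_31p()]-style data.frame (possibly a subset
#'   of its rows).
#' @param restarts number of initializations (>= 1; the first is unperturbed).
#' @param seed seed for the deterministic perturbations.
#' @return a `spectrum_fit` data.frame: one row per metabolite with
#'   `amplitude`, `f_hz`, `ppm`, `damp_hz` and Cramer-Rao-style standard
#'   errors; attributes `phase_rad`, `converged`, `rss`.
#' @export
fit_spectrum <- function(fid, sw_hz = 8000, prior = default_prior_31p(),
                         restarts = 3L, seed = 1L) {
  if (all(Mod(fid) == 0)) stopf("FID is identically zero")
  npts <- length(fid)
  t <- (seq_len(npts) - 1L) / sw_hz
  K <- nrow(prior)
  f0 <- prior$ppm0 * F0_31P_MHZ
  fw <- prior$ppm_window * F0_31P_MHZ

  model_fid <- function(p) {
    phase <- p[1]
    amp <- p[1 + seq_len(K)]
    fr <- p[1 + K + seq_len(K)]
    dp <- p[1 + 2 * K + seq_len(K)]
    lines <- lines_from_pars(prior, amp, fr, dp)
    synth_fid(lines, npts, sw_hz, phase)
  }
  resid_fn <- function(p) {
    d <- model_fid(p) - fid
    c(Re(d), Im(d))
  }
  # analytic Jacobian of the stacked (Re, Im) residuals
  jac_fn <- function(p) {
    phase <- p[1]
    amp <- p[1 + seq_len(K)]
    fr <- p[1 + K + seq_len(K)]
    dp <- p[1 + 2 * K + seq_len(K)]
    J <- matrix(0, 2L * npts, length(p))
    tot <- complex(real = numeric(npts))
    for (k in seq_len(K)) {
      ex <- expand_multiplet(fr[k], 1, prior$mult[k])
      mk <- complex(real = numeric(npts))
      for (l in seq_along(ex$f))
        mk <- mk + ex$a[l] * exp(-dp[k] * t) *
          exp(1i * (2 * pi * ex$f[l] * t + phase))
      tot <- tot + amp[k] * mk
      J[, 1 + k] <- c(Re(mk), Im(mk))
      dfk <- amp[k] * 2i * pi * t * mk
      J[, 1 + K + k] <- c(Re(dfk), Im(dfk))
      ddk <- -amp[k] * t * mk
      J[, 1 + 2 * K + k] <- c(Re(ddk), Im(ddk))
    }
    J[, 1] <- c(Re(1i * tot), Im(1i * tot))
    J
  }

  # starting frequencies by multiplet-template matching on the FFT magnitude
  # spectrum inside each prior window (a bare peak pick would sit J/2 off a
  # doublet's center)
  spec <- Mod(stats::fft(fid))
  fax <- (seq_len(npts) - 1L) / npts * sw_hz
  fax[fax >= sw_hz / 2] <- fax[fax >= sw_hz / 2] - sw_hz
  spec_at <- function(f) {
    i <- round((f %% sw_hz) / sw_hz * npts) + 1L
    spec[pmin(pmax(i, 1L), npts)]
  }
  f_pick <- vapply(seq_len(K), function(k) {
    cand <- seq(f0[k] - fw[k], f0[k] + fw[k], by = sw_hz / npts / 2)
    ex <- expand_multiplet(0, 1, prior$mult[k])
    score <- rowSums(vapply(seq_along(ex$f),
                            function(l) ex$a[l] * spec_at(cand + ex$f[l]),
                            numeric(length(cand))))
    cand[which.max(score)]
  }, 0)

  # linear complex least squares for starting amplitudes / phase
  init_amps <- function(fr, dp) {
    B <- matrix(0i, npts, K)
    for (k in seq_len(K)) {
      ex <- expand_multiplet(fr[k], 1, prior$mult[k])
      for (l in seq_along(ex$f))
        B[, k] <- B[, k] + ex$a[l] * exp(-dp[k] * t) * exp(2i * pi * ex$f[l] * t)
    }
    cf <- qr.solve(B, fid)
    amp <- Mod(cf)
    phase <- Arg(sum(cf * amp))
    list(amp = pmax(amp, 1e-6 * max(amp)), phase = phase)
  }

  lower <- c(-2 * pi, rep(0, K), f0 - fw, prior$damp_min_hz)
  upper <- c(2 * pi, rep(Inf, K), f0 + fw, prior$damp_max_hz)
  if (length(prior$damp_min_hz) == 1L) {
    lower <- c(-2 * pi, rep(0, K), f0 - fw, rep(prior$damp_min_hz[1], K))
    upper <- c(2 * pi, rep(Inf, K), f0 + fw, rep(prior$damp_max_hz[1], K))
  }

  starts <- with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      if (r == 1L) {
        fr <- f_pick; dp <- prior$damp0_hz
      } else {
        fr <- pmin(pmax(f_pick + stats::runif(K, -0.05, 0.05) * F0_31P_MHZ,
                        f0 - fw), f0 + fw)
        dp <- pmin(pmax(prior$damp0_hz * exp(stats::runif(K, -0.3, 0.3)),
                        lower[1 + 2 * K + seq_len(K)]),
                   upper[1 + 2 * K + seq_len(K)])
      }
      ia <- init_amps(fr, dp)
      c(ia$phase, ia$amp, fr, dp)
    })
  })

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, maxfev = 100000,
                           ftol = 1e-15, ptol = 1e-15, gtol = 1e-15)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    out <- data.frame(name = prior$name, amplitude = NA_real_, f_hz = NA_real_,
                      ppm = NA_real_, damp_hz = NA_real_,
                      amplitude_se = NA_real_, f_hz_se = NA_real_)
    attr(out, "converged") <- FALSE
    attr(out, "rss") <- NA_real_
    class(out) <- c("spectrum_fit", class(out))
    return(out)
  }
  p <- best$par
  dof <- max(1L, 2L * npts - length(p))
  s2 <- best$deviance / dof
  se <- rep(NA_real_, length(p))
  cv <- tryCatch(s2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  out <- data.frame(
    name = prior$name,
    amplitude = p[1 + seq_len(K)],
    f_hz = p[1 + K + seq_len(K)],
    ppm = p[1 + K + seq_len(K)] / F0_31P_MHZ,
    damp_hz = p[1 + 2 * K + seq_len(K)],
    amplitude_se = se[1 + seq_len(K)],
    f_hz_se = se[1 + K + seq_len(K)])
  attr(out, "phase_rad") <- p[1]
  attr(out, "converged") <- best$info %in% 1:4
  attr(out, "rss") <- best$deviance
  attr(out, "residuals") <- best$fvec
  class(out) <- c("spectrum_fit", class(out))
  out
}

#' Resting PCr/ATP ratio from a fully relaxed spectrum fit
#'
#' Ratio of the PCr amplitude to the beta-ATP amplitude (the beta-ATP triplet
#' is the cleanest ATP resonance: no overlap with NAD or phosphodiesters).
#'
#' @param fit a [fit_spectrum()] result containing `PCr` and `bATP` rows.
#' @return scalar ratio.
#' @export
pcr_atp_ratio <- function(fit) {
  stopifnot(inherits(fit, "spectrum_fit"))
  a <- fit$amplitude[match(c("PCr", "bATP"), fit$name)]
  if (anyNA(a)) stopf("fit must contain PCr and bATP")
  a[1] / a[2]
}

#' Metabolite time course from per-bin spectral fits
#'
#' Fits every bin of a series and expresses PCr and Pi amplitudes (per-FID
#' normalized) as percentages of the rest bin; pH per bin from the fitted
#' Pi-PCr shift (NA when Pi is not detected above its uncertainty).
#'
#' @param series a `spectrum_series` ([simulate_mrs_series()] / [bin_fids()]).
#' @param prior prior knowledge passed to [fit_spectrum()].
#' @param rest_fit optional [fit_spectrum()] of the fully relaxed spectrum;
#'   if given, the PCr/ATP ratio is computed from it.
#' @param restarts,seed passed to [fit_spectrum()].
#' @return a `metabolite_time_course`: data.frame (bin, phase, t_mid_s,
#'   pcr_pct, pi_pct, phi), attributes `pcr_atp`, `fits`.
#' @export
build_time_course <- function(series, prior = default_prior_31p(),
                              rest_fit = NULL, restarts = 3L, seed = 1L) {
  stopifnot(inherits(series, "spectrum_series"))
  meta <- series$meta
  if (!any(meta$phase == "rest")) stopf("series has no rest bin")
  fits <- vector("list", nrow(meta))
  amp <- function(f, nm) f$amplitude[match(nm, f$name)]
  se_of <- function(f, nm) f$amplitude_se[match(nm, f$name)]
  for (i in seq_len(nrow(meta))) {
    fits[[i]] <- fit_spectrum(series$bins[[i]], series$sw_hz, prior,
                              restarts = restarts, seed = seed + i)
  }
  rest_i <- which(meta$phase == "rest")[1]
  pcr0 <- amp(fits[[rest_i]], "PCr") / meta$n_fids[rest_i]
  pi0 <- amp(fits[[rest_i]], "Pi") / meta$n_fids[rest_i]
  tc <- data.frame(bin = seq_len(nrow(meta)), phase = meta$phase,
                   t_mid_s = meta$t_mid_s,
                   pcr_pct = NA_real_, pi_pct = NA_real_, phi = NA_real_)
  for (i in seq_len(nrow(meta))) {
    f <- fits[[i]]
    n <- meta$n_fids[i]
    tc$pcr_pct[i] <- 100 * (amp(f, "PCr") / n) / pcr0
    tc$pi_pct[i] <- 100 * (amp(f, "Pi") / n) / pi0
    a_pi <- amp(f, "Pi"); s_pi <- se_of(f, "Pi")
    detected <- is.finite(a_pi) && a_pi > 0 &&
      (!is.finite(s_pi) || a_pi > 2 * s_pi)
    if (detected) {
      d <- f$ppm[match("Pi", f$name)] - f$ppm[match("PCr", f$name)]
      if (d > PH_DELTA_MIN && d < PH_DELTA_MAX) tc$phi[i] <- compute_phi(d)
    }
  }
  attr(tc, "pcr_atp") <- if (!is.null(rest_fit)) pcr_atp_ratio(rest_fit) else NA_real_
  attr(tc, "fits") <- fits
  class(tc) <- c("metabolite_time_course", class(tc))
  tc
}

#' Monoexponential PCr recovery fit (tauPCr)
#'
#' Least-squares fit of `PCr(t) = asym - delta * exp(-(t - t0)/tau)` over the
#' recovery bins. A flat recovery (delta indistinguishable from zero) leaves
#' tau unidentifiable and is returned flagged rather than as an error.
#'
#' @param t_s bin timestamps, s (recovery bins).
#' @param pcr PCr values at those times (% of rest or raw amplitude; tau is
#'   scale invariant).
#' @param t0_s end of stimulation (time origin of the recovery), s.
#' @return list: `tau_s`, `asym`, `delta`, `converged`, `flagged`, `reason`.
#' @export
fit_pcr_recovery <- function(t_s, pcr, t0_s = 0) {
  if (length(t_s) < 4L) stopf("need >= 4 recovery points")
  if (length(t_s) != length(pcr)) stopf("t_s and pcr lengths differ")
  o <- order(t_s); t_s <- t_s[o]; pcr <- pcr[o]
  asym0 <- mean(utils::tail(pcr, 2))
  delta0 <- asym0 - pcr[1]
  if (!is.finite(delta0) || abs(delta0) < 0.01 * abs(asym0) ||
      stats::sd(pcr) < 1e-12) {
    return(list(tau_s = NA_real_, asym = asym0, delta = delta0,
                converged = FALSE, flagged = TRUE,
                reason = "flat recovery: tau unidentifiable"))
  }
  tau0 <- (max(t_s) - min(t_s)) / 3
  df <- data.frame(tt = t_s - t0_s, y = pcr)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ asym - delta * exp(-tt / tau),
                      data = df,
                      start = list(asym = asym0, delta = delta0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 300,
                                                           ftol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(tau_s = NA_real_, asym = NA_real_, delta = NA_real_,
                converged = FALSE, flagged = TRUE,
                reason = "recovery fit did not converge"))
  }
  cf <- stats::coef(fit)
  list(tau_s = unname(cf["tau"]), asym = unname(cf["asym"]),
       delta = unname(cf["delta"]), converged = TRUE, flagged = FALSE,
       reason = NULL)
}
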