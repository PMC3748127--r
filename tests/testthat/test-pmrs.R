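test_that("binning produces 18 bins conserving the 768 FIDs", {
  prot <- mrs_protocol()
  expect_equal(sum(prot$bins$n_fids), 768L)
  expect_equal(nrow(prot$bins), 18L)
  expect_equal(as.vector(table(prot$bins$phase)[c("rest", "stim", "recovery")]),
               c(1L, 6L, 11L))
  # stimulation bins have ~60 s temporal resolution
  expect_equal(unique(prot$bins$width_s[prot$bins$phase == "stim"]),
               32 * 1.875)
  # identical unit FIDs: rest bin amplitude is 64x a single FID
  raw <- matrix(1 + 0i, nrow = 64, ncol = 768)
  ser <- bin_fids(raw, prot)
  expect_equal(ser$bins[[1]], rep(64 + 0i, 64))
  expect_true(all(diff(ser$meta$t_mid_s) > 0))
  expect_error(bin_fids(raw[, 1:700], prot), "expected 768")
})

test_that("spectral fitting recovers a single damped sinusoid exactly", {
  fid <- synth_fid(data.frame(f_hz = 0, amp = 100, damp_hz = 10))
  pr <- default_prior_31p()[1, ]
  f <- fit_spectrum(fid, prior = pr, restarts = 1)
  expect_lt(abs(f$amplitude - 100), 1e-6)
  expect_lt(abs(f$damp_hz - 10), 1e-6)
  expect_lt(abs(f$f_hz), 1e-6)
  expect_true(attr(f, "converged"))
  expect_error(fit_spectrum(complex(real = numeric(64))), "zero")
})

test_that("two peaks 30 Hz apart match a dense grid-search oracle", {
  pr <- two_peak_prior(0, 30 / 81.08, window = 0.1)
  truth <- data.frame(f_hz = c(0, 30), amp = c(80, 50), damp_hz = c(12, 12))
  fid <- synth_fid(truth)
  set.seed(5)
  fid <- fid + complex(real = rnorm(2048, 0, 1), imaginary = rnorm(2048, 0, 1))
  fit <- fit_spectrum(fid, prior = pr, restarts = 2)
  # oracle: exhaustive amplitude grid at the true frequencies/dampings
  t <- (0:2047) / 8000
  b1 <- exp(-12 * t); b2 <- exp(-12 * t) * exp(2i * pi * 30 * t)
  rss <- function(a1, a2) sum(Mod(a1 * b1 + a2 * b2 - fid)^2)
  grid <- expand.grid(a1 = seq(76, 84, by = 0.05), a2 = seq(46, 54, by = 0.05))
  best <- grid[which.min(mapply(rss, grid$a1, grid$a2)), ]
  expect_lt(abs(fit$amplitude[1] / best$a1 - 1), 0.01)
  expect_lt(abs(fit$amplitude[2] / best$a2 - 1), 0.01)
})

test_that("PCr/ATP ratio is recovered within 3% at SNR 50", {
  kin <- mrs_kinetics(pcr_atp_ratio = 3.5, noise_sigma = 2)  # sigma = 100/50
  errs <- sapply(1:5, function(s) {
    rs <- simulate_rest_spectrum(kin, seed = s)
    pcr_atp_ratio(fit_spectrum(rs$bins[[1]])) / 3.5 - 1
  })
  expect_true(all(abs(errs) < 0.03))
})

test_that("pH calibration matches its closed form and inverts exactly", {
  expect_equal(compute_phi(4.48), 6.75)
  expect_equal(compute_phi(4.60),
               6.75 + log10((4.60 - 3.27) / (5.69 - 4.60)), tolerance = 1e-12)
  expect_equal(round(compute_phi(4.60), 4), 6.8364)
  expect_equal(compute_phi(phi_to_delta(7.06)), 7.06, tolerance = 1e-12)
  ph <- seq(6.4, 7.4, by = 0.01)
  expect_lt(max(abs(compute_phi(phi_to_delta(ph)) - ph)), 1e-12)
  d <- phi_to_delta(ph)
  expect_true(all(diff(d) > 0))  # strictly monotonic calibration
  expect_error(compute_phi(3.27), "calibration")
  expect_error(compute_phi(5.7), "calibration")
})

test_that("time course is expressed as percent of rest with mirrored Pi", {
  kin <- mrs_kinetics(pcr_end_stim_pct = 60, noise_sigma = 0)
  ser <- simulate_mrs_series(kin)
  rest_fit <- fit_spectrum(simulate_rest_spectrum(kin)$bins[[1]])
  tc <- build_time_course(ser, rest_fit = rest_fit, restarts = 1)
  expect_equal(tc$pcr_pct[tc$phase == "rest"], 100, tolerance = 1e-6)
  # end-stimulation bin near the configured depletion level
  expect_equal(tc$pcr_pct[7], ser$meta$pcr_pct_true[7], tolerance = 1e-4)
  expect_lt(abs(tc$pcr_pct[7] - 60), 1)
  # Pi mirrors PCr: amplitude-units sum conserved within fit tolerance
  pcr_amp <- tc$pcr_pct
  pi_amp <- tc$pi_pct * kin$pi_rest_frac
  expect_lt(max(abs(pcr_amp + pi_amp - (100 + 100 * kin$pi_rest_frac))), 0.01)
  # fitted pH tracks the generator truth
  expect_lt(max(abs(tc$phi - ser$meta$ph_true)), 0.005)
  expect_equal(attr(tc, "pcr_atp"), 3.5, tolerance = 1e-6)
  ser2 <- ser; ser2$meta$phase[1] <- "stim"
  expect_error(build_time_course(ser2), "rest bin")
})

test_that("identical bins give a flat 100% time course", {
  kin <- mrs_kinetics()
  rest <- simulate_rest_spectrum(kin, n_acq = 1L)
  ser <- simulate_mrs_series(kin)
  for (i in seq_along(ser$bins)) ser$bins[[i]] <- rest$bins[[1]] * ser$meta$n_fids[i]
  tc <- build_time_course(ser, restarts = 1)
  expect_equal(tc$pcr_pct, rep(100, 18), tolerance = 1e-6)
  expect_equal(tc$pi_pct, rep(100, 18), tolerance = 1e-6)
})

test_that("monoexponential recovery fitting recovers tau", {
  prot <- mrs_protocol()
  mids <- prot$bins$t_mid_s[prot$bins$phase == "recovery"]
  t0 <- prot$stim_end_s
  # noiseless: tau = 159 exactly
  y <- 100 - 40 * exp(-(mids - t0) / 159)
  fit <- fit_pcr_recovery(mids, y, t0_s = t0)
  expect_equal(fit$tau_s, 159, tolerance = 1e-9)
  expect_equal(fit$asym, 100, tolerance = 1e-9)
  # flat recovery: flagged, not an error
  flat <- fit_pcr_recovery(mids, rep(80, 11), t0_s = t0)
  expect_true(flat$flagged)
  expect_true(is.na(flat$tau_s))
  expect_error(fit_pcr_recovery(mids[1:3], y[1:3]), ">= 4")
})

test_that("tau fitting at 2% noise agrees with a grid-search oracle", {
  prot <- mrs_protocol()
  mids <- prot$bins$t_mid_s[prot$bins$phase == "recovery"]
  t0 <- prot$stim_end_s
  taus <- sapply(1:50, function(s) {
    set.seed(s)
    y <- 100 - 40 * exp(-(mids - t0) / 159) + rnorm(11, 0, 2)
    fit_pcr_recovery(mids, y, t0_s = t0)$tau_s
  })
  expect_lt(abs(mean(taus) / 159 - 1), 0.05)
  # grid oracle on one noisy realization: asym/delta solved linearly per tau
  set.seed(7)
  y <- 100 - 40 * exp(-(mids - t0) / 159) + rnorm(11, 0, 2)
  tau_grid <- seq(80, 280, by = 0.25)
  rss <- sapply(tau_grid, function(tau) {
    X <- cbind(1, -exp(-(mids - t0) / tau))
    sum(lm.fit(X, y)$residuals^2)
  })
  tau_oracle <- tau_grid[which.min(rss)]
  expect_equal(fit_pcr_recovery(mids, y, t0_s = t0)$tau_s, tau_oracle,
               tolerance = 0.25 / tau_oracle + 1e-4)
})

test_that("fit residuals on simulated spectra are white", {
  kin <- mrs_kinetics(noise_sigma = 2)
  pvals <- sapply(1:10, function(s) {
    rs <- simulate_rest_spectrum(kin, seed = 100 + s)
    f <- fit_spectrum(rs$bins[[1]], restarts = 1)
    r <- attr(f, "residuals")[1:2048]   # real channel
    stats::Box.test(r, lag = 20, type = "Ljung-Box")$p.value
  })
  # at a 5% level, rejections should be rare if residuals carry no structure
  expect_lte(sum(pvals < 0.05), 2L)
})

test_that("time-domain model and spectrum agree (Parseval check)", {
  kin <- mrs_kinetics(noise_sigma = 2)
  rs <- simulate_rest_spectrum(kin, seed = 9)
  f <- fit_spectrum(rs$bins[[1]], restarts = 1)
  res <- attr(f, "residuals")
  resid_energy <- sum(res^2)
  noise_energy <- 2048 * 2 * (2 * sqrt(12))^2  # E[sum of squares] per channel
  expect_lt(resid_energy, 1.2 * noise_energy)
})
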