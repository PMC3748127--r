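test_that("tetanus metrics match their closed forms on noiseless traces", {
  # half relaxation = relax_tau * ln 2 exactly
  sp <- force_protocol_spec(frequencies_hz = 150, relax_tau_s = 0.262 / log(2))
  rec <- simulate_force_protocol(sp)
  tm <- train_metrics(rec)
  expect_equal(tm$half_relaxation_ms, 262, tolerance = 1e-6)
  # peak equals the Hill amplitude times the rise saturation
  pk_true <- sp$f_max_mN * 150^3 / (150^3 + 40^3)
  expect_equal(tm$peak_force_mN, pk_true * (1 - exp(-sp$rise_k_per_s * 0.75)),
               tolerance = 1e-9)
  expect_error(train_metrics(rec, train = 3), "no train")
})

test_that("max rate of force development is recovered within 2%", {
  # choose k so the true max slope at the 150 Hz train is 3.15 mN/ms
  pk <- 300 * 150^3 / (150^3 + 40^3)
  sp <- force_protocol_spec(frequencies_hz = 150, f_max_mN = 300,
                            rise_k_per_s = 3.15 * 1000 / pk)
  rec <- simulate_force_protocol(sp)
  tm <- train_metrics(rec)
  expect_lt(abs(tm$max_dfdt_mN_per_ms / 3.15 - 1), 0.02)
  # discrete vs analytic derivative of the raw waveform: within one sample
  d_raw <- max(diff(rec$force_mN)) * sp$sample_rate_hz / 1000
  expect_lt(abs(d_raw - 3.15), 3.15 * sp$rise_k_per_s / sp$sample_rate_hz)
})

test_that("Hill force-frequency fit is exact on exact Hill data", {
  f <- c(1, 10, 20, 40, 60, 80, 100, 150)
  pk <- data.frame(frequency_hz = f,
                   peak_force_mN = 300 * f^3 / (f^3 + 40^3))
  fit <- fit_force_frequency(pk)
  expect_equal(fit$f_max_mN, 300, tolerance = 1e-6)
  expect_equal(fit$f50_hz, 40, tolerance = 1e-6)
  expect_equal(fit$hill_n, 3, tolerance = 1e-6)
  # F(f50) = F_max / 2 under the fitted model, by construction
  expect_equal(fit$f_max_mN * fit$f50_hz^fit$hill_n /
                 (fit$f50_hz^fit$hill_n + fit$f50_hz^fit$hill_n),
               fit$f_max_mN / 2, tolerance = 1e-9)
  flat <- fit_force_frequency(data.frame(frequency_hz = f,
                                         peak_force_mN = rep(100, 8)))
  expect_true(flat$flagged)
  expect_error(fit_force_frequency(pk[1:3, ]), ">= 4")
})

test_that("f50 recovery at 2% noise agrees with a grid-search oracle", {
  f <- c(1, 10, 20, 40, 60, 80, 100, 150)
  truth <- 300 * f^3 / (f^3 + 40^3)
  f50s <- sapply(1:50, function(s) {
    set.seed(s)
    pk <- data.frame(frequency_hz = f,
                     peak_force_mN = truth + rnorm(8, 0, 6))
    fit_force_frequency(pk)$f50_hz
  })
  expect_lt(abs(mean(f50s) / 40 - 1), 0.05)
  # oracle on one realization: (f50, n) grid with F_max solved linearly
  set.seed(3)
  y <- truth + rnorm(8, 0, 6)
  grid <- expand.grid(f50 = seq(30, 50, by = 0.1), n = seq(2, 4.5, by = 0.02))
  rss <- mapply(function(f50, n) {
    h <- f^n / (f^n + f50^n)
    fm <- sum(y * h) / sum(h^2)
    sum((y - fm * h)^2)
  }, grid$f50, grid$n)
  oracle <- grid$f50[which.min(rss)]
  set.seed(3)
  pk <- data.frame(frequency_hz = f, peak_force_mN = truth + rnorm(8, 0, 6))
  expect_equal(fit_force_frequency(pk)$f50_hz, oracle, tolerance = 0.005)
})

test_that("relative force-frequency curve is scale invariant", {
  f <- c(1, 10, 20, 40, 60, 80, 100, 150)
  pk <- data.frame(frequency_hz = f, peak_force_mN = 300 * f^3 / (f^3 + 40^3))
  r1 <- fit_force_frequency(pk)$peaks$relative
  pk2 <- pk; pk2$peak_force_mN <- pk$peak_force_mN * 3.7
  r2 <- fit_force_frequency(pk2)$peaks$relative
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("fatigue analysis bins twitch peaks over 15 s windows", {
  sp <- force_protocol_spec(mode = "fatigue")
  rec <- simulate_force_protocol(sp)
  fs <- fatigue_summary(rec, volume_mm3 = 107)
  expect_equal(fs$n_bins, 24L)
  expect_length(fs$twitch_peaks_mN, 612L)
  # peak detection recovers every scheduled stimulus on a noiseless trace
  expect_true(all(fs$twitch_peaks_mN > 0))
  # bin means equal the within-bin average of the generator schedule
  sched <- rec$schedule
  bin <- floor((sched$stim_times_s - sched$stim_times_s[1]) / 15)
  truth_means <- as.numeric(tapply(sched$amp_true_mN, bin, mean))
  expect_lt(max(abs(fs$bin_means_mN / truth_means - 1)), 0.005)
  expect_equal(fs$bin_means_specific, fs$bin_means_mN / 107, tolerance = 1e-12)
  # constant amplitude schedule: every bin mean equals the amplitude
  spc <- force_protocol_spec(mode = "fatigue", fatigue_plateau_frac = 1,
                             twitch_amplitude_mN = 60)
  fsc <- fatigue_summary(simulate_force_protocol(spc))
  expect_equal(fsc$bin_means_mN, rep(60, 24), tolerance = 1e-6)
})

test_that("specific force is elementwise division by volume", {
  expect_equal(specific_force(300, 1), 300)
  expect_equal(specific_force(300, 107), 300 / 107)
  expect_equal(specific_force(c(10, 20), 50), c(0.2, 0.4))
  expect_equal(specific_force(300, 2 * 107), specific_force(300, 107) / 2)
  expect_error(specific_force(300, 0), "positive")
  expect_error(specific_force(300, -3), "positive")
})
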