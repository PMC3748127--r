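#!/usr/bin/env Rscript
# Dynamic 31P-MRS arm: simulate the rest/stimulation/recovery protocol for
# both groups at a realistic per-FID SNR, quantify every bin with the
# prior-knowledge time-domain fit, and extract PCr/Pi/pHi time courses,
# resting PCr/ATP and tauPCr.
#
# Findings (seed 1): fitted PCr/Pi time courses track the generator truth to
# well under 1% of rest, pHi to ~0.01 units, and tauPCr is recovered within
# a few percent for both groups at this SNR.

suppressPackageStartupMessages(library(myomri))
dir.create("results", showWarnings = FALSE)
seed <- 1L

summary_rows <- list()
for (grp in c("wt", "tg")) {
  p <- group_preset(grp)
  kin <- mrs_kinetics(tau_recovery_s = p$tau_pcr_s, ph_rest = p$ph_rest,
                      pcr_atp_ratio = p$pcr_atp, noise_sigma = 1)  # SNR 100
  ser <- simulate_mrs_series(kin, seed = seed)
  rest_fit <- fit_spectrum(simulate_rest_spectrum(kin, seed = seed + 1L)$bins[[1]],
                           seed = seed)
  tc <- build_time_course(ser, rest_fit = rest_fit, seed = seed)
  rec <- tc[tc$phase == "recovery", ]
  tau <- fit_pcr_recovery(rec$t_mid_s, rec$pcr_pct,
                          t0_s = ser$protocol$stim_end_s)
  out <- cbind(group = toupper(grp), tc,
               pcr_pct_true = ser$meta$pcr_pct_true,
               pi_pct_true = ser$meta$pi_pct_true,
               ph_true = ser$meta$ph_true)
  write.csv(out, sprintf("results/mrs_timecourse_%s.csv", grp),
            row.names = FALSE)
  summary_rows[[grp]] <- data.frame(
    group = toupper(grp),
    pcr_atp = attr(tc, "pcr_atp"), pcr_atp_truth = p$pcr_atp,
    phi_rest = tc$phi[tc$phase == "rest"], phi_truth = p$ph_rest,
    tau_pcr_s = tau$tau_s, tau_truth_s = p$tau_pcr_s)
}
sm <- do.call(rbind, summary_rows)
write.csv(sm, "results/mrs_summary.csv", row.names = FALSE)
print(sm, digits = 4, row.names = FALSE)
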