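#!/usr/bin/env Rscript
# Imaging arm of the pipeline on the digital hindlimb phantom: for each study
# group, simulate the three MR acquisitions at study noise levels, run the
# analyzers, and tabulate recovered vs ground-truth values.
#
# Findings (seed 1): every ROI statistic lands within ~1% of its ground
# truth (fat percentage within 0.01 percentage points), and the anatomy
# measures reproduce the preset CSA/volume to raster precision.

suppressPackageStartupMessages(library(myomri))
dir.create("results", showWarnings = FALSE)
seed <- 1L

rows <- list()
for (grp in c("wt", "tg")) {
  p <- group_preset(grp)
  gt <- build_phantom(hindlimb_phantom(grp, rng_seed = seed))
  post <- gt$label == 1L

  # 3-point Dixon at SNR 200: fat percentage + anatomy from the water image
  fw <- separate_fat_water(simulate_dixon(gt, noise_sigma = 1 / 200, seed = seed))
  an <- measure_anatomy(fw$water, gt$voxel_dims_mm, n_slices = 4L)
  fat <- fat_percentage(fw, an$mask, n_slices = 4L)

  # multi-echo T2 at SNR 100, posterior-ROI mean over the 3 largest slices
  t2 <- roi_mean_t2(fit_t2_map(simulate_multiecho_t2(
    gt, noise_sigma = 1 / 100, seed = seed)), post)

  # DTI at SNR 100, eigenvalues / ADC / FA in the posterior ROI
  dti <- roi_mean_metrics(tensor_metrics(fit_tensor(simulate_dwi(
    gt, noise_sigma = 1 / 100, seed = seed))), post)

  rows[[grp]] <- data.frame(
    group = toupper(grp),
    variable = c("fat_pct", "max_csa_mm2", "volume_mm3", "t2_ms",
                 "lambda1", "lambda2", "lambda3", "adc", "fa"),
    truth = c(p$fat_pct, p$max_csa_mm2, p$volume_mm3, p$t2_ms,
              p$lambda_um2_ms, adc_from_eigenvalues(p$lambda_um2_ms),
              fa_from_eigenvalues(p$lambda_um2_ms)),
    recovered = c(fat, an$max_csa_mm2, an$volume_mm3, t2, dti))
}
tab <- do.call(rbind, rows)
tab$rel_err_pct <- 100 * (tab$recovered / tab$truth - 1)
write.csv(tab, "results/imaging_recovery.csv", row.names = FALSE)
print(tab, digits = 4, row.names = FALSE)
cat(sprintf("\nmax |relative error| %.2f%% (fat pct compared absolutely: %+.4f pp)\n",
            max(abs(tab$rel_err_pct[tab$variable != "fat_pct"])),
            max(abs(tab$recovered[tab$variable == "fat_pct"] -
                      tab$truth[tab$variable == "fat_pct"]))))
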