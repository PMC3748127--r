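# myomri

Noninvasive phenotyping of mouse hindlimb muscle, as a tested and reusable R
pipeline. The package targets the combined readout used to characterize
nemaline-myopathy mouse models in vivo:

* **Anatomy and fat** — three-point Dixon gradient-echo imaging; per voxel
  the percentage fat is `100 * SI_fat / (SI_fat + SI_water)`, the maximal
  cross-sectional area (mm²) comes from the largest slice of the water image
  and the hindlimb volume (mm³) from the consecutive largest slices.
* **Microstructure** — pixel-wise T2 mapping by ordinary least squares on
  `log S(TE) = log S0 − TE/T2`, and diffusion-tensor metrics (λ1 ≥ λ2 ≥ λ3,
  ADC = (λ1+λ2+λ3)/3, FA) from a Stejskal–Tanner acquisition
  (`S = S0 exp(−b gᵀDg)`, b = 450 s/mm², 12 directions), both averaged over a
  posterior-muscle ROI on the three largest slices.
* **Energetics** — dynamic ³¹P spectroscopy over a rest/stimulation/recovery
  protocol (768 FIDs binned into 18 spectra), quantified by prior-knowledge
  time-domain fitting (AMARES-style: multiplet ratios, J-coupling and
  frequency windows imposed by parameterization); PCr and Pi time courses as
  % of rest, intracellular pH from the Pi–PCr shift via
  `pH = 6.75 + log10((δ − 3.27)/(5.69 − δ))`, resting PCr/ATP, and the PCr
  recovery time constant τPCr from a monoexponential fit.
* **Function** — evoked-force analysis: per-train peaks, Hill
  force–frequency fit `F(f) = F_max fⁿ/(fⁿ + f50ⁿ)`, maximal rate of force
  development and half relaxation time from the 150 Hz tetanus, 15-s fatigue
  binning, and specific force (mN/mm³).

Because no raw data are deposited, the package ships a digital hindlimb
phantom and signal generators for every acquisition (`hindlimb_phantom()`,
`simulate_dixon()`, `simulate_multiecho_t2()`, `simulate_dwi()`,
`simulate_mrs_series()`, `simulate_force_protocol()`), each exposing its
ground truth so that every analyzer is validated by parameter recovery.
Group presets (`group_preset("wt")`, `group_preset("tg")`) carry the two
study conditions.

## Worked example

Recover the transgenic group's muscle T2 from a noisy synthetic acquisition,
and quantify a resting ³¹P spectrum:

```r
library(myomri)

gt <- build_phantom(hindlimb_phantom("tg"))        # truth: posterior T2 = 19.8 ms
me <- simulate_multiecho_t2(gt, tes_ms = c(8, 12, 16, 20, 24),
                            noise_sigma = 1/100, seed = 7)   # SNR 100
roi_mean_t2(fit_t2_map(me), gt$label == 1L)
#> [1] 19.80922

kin <- mrs_kinetics(pcr_atp_ratio = 3.5, ph_rest = 7.06, noise_sigma = 2)
rs  <- simulate_rest_spectrum(kin, seed = 7)        # SNR 50
fit <- fit_spectrum(rs$bins[[1]])
pcr_atp_ratio(fit)
#> [1] 3.498793
compute_phi(fit$ppm[fit$name == "Pi"] - fit$ppm[fit$name == "PCr"])
#> [1] 7.060204
```

The T2 ROI mean lands within 0.05% of the 19.8 ms ground truth, the fitted
PCr/ATP within 0.1% of the generated 3.5, and the pH read back from the
fitted Pi shift within 0.001 units of the generated 7.06.

The numbered scripts under `analysis/` run the full arms of the study design
(imaging recovery, dynamic MRS, force protocols, cohort statistics) and write
their tables under `results/`:

```sh
Rscript analysis/01_phantom_imaging.R
Rscript analysis/02_dynamic_mrs.R
Rscript analysis/03_force.R
Rscript analysis/04_cohort.R
```

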