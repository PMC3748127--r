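---
title: "Noninvasive muscle phenotyping: models, simulators and analyzers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive muscle phenotyping: models, simulators and analyzers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomri)
```

## Scope

`myomri` re-implements, as a tested pipeline, the noninvasive phenotyping of
mouse hindlimb muscle used to characterize a nemaline-myopathy model: Dixon
fat/water imaging with muscle anatomy, multi-echo T2 mapping, diffusion-tensor
metrics, dynamic phosphorus spectroscopy, and evoked-force analysis. No raw
animal data are available, so a digital hindlimb phantom and signal generators
stand in for the scanner and the ergometer; every generator exposes its ground
truth so that each analyzer can be validated by parameter recovery. This
vignette records the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data do and do not establish.

## The digital hindlimb phantom

`hindlimb_phantom()` builds a 128 x 128 x 7 voxel phantom over a 2 x 2 cm
field of view with 1 mm slices (in-plane voxel 0.156 mm). Compartments are
per-slice ellipses: a posterior and an anterior muscle belly (60/40 split of
the muscle cross section) tapering along the leg, a subcutaneous-fat annulus,
and a small bone ellipse. The taper is chosen so that the largest analytic
muscle cross section equals the group's maximal CSA and the four consecutive
largest slices sum to the group volume (37.2 mm^2 / 107 mm^3 for wild type,
32.0 mm^2 / 92 mm^3 for the transgenic condition). Anatomical realism beyond
these ROI-level statistics is deliberately not attempted: the analyses only
consume ROI means, areas and volumes.

Per-compartment ground truth: proton density, fat fraction, T2, the diffusion
tensor (eigenvalues in 10^-3 mm^2/s plus a principal fiber axis, along the
leg by default), and a B0 offset in Hz. Group presets (`group_preset()`)
carry the two conditions' reference values: muscle T2 18.8 / 19.8 ms, fat fraction 0.09% / 0.19%,
eigenvalues (1.95, 1.45, 1.07) / (1.88, 1.34, 1.00) x 10^-3 mm^2/s.

Noise in all MR simulators is independent complex Gaussian per channel, so
magnitude images are Rician; at the signal-to-noise ratios used throughout
(SNR 100-200 in muscle) the Gaussian approximation of the magnitude noise is
excellent and ROI means are effectively unbiased. "SNR" here always means
(muscle signal)/(per-channel noise sd). Seeds are mandatory arguments; there
is no hidden global RNG state, and identical spec + seed gives bit-identical
output.

## Dixon fat/water imaging

Three gradient echoes are generated at idealized water-fat phase angles 0,
pi, 2 pi (in, opposed, in phase):

S_n = (W + F e^{i theta_n}) e^{2 pi i psi TE_n},  W = rho (1 - FF),  F = rho FF,

with psi the local field offset. The scanner's literal echo times
(1.5/1.8/2.1 ms at 11.75 T) correspond to water-fat phase increments of about
189 degrees rather than exactly 180; since the analysis treats the echoes as
in/opposed/in phase, the generator adopts the idealized phases and keeps the
literal echo times only for the field-offset ramp. The analyzer estimates the
inter-echo field phase from the in-phase pair, phi = Arg(S1* S3)/2, assumed
within (-pi/2, pi/2] per voxel — no spatial unwrapping, which suffices for
the phantom's small offsets (tens of Hz); real-data use would add spatial
unwrapping at this point. After demodulation, W = (|S1| + S2c)/2 and
F = (|S1| - S2c)/2 with S2c the phase-corrected opposed-echo real part.

Two deliberate choices:

* The `fat_fraction` map is clamped to [0, 1] (with the clamp count
  reported), but the ROI fat percentage averages the raw per-voxel
  100 F/(F + W): clamping rectifies zero-mean noise and would bias a
  near-zero fat fraction upward by an order of magnitude at these SNRs.
* Muscle segmentation for CSA/volume thresholds the water image at 50% of
  the median bright-voxel intensity and keeps all 6-connected components at
  least half the size of the largest. A single-largest-component rule would
  amputate the anterior belly, which is anatomically separate from the
  posterior one in the phantom (and in a real leg cross section muscles form
  several bellies).

The printed methods describe the volume as "the sum of the four CSAs of the
five consecutive largest slices", which is internally inconsistent (four vs
five); the implementation sums the `n_slices` consecutive largest CSAs with
`n_slices = 4` by default, which reproduces the reported volumes given the
reported maximal CSAs.

## T2 mapping

Pixel-wise ordinary least squares of log S(TE) on TE (log S = log S0 - TE/T2),
unweighted — deliberately the simplest estimator consistent with the model. Voxels with any nonpositive echo
are flagged invalid rather than offset (the log is undefined and offsets bias
T2), as are voxels with a nonnegative slope. A nonlinear fit is kept in the
test suite as an oracle only. ROI statistics average valid voxels in the
posterior-muscle ROI over the three slices with the largest sections. At SNR
100 with echoes 8-24 ms the residual Rician bias is below 0.1% of T2.

## Diffusion tensor imaging

Signals follow the Stejskal-Tanner form S = S0 exp(-b g' D g) at b = 450
s/mm^2 along 12 directions plus one b = 0 volume; fat signal is absent (the
acquisitions are fat-suppressed). No single 12-direction set is canonical,
so the package freezes a 12-direction set spread by antipodally
symmetric electrostatic repulsion (`dti_directions()`); its tensor design has
condition number < 1.6. The estimator is unweighted log-linear least squares
with design rows (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz) — deterministic and
sufficient at this single b-value. Eigenvalues (sorted descending, no
orientation tracking), ADC = trace/3 and FA are computed analytically per
voxel; negative eigenvalues that noise can produce are counted but not
clamped, to avoid biasing ROI means.

## Dynamic 31P spectroscopy

The protocol layout is fixed by `mrs_protocol()`: a fully relaxed rest
spectrum (12 accumulations, TR 20 s), then 768 FIDs at TR 1.875 s — 64 at
rest (one bin), 192 during stimulation in packets of 32 (~60 s resolution),
and 512 in recovery (7 x 32, 3 x 64, 1 x 96), i.e. 18 protocol bins. Bin
timestamps are packet midpoints, which is unbiased for monoexponential
fitting at these widths. Binning is coherent complex summation; per-FID
normalization happens when time courses are expressed as percent of rest.

FIDs are sums of damped sinusoids at 2048 points / 8 kHz: PCr (reference,
0 ppm), Pi at the pH-dependent shift, and the ATP multiplets — gamma and
alpha 1:1 doublets at -2.48 and -7.52 ppm, beta a 1:2:1 triplet at -16.26
ppm, J = 16.5 Hz, at 81.08 MHz (31P at 4.7 T). These shifts and the coupling are the standard in vivo muscle literature
values at this field strength.
The kinetic model: PCr falls monoexponentially during stimulation to
`pcr_end_stim_pct` (default 60% of rest, with a 50 s depletion constant — a
rapid fall to a steady state, matching the described time course) and
recovers monoexponentially with time constant tauPCr; Pi mirrors PCr so that
PCr + Pi is constant in amplitude units; pH falls linearly from its resting
value to `ph_end` (default 6.80, a moderate end-exercise acidosis) during
stimulation and recovers with tauPCr. Bin amplitudes are exact time averages
of this model over each bin's acquisition window (closed form, verified
against quadrature in the tests); bin pH is evaluated at the midpoint since
it varies slowly within a bin.

Quantification is nonlinear least squares in the time domain with prior
knowledge imposed by parameterization, not penalties: per metabolite one
amplitude, one center frequency bounded to a window around its nominal
shift, one damping shared across multiplet lines with fixed 1:1 / 1:2:1
ratios and J-spacing, plus a single zero-order phase. Windows are +/-0.2 ppm
except Pi, whose window is +/-0.55 ppm around 4.60 ppm because the pH-driven
shift must be trackable over pH ~6.4-7.3. Starting frequencies come from
multiplet-template matching on the FFT magnitude spectrum (a bare peak pick
would sit J/2 off a doublet center); starting amplitudes and phase from a
complex linear solve; the optimizer (Levenberg-Marquardt with an analytic
Jacobian) restarts from deterministically perturbed initializations and
keeps the best residual. Non-convergence returns a flagged result with
diagnostics rather than an exception. Uncertainties are Cramer-Rao-style,
from the residual variance and the Gauss-Newton Hessian at the solution.

pH follows the Henderson-Hasselbalch calibration of the Pi-PCr shift with
pKa 6.75 and endpoints 3.27 / 5.69 ppm, the standard constants for this
calibration. pH is reported only
when the fitted Pi amplitude exceeds twice its uncertainty. The PCr/ATP
ratio uses the beta-ATP amplitude from the fully relaxed spectrum only; no
saturation correction is applied to the dynamic bins because all dynamic
quantities are percentages of a rest bin acquired at the same TR.

tauPCr is fitted as PCr(t) = asym - delta exp(-(t - t0)/tau) over the 11
recovery bins with t0 the end of stimulation; percent-of-rest and raw
amplitudes give identical tau. A flat recovery (delta below 1% of the
asymptote) leaves tau unidentifiable and is returned flagged. One bias worth
recording: when the fit consumes *window-averaged* bins (the realistic
case), tau is attenuated by ~0.1% relative to point sampling at midpoints —
far below the noise floor, but visible in noiseless round trips.

## Evoked force

The generator produces 0.75 s tetanic trains (30 s rest) at 1-150 Hz and a
6-min 1.7 Hz twitch protocol at 10 kHz sampling. A train rises as
F_peak (1 - e^{-kt}) and relaxes as F_end e^{-t/tau_rel}; per-train peaks
follow a Hill curve F_max f^n/(f^n + f50^n) (defaults F_max 300 mN, f50 40
Hz, n 3 — f50 placed mid-range of the tested frequencies; no numeric f50 reference
exists, so it is a free generator choice). The
true maximal rate of force development is F_peak k and the true half
relaxation time is tau_rel ln 2, giving closed-form targets for the
analyzers. Twitches are (t/tc) e^{1 - t/tc} pulses (time-to-peak tc = 20 ms)
whose amplitudes follow a configurable decline schedule, by default an
exponential fall to a 50% plateau with a 60 s constant; only the binned summary of
the decline, not its shape, is analyzed downstream.

Analysis choices: baseline is the median of the 50 ms before each train.
The derivative is a centered difference after a moving average
(`deriv_smooth_ms`, default 1 ms; ~10 ms is appropriate at percent-level
noise), with samples whose smoothing window is incomplete excluded — raw
derivatives of noisy traces are unusable, so some smoothing choice is
unavoidable. Half relaxation is measured from the post-train force maximum to
50% of the decline toward baseline, with linear interpolation at the
crossing; the peak-time search starts at the end of stimulation because the
tetanic plateau is nearly flat and noise would otherwise drag the detected
peak time into the plateau and lengthen the half-relaxation estimate. The
Hill fit uses the zero-offset form above — forced by the definition of f50
as the frequency of half-*maximal* force — with F_max, f50 and the exponent
free. Fatigue analysis averages per-twitch peaks over consecutive 15 s bins
(24 bins for 6 min) and divides by the hindlimb volume for specific force
(mN/mm^3).

## Cohort statistics

`cohort_table()` collects one value per animal and variable; summaries are
mean +/- SEM, percent differences relative to the reference group (reported
rounded to integers, the convention for such contrasts), two-sided equal-variance
t-tests (Student's form, the default reading of an unpaired t-test when no
variance heterogeneity is claimed), and Pearson correlations.
Repeated-measures ANOVA and post-hoc machinery are out of scope; the
pipeline emits tidy per-bin tables for external statistics instead.

## Problem sizes and determinism

The test suite and the acceptance script run the full 128 x 128 x 7 phantom
for Dixon and T2, a 48 x 48 x 7 phantom where many seeds are needed, 50-seed
Monte Carlo loops for the tau and Hill fits, and single 2048-point spectral
fits — sizes chosen so each check completes in seconds while keeping ROI
sampling error far below the tolerances being asserted. All stochastic steps
take explicit seeds.

## What the synthetic data do not show

The phantom establishes correctness of the estimators (round-trip exactness,
known-truth recovery, invariances), not fidelity to mouse anatomy or
physiology. It omits k-space/EPI artifacts, multi-peak fat spectra, T2*
decay across Dixon echoes, B1 inhomogeneity, partial-volume mixtures at
compartment borders, motion, and any systematic error shared by simulator
and analyzer by construction (the same signal equations). The in vivo group
contrasts — the 30% absolute force deficit, the +5% T2 shift and the
eigenvalue reductions as *biological findings* — cannot be reproduced
without animals; they live in the group presets as generator inputs, and
only printed arithmetic (percent differences, eigenvalue/ADC/FA consistency)
and synthetic parameter recovery are asserted.
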