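---
title: "Measuring replication fork stalling and restart from live-cell movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring replication fork stalling and restart from live-cell movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifork)
```

## The measurement problem

During S phase, PCNA (the replicative sliding clamp) and RPA (the
ssDNA-binding complex) concentrate in nuclear replication foci. When
nucleotide depletion (e.g. hydroxyurea, HU) stalls replication forks, PCNA
leaves the foci within minutes, while RPA gradually accumulates on the
ssDNA exposed by continued unwinding; washing the drug out reverses both.
Foci are numerous, crowded and variable in shape, so summing focal
intensity directly is unreliable. `replifork` instead quantifies the
*freely diffusing* pool: because the total nuclear amount of each protein
is conserved on the timescale of one movie, any protein that leaves the
foci must appear in the diffuse pool, and vice versa.

## The diffuse-pool model

Three ROI classes are measured per frame: the nucleus (A), one to three
small nuclear regions that never contain foci (B), and an extracellular
background region (C). With `mean(B)` and `mean(C)` the per-frame region
means,

* `D_t = mean(B)_t − mean(C)_t` — background-corrected diffuse intensity;
* `T_ref = mean(D_t)` over a *reference window* in which the entire pool
  diffuses freely;
* `E_t = T_ref − D_t` — intensity bound at foci;
* `F_t = E_t / T_ref` — fraction of the total nuclear pool bound at foci;
* `nE_t = E_t / max(5-frame moving average of E_t)` — max-normalized bound
  intensity.

The reference window is the one modelling decision that matters. For a
decay-type (PCNA-like) channel the pool is fully free only after focus
dissolution, so the default window is 10–15 min after treatment; for a
rise-type (RPA-like) channel it is the pre-treatment baseline, when no
RPA foci are visible. Any protein still bound during the reference window
biases `T_ref` low; with a 2.1 min dissolution half-time the residual
10–15 min after treatment is below 1% of the pool, which is the dominant
(and acceptably small) systematic of the method. An optional
`pool_correction` factor on `T_ref` is exposed for cases where the
residual is known; the default (1.0) applies no correction. Negative
`E_t` values arising from noise are deliberately retained, not clamped,
so that population averages stay unbiased.

`nE_t` is normalized by the maximum of a 5-frame moving average rather
than the raw maximum so that a single noise spike cannot define the
normalization. As a consequence `max(nE_t) = 1` holds exactly only when
the trace maximum sits on a plateau (the realistic shape for both
channels here); on a strictly monotone noisy trace the raw maximum can
slightly exceed 1.

## From fractions to molecules

With proteome copy numbers for the imaged line (defaults: HeLa, ~2.6 M
PCNA molecules = 865,300 homotrimers; 926,424 RPA heterotrimers) and
~4000 concurrently active forks, the bound fraction converts to
complexes per fork, `G_t = F_t · N / 4000`, and for RPA to ssDNA
nucleotides, `H_t = 30 · G_t` (one heterotrimer covers ~30 nt). Both
conversions are linear, so SDs propagate by the same factors. Two
deliberate simplifications: the fork count is applied uniformly although
it drops at the very start and end of S phase, and the tagged/endogenous
expression ratio is *not* applied — the tagged subpopulation is assumed
kinetically representative, and copy numbers refer to the whole pool.

## Kinetics

Stalling and restart trajectories are fitted as single exponentials with
offset (`fit_decay()`, `fit_rise()`), the minimal model consistent with
reported half-times and plateaus; half-times are `ln 2 / k`. Rates of
accumulation/removal are reported under three conventions
(`estimate_rate()`): onset-to-half-maximum regression slope (headline
default), net change over the phase, and steepest sliding-window slope.
Published rate figures in this field do not always state their window, so
the convention used is always recorded in the output and comparisons
should match conventions, not just numbers. `detect_plateau()` reports
the earliest time from which the smoothed trace stays within a tolerance
(default 5% of dynamic range) of its final level.

## FRAP

`normalize_frap()` applies, in order: (a) background subtraction for the
bleached and a reference (unbleached) focus; (b) normalization of each
focus to its six-frame pre-bleach mean; (c) division of the bleached by
the unbleached trace, which cancels acquisition photobleaching exactly;
(d) an affine map pinning the first post-bleach value to 0 and the
pre-bleach mean to 1. Step (d) makes the curve independent of bleach
depth and of any constant diffuse/background offset inside the
measurement circle.

`fit_two_component()` decomposes recovery into a fast (freely diffusing)
and a slow (bound-exchange) component with an immobile remainder
`1 − A_f − A_s`. Two rules are ours, chosen for identifiability rather
than taken from any published convention: the two-component model is kept
only if it (i) reduces the residual sum of squares by ≥ 5% over a single
exponential and (ii) satisfies `k_f ≥ 10 k_s`; otherwise the
single-component fallback is used, which is the correct model for
fast-exchanging RPA-like foci. `bound_recovery()` subtracts the fitted
fast component and renormalizes by `1 − A_f`, isolating the bound pool
whose half-time is `ln 2 / k_s`. `exchange_rate()` converts recovery over
a window (default 9 s for RPA-like, 60 s for PCNA-like channels) into
complexes exchanged and a per-minute rate. Note one ambiguity in the
underlying protocol descriptions: the 9 s / 60 s windows are attached to
different conditions in the acquisition and analysis write-ups; we follow
the analysis usage and keep both configurable. Six pre-bleach frames are
required (the simulator emits six), even though FRAP acquisitions are
sometimes described with five.

## Single-focus validation

`track_focus()` follows one focus by locally background-subtracted
intensity-weighted centroids; `build_kymogram()` stitches 7×7 crops
around the rounded center per frame; `focus_trace()` measures the mean
inside a radius-3.5 px circle at the *unrounded* center minus a local
background (default: a 1 px annulus at radius 5–6 px, or an explicit
region). A pixel belongs to the circle when its center is within 3.5 px,
i.e. 37 pixels for an on-grid center. The normalized single-focus trace
`nM_t` should agree with the diffuse-pool `nE_t`; on noise-free synthetic
movies the two agree within 5% of dynamic range, which is the package's
internal cross-validation of the ROI method.

## What the simulator does and does not emulate

The generator (`render_movie()`, `render_frap_movie()`) is a first-class,
tested component: every downstream number can be checked against its
hidden ground truth. A nucleus is an ellipse carrying a fixed fluorophore
budget per channel; the per-frame bound fraction follows the closed-form
piecewise-exponential schedule; the bound part is split across Gaussian
foci (σ = 2 px default) and the rest is spread uniformly, so pool
conservation holds by construction. Noise is Poisson photon noise plus
Gaussian read noise (defaults give focus SNR ≈ 10); optional per-frame
drift and acquisition photobleaching are available. Defaults for the
study conditions: 30 s frame interval, 15 min baseline, 60 min treatment,
45 min washout; FRAP movies at 1 s for 300 s with six pre-bleach frames.

Default kinetic parameters are the reported HeLa values: PCNA 27% bound
at baseline dissolving with t½ = 2.1 min; RPA accumulating with
t½ = 23.9 min. The RPA plateau parameter is 0.424, not 0.35: a
saturating exponential with t½ = 23.9 min that reads 35% bound at the end
of a 1 h treatment must have asymptote 0.35/(1 − 2^(−60/23.9)) ≈ 0.424,
which also reproduces the ~40% level observed on 3 h treatments. The
decay channel's residual fraction defaults to 0 (complete dissolution):
residual PCNA is a property of the largest foci and is negligible at the
whole-pool level; it remains available as `f_res` and in the
stoichiometric helpers (`residual_complexes()`). Restart defaults are
t½ = 5.1 min (PCNA re-accumulation) and 2.5 min (RPA removal, complete
~12 min after washout). Focus count per nucleus and the per-focus
intensity distribution are not constrained by any measurement we know of;
the defaults (20 foci, equal weights, configurable jitter) are explicit
choices.

Not emulated: 3-D PSFs and deconvolution (the analysis consumes maximum
projections, so the simulator renders the projected plane directly),
chromatin texture, cell-cycle morphology, focus birth/death and motion
beyond global drift. Passing tests on synthetic movies therefore
validates the *estimators* — formulas, fits, tracking — under a correct
conservation model with realistic noise; it cannot certify segmentation
or ROI placement on real chromatin, which remain the user's
responsibility (B regions are deliberately manual/config-specified).

## Numerical choices

Registration estimates translation by Fourier cross-correlation with a
continuous-domain refinement of the correlation peak (equivalent to
upsampled-DFT localization); flat frames yield a zero shift with a
warning. Curve fits use Levenberg–Marquardt (`minpack.lm`) with endpoint
-derived starting values; a perfectly flat kinetic trace returns a
flagged fit (`r2 = -Inf`, `k = NA`) rather than an error. Kymogram crops
round the subpixel center to the nearest pixel (a 7×7 window cannot be
centered on a half-pixel) while the measurement circle uses the unrounded
center. Movies are written as 32-bit float multi-page TIFFs scaled into
[0, 1] with the scale recorded in the JSON sidecar (round-trip accurate
to single precision, ~1e-7 relative).

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script use 10-cell batches of
128×128 px nuclei with 14 foci at 30 s sampling (baseline + 1 h
treatment) and 10-replicate FRAP batches at 1 s sampling for 300 s —
sizes at which the stochastic recovery criteria are comfortably
resolved while a full run stays in the minutes range.

## Limitations

Absolute molecule numbers inherit the uncertainty of the proteome copy
numbers and the fixed fork count; they are best read as order-of-
magnitude anchors with exact internal ratios. The diffuse-pool method
assumes the reference window captures a fully free pool and that total
abundance is constant within a movie (no synthesis/degradation). The
two-component FRAP decomposition is phenomenological — no
reaction-diffusion modelling, no bleach-profile correction — and
component half-times close to the acquisition span are estimated with
wide confidence intervals.
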