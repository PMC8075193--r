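---
title: "Laminar perfusion fMRI with ASL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar perfusion fMRI with ASL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarASL)
```

## The problem

Gradient-echo BOLD fMRI is the workhorse of laminar (cortical-depth) imaging
at ultra-high field, but its amplitude rises toward the cortical surface
regardless of where neurons fire, because intra-cortical ascending veins
accumulate deoxyhaemoglobin changes from all laminae below on their way to
the pial surface. Arterial spin labelling (ASL) measures perfusion, which is
colocalised with neuronal activity, and acquires a BOLD-weighted signal
simultaneously. When both are measured at sub-millimetre resolution, the two
depth profiles disagree: the BOLD response grows toward the surface while the
relative perfusion response shrinks. This package implements the full
analysis chain that produces those profiles from interleaved label/control
ASL time-series, plus the steady-state venous-drainage forward model that
shows the two profiles are physiologically consistent: feeding the measured
perfusion profiles through the drainage model predicts a BOLD profile that
rises toward the surface.

Because the raw data of such studies are rarely shareable, the package is
organised around a synthetic generator whose defaults encode the acquisition
it emulates; every downstream stage is exercised and tested against known
ground truth.

## Signal model and generator

A run is a block design: `lead_in` seconds of rest, then `n_blocks` cycles of
`on_duration` stimulation and `off_duration` rest, sampled every `tr` seconds
for `n_volumes` volumes (defaults: 30 s, 10 blocks, 20 s / 40 s, 2.85 s, 230
volumes — an 11-minute run). Volumes alternate between *label* (arterial
blood magnetically tagged) and *control*. For depth $d$ at time $t_i$:

$$ s_{d,i} = B_d(t_i) - [\text{label}_i]\, P_d(t_i) + \delta_d i +
   \varepsilon_{d,i} $$

* $B_d(t) = S_d\,(1 + \beta_d\, h(t))$ — the BOLD envelope: baseline signal
  $S_d$ (a.u., default 100) with fractional plateau amplitude $\beta_d$
  (default rising 2% at the WM side to 5% at the CSF side).
* $P_d(t) = P_{0,d}\,(1 + \pi_d\, h(t))$ — the perfusion modulation removed
  on label volumes: baseline modulation depth $P_{0,d}$ (default 0.8%
  rising to 2.2% of $S_d$, mean 1.5%, consistent with a microvascular volume
  fraction of 1–2% and a vascular density that increases toward the
  surface), with fractional activation $\pi_d$ (default falling 60% to 30%).
  Labels are control minus perfusion, so control − label is non-negative by
  construction.
* $h(t)$ — the stimulus boxcar convolved with a canonical double-gamma HRF,
  $h_0(t) = (t/6)^6 e^{6-t} - \tfrac16 (t/16)^{16} e^{16-t}$ (response peak
  6 s, undershoot 16 s, ratio 1/6), sampled at the TR and normalised to unit
  sum. A unit-sum kernel makes the envelope of a sustained block plateau at
  exactly 1, so the amplitudes above are plateau fractions; the envelope
  transiently overshoots 1 early in a block, as the canonical response does.
* $\delta_d$ — linear drift, `drift_slope` (default $10^{-4}$) times $S_d$
  per volume: the minimal nuisance structure that surround subtraction must
  cancel.
* $\varepsilon$ — white Gaussian noise (default SD 0.5 a.u., giving
  single-voxel perfusion tSNR near 2–3, typical of sub-millimetre ASL).
  Physiological (autocorrelated) noise is deliberately omitted; the GLM
  below assumes white noise accordingly, and nothing in the tests probes
  autocorrelation robustness.

Whether a run starts with a label or a control volume is scanner-dependent
and not observable from the analysis side; it is a parameter
(`first_parity`, default `"label"`).

The generator evaluates $h$ at the volume timestamps $t_i = i\,\mathrm{TR}$
with no slice-timing model, appropriate for a 3D readout that excites the
whole volume each TR.

## Separating perfusion and BOLD

Interleaving makes the raw series zig-zag. Three-point sliding operators
separate the components while keeping the output on the input grid:

* **surround subtraction** $p_i = \sigma_i (s_i - \tfrac12 (s_{i-1} +
  s_{i+1}))$, with $\sigma_i = +1$ on control and $-1$ on label volumes,
  recovers the modulation depth (the perfusion-weighted series). Any signal
  affine in time has zero second difference, so drift and slow BOLD trends
  cancel; the residual BOLD contamination is bounded by the largest second
  difference of the envelope.
* **surround averaging** $b_i = \tfrac12 s_i + \tfrac14 (s_{i-1} + s_{i+1})$
  removes the alternating component and keeps the envelope; on noiseless
  data it equals $B - P/2$ where the envelope is locally constant.

Endpoints use the single available neighbour (two-point differences); the
choice is not in the source methods, and keeping series length equal to the
input simplifies downstream indexing. Baseline perfusion is the mean of
control−label differences over adjacent rest-period pairs (initial rest and
pre-stimulus intervals); whether a control pairs with the preceding or the
following label is unstated in the field's descriptions, so greedy adjacent
pairing is the default with both directional variants available. Perfusion
tSNR is the temporal mean over the temporal SD of the perfusion-weighted
series.

## The three-regressor GLM

Activation is detected with ordinary least squares on four regressors: the
HRF-convolved boxcar (BOLD, mean-centred), the alternating ±1/2 parity
regressor (baseline perfusion), their elementwise product (perfusion
activation), and an intercept. Centring the BOLD regressor but not the
interaction keeps the parity beta interpretable as baseline perfusion and
the interaction beta as the activation-driven change in modulation depth;
the alternative (centred interaction) is a switch, since conventions differ
between implementations. Simple voxelwise t-thresholding (default t ≥ 3.1)
replaces cluster-level inference, which is a property of specific external
software rather than of the model; the BOLD/perfusion overlap mask is the
voxelwise conjunction of the two thresholded maps. No prewhitening is
applied (see the noise model above).

## Equi-volume layering

Cortical geometry is idealised as a column whose cross-sectional area varies
linearly between the WM and pial boundaries — the simplest shape that
distinguishes equi-volume from equidistant layering and admits a closed
form. Boundaries are first extended by 30% of the cortical thickness into
WM and CSF (guarding against boundary misplacement and pial partial-volume
effects), then 21 intermediate surfaces are placed so consecutive surfaces
bound equal tissue volumes: with boundary areas $A_{in}, A_{out}$ and target
volume fraction $\rho$, the normalised depth solves a quadratic,

$$ x(\rho) = \frac{-A_{in} + \sqrt{(1-\rho)A_{in}^2 + \rho A_{out}^2}}
   {A_{out} - A_{in}}, $$

reducing to $x = \rho$ for a flat column. Including both extended boundaries
gives 23 sampling depths. Signals are sampled at each depth from the voxel
grid by nearest neighbour, with ties broken toward the WM side (fixed for
reproducibility). Extension happens before layering, following the stated
processing order of the workflow this reproduces.

## Laminar profiles

Event-related averages align trials at block onsets on a fixed-length volume
window (default −10 s to +40 s); trials whose window leaves the series are
dropped. Percent BOLD change is rescaled to the ~10 s pre-stimulus baseline.
Absolute perfusion change subtracts the pre-stimulus baseline and divides by
the mean EPI signal (removing transmit/receive bias and baseline T2\*
weighting); relative perfusion change divides by the perfusion baseline
itself, so the mean-EPI factor cancels. Steady-state profiles average the
half-open interval [14, 28) s after onset — half-open so boundary samples
are counted deterministically. Line fits report the slope per unit
normalised depth (0 = extended WM boundary, 1 = extended CSF boundary) and
$R^2$, with $R^2 \equiv 0$ for a zero-variance profile so degenerate inputs
do not crash group summaries. Group aggregation is the unweighted mean with
SEM across runs/participants.

Note that with 20 s blocks the envelope never fully plateaus inside
[14, 28) s, so measured plateau amplitudes are attenuated by the mean of
$h$ over the window (~0.8 at these defaults) relative to the generative
amplitudes; the round-trip tests therefore use sustained 60 s blocks where
the identity is exact, and the pipeline's recovered amplitudes are expected
to sit below the generative plateau fractions by that factor.

## The venous-drainage forward model

The forward model predicts the laminar BOLD profile from measured perfusion
profiles (baseline and activation, arbitrary units) and baseline physiology,
at steady state. Per depth $k$ (depth 1 deepest), with relative flow
$f_k = \text{active}_k / \text{baseline}_k$:

* **Baseline volumes.** Total venous blood volume `cbv0_total` = 2 mL/100 g,
  half microvascular (venules, uniform across depths), half ascending vein,
  the latter rising linearly toward the surface with slope `s_d` = 0.4
  (ramp $1 + s_d (k-1)/(K-1)$, normalised to the compartment total — the
  ramp's normalisation is not fixed by its one-line description, so this
  form is a documented choice, switchable via the parameters object).
* **Baseline flows.** Venule flows proportional to the measured baseline
  perfusion (uniform option for analytic tests); the vein's baseline flow is
  cumulative from below. `rescale_cbf()` pins the depth-mean baseline
  perfusion to CBV₀ᵐⁱᶜʳᵒ/t_v0 = 1 mL/s/100 g = 60 mL/min/100 g via the
  central volume principle (transit time `t_v0` = 1 s); the prediction
  itself depends only on the relative flows.
* **Coupling.** CMRO₂ follows $m = 1 + (f-1)/n$ with $n = 3$; volumes follow
  Grubb relations $v = f^{\alpha}$ with $\alpha_v = 0.35$ (venules) and
  $\alpha_d = 0.1$ (vein).
* **Venule steady state.** Deoxyhaemoglobin content from mass balance:
  production $m$, clearance $f q/v$, so $q = m v / f$; baseline O₂
  extraction `e0` = 0.35 enters only the signal constants.
* **Vein drainage.** Vein flow at depth $k$ is the cumulative venule outflow
  $\sum_{j \le k} f_j F^0_{v,j}$; its dHb concentration is the flux-weighted
  mixture of the local venule outflow and the vein inflow from below. This
  cumulative mixing is the surface bias.
* **Signal equation.** $\Delta S/S_k = \sum_j w_{j,k}[(k_1 + k_2)(1-q) -
  (k_2 + k_3)(1-v)]$ per compartment $j$, with $w$ the baseline volume
  fraction within the lamina's tissue, $k_1 = c_1 e_0 T_E$,
  $k_2 = c_2 e_0 T_E$, $k_3 = c_3$, $T_E$ = 15 ms.

The constants $c_1, c_2, c_3$ are exposed in `physiology_params()`. Defaults
represent a 7 T gradient-echo regime: for the ascending vein (static
dephasing around a large vessel) $c_1 = 4.3 \nu_0$ with
$\nu_0 = 188.1\,\mathrm{s}^{-1}$; for venules the extravascular efficacy is
reduced to 25% of that by diffusion narrowing around microvessels;
intravascular weighting is near-negligible at this field and echo time
($c_2 = 0.01 \cdot 102\,\mathrm{s}^{-1}$, $c_3 = 0.01 - 1$). The test suite
asserts only null, sign, conservation and monotonicity properties of the
model, not particular amplitudes, since amplitudes trade off directly
against these constants.

### What the reconciliation does and does not claim

For relative-flow profiles inside the physiologically measured envelope —
monotone declines with $f$ between about 1.2 and 1.8 — the simulated BOLD
profile has a positive slope toward the surface for any monotone shape
(validated over randomised convex/concave declines). The claim cannot be
universal: if superficial activation approaches null ($f \to 1$ in the upper
laminae), the vein's dHb perturbation dilutes toward baseline faster than
its volume grows, and the simulated profile must eventually fall toward the
surface. That is a property of any drainage model of this class, not an
implementation artefact.

## The pipeline and its study emulation

`run_pipeline()` chains every stage with one seed. Defaults emulate the
study scale: 28 runs (7 participants × 4 runs, ~44 minutes of data), each
230 volumes; GLM statistics are combined across runs as fixed effects
($\sum\hat\beta / \sqrt{\sum \mathrm{se}^2}$). Laminar time-courses in such
studies are averages over all ROI vertices of a lamina, not single voxels;
the pipeline models the ROI average over `n_columns` = 50 independent
columns, implemented exactly (white Gaussian noise) by generating the
laminar series with noise SD divided by $\sqrt{50}$, while voxelwise maps
(GLM, tSNR, baseline perfusion) keep single-voxel noise. The synthetic
cortical patch uses 12 voxels across the extended 2.6 mm span — a finer
grid than the 0.9 mm acquisition so the 23 sampled depths are not dominated
by duplication; nearest-neighbour duplication is still visible as steps in
the profiles, as it is in real sampled data.

Problem sizes in the tests mirror these defaults scaled down (4–28 runs,
8–12 voxels, 50–100 Monte-Carlo replicates), chosen so the whole suite runs
in well under a minute while keeping every property at its stated tolerance.

## Known limitations

* White noise only; no motion, distortion, or physiological confounds — the
  registration/distortion stages of a real workflow are out of scope, so the
  pipeline's pass says nothing about their failure modes.
* The column geometry is a linear-area wedge, not a surface mesh; curvature
  enters only through the boundary-area ratio.
* The forward model is steady-state: transients, post-stimulus undershoots
  and their depth-dependent oscillations are outside its scope.
* The k-space module is 1-D and noiseless: no T2\* decay across the echo
  train (the PSF is "nominal"), no parallel-imaging or multi-coil effects.
* Perfusion stays in arbitrary units end to end except for the reporting
  rescale to mL/min/100 g; no kinetic-model quantification.
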