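# laminarASL

Analysis pipeline for sub-millimetre **laminar perfusion fMRI with arterial
spin labelling (ASL)** — for imaging scientists who want to analyse
interleaved label/control ASL time-series across cortical depth, and to test
whether measured BOLD and perfusion depth profiles are mutually consistent
under a venous-drainage model.

ASL runs alternate magnetically *labelled* and *control* volumes, so the raw
signal zig-zags: the modulation depth is the perfusion-weighted signal, the
envelope is the BOLD-weighted signal. At laminar resolution the two tell
different stories — BOLD amplitude rises toward the cortical surface, the
relative perfusion response falls toward it. The package implements the full
chain that produces those profiles and the forward model that reconciles
them:

1. **Synthetic generation** (`generate_laminar_asl`) of block-design laminar
   ASL with known ground truth: per depth,
   `s(t) = B(t) − [label]·P(t) + drift + noise` with
   `B = S(1 + β h(t))`, `P = P₀(1 + π h(t))` and `h` the HRF-convolved
   boxcar (unit plateau).
2. **Signal separation** by surround subtraction / surround averaging
   (`surround_subtract`, `surround_average`), baseline perfusion from rest
   label/control pairs, and perfusion tSNR.
3. **Three-regressor perfusion GLM** (`build_design`, `fit_glm`): the
   HRF-convolved boxcar (BOLD), the ±1/2 parity regressor (baseline
   perfusion) and their product (perfusion activation), plus the
   BOLD/perfusion overlap mask.
4. **Equi-volume layering** (`extend_boundaries`, `equivolume_depths`):
   boundaries extended 30% of thickness, 21 intermediate equal-volume
   surfaces on a linear-area column — 23 sampling depths with the closed
   form `x(ρ) = (−A_in + √((1−ρ)A_in² + ρA_out²)) / (A_out − A_in)`.
5. **Laminar profiles** (`event_related_average`, `steady_state_profile`):
   percent BOLD change, absolute (mean-EPI-normalised) and relative
   perfusion change over the 14–28 s steady-state window, with line fits.
6. **Venous-drainage forward model** (`simulate_bold_profile`): venule
   steady state `q = m v / f` (with `m = 1 + (f−1)/n`, `v = f^α`),
   flux-weighted deoxyhaemoglobin mixing up the ascending vein, and the
   static BOLD signal equation
   `ΔS/S = Σ w[(k₁+k₂)(1−q) − (k₂+k₃)(1−v)]`.

`run_pipeline()` chains all stages under one seed, emulating the study scale
(28 runs ≈ 7 participants × 4 runs). A 1-D partial-Fourier module
(`simulate_psf`, `pocs_recon`) reproduces the acquisition's nominal
point-spread-function computation.

## Worked example

```r
library(laminarASL)
res <- run_pipeline(default_config(seed = 1))
str(res$summary)
#> $ bold_slope               : num 2.59
#> $ bold_r2                  : num 0.992
#> $ abs_perf_slope           : num 0.00172
#> $ abs_perf_r2              : num 0.764
#> $ rel_perf_slope           : num -26.4
#> $ rel_perf_r2              : num 0.991
#> $ pearson_r_sim_vs_measured: num 0.975
#> $ n_depths                 : int 23
#> $ cbf_scaling_x            : num 65.6
#> $ mean_cbf0_ml_per_min_100g: num 60
#> $ n_overlap_voxels         : int 12
#> $ mean_perfusion_tsnr      : num 2.24
```

Reading: across 23 equi-volume depths, the percent-BOLD profile **rises**
toward the surface (slope +2.59 per unit depth, R² 0.99) while the relative
perfusion profile **falls** (slope −26.4, R² 0.99) and the absolute
perfusion change rises only weakly — the characteristic dissociation.
Feeding the measured-synthetic perfusion profiles through the drainage
model predicts a BOLD profile that correlates at r = 0.975 with the
measured-synthetic one: the opposing profiles are consistent once the
ascending-vein bias is modelled. The CBF rescaling pins mean baseline
perfusion at 60 mL/min/100 g via the central volume principle.

The numbered drivers under `analysis/` run the same stages as a narrated
sequence (PSF → simulate → separate → GLM → profiles → forward model),
writing tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

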