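#!/usr/bin/env Rscript
# Laminar analysis of the full study emulation: equi-volume layering (21
# intermediate surfaces inside boundaries extended by 30% of the thickness,
# 23 sampling depths), nearest-neighbour depth sampling, event-related
# averaging, and the three laminar read-outs — percent BOLD change, absolute
# perfusion change (baseline-subtracted, mean-EPI-normalised) and relative
# perfusion change — averaged over 28 runs. Finding: the BOLD profile rises
# steeply toward the surface with a strong linear trend, the relative
# perfusion profile falls, and the absolute perfusion change rises only
# modestly — the characteristic dissociation of the three signals.

library(laminarASL)

res <- run_pipeline(default_config(seed = 1), outdir = "results/laminar")

fits <- res$fits
cat("Laminar steady-state profiles over", res$summary$n_depths,
    "depths,", res$summary$n_runs, "runs:\n")
cat(sprintf("  %% BOLD change:        slope %+.2f (SE %.2f), R^2 %.3f\n",
            fits$bold$slope, fits$bold$slope_se, fits$bold$r_squared))
cat(sprintf("  abs perfusion change: slope %+.4f (SE %.4f), R^2 %.3f\n",
            fits$abs_perf$slope, fits$abs_perf$slope_se,
            fits$abs_perf$r_squared))
cat(sprintf("  rel perfusion change: slope %+.2f (SE %.2f), R^2 %.3f\n",
            fits$rel_perf$slope, fits$rel_perf$slope_se,
            fits$rel_perf$r_squared))
cat(sprintf("  overlap mask: %d voxels; mean single-run perfusion tSNR %.2f\n",
            res$summary$n_overlap_voxels, res$summary$mean_perfusion_tsnr))
cat("wrote results/laminar/profile_{bold,abs_perf,rel_perf,simulated_bold}.tsv,",
    "profile_fits.tsv, summary.yaml\n")
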