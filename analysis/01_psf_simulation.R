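#!/usr/bin/env Rscript
# Acquisition-side resolution check: the nominal 1-D point spread function
# along the phase-encoding direction under 5/8 partial-Fourier sampling,
# reconstructed by zero-filling (the default) and by 8 POCS iterations.
# Finding: zero-filling broadens the PSF to ~2 nominal voxels FWHM; POCS
# restores it to near the fully-sampled width, which is why the study's data
# were reconstructed with POCS.

library(laminarASL)

dir.create("results", showWarnings = FALSE)

os <- 16
zf <- simulate_psf(64, 5 / 8, recon = "zerofill", oversample = os)
pocs <- simulate_psf(64, 5 / 8, recon = "pocs", n_iter = 8, oversample = os)
full <- simulate_psf(64, 1, recon = "zerofill", oversample = os)

x <- (seq_along(zf$profile) - length(zf$profile) / 2 - 1) / os
keep <- abs(x) <= 8
write.table(
  data.frame(voxel = x[keep],
             zerofill = zf$profile[keep] / max(zf$profile),
             pocs = pocs$profile[keep] / max(pocs$profile),
             full = full$profile[keep] / max(full$profile)),
  "results/psf_profiles.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

fwhm <- data.frame(
  recon = c("zerofill_5of8", "pocs_5of8", "full"),
  fwhm_voxels = c(zf$fwhm_voxels, pocs$fwhm_voxels, full$fwhm_voxels))
write.table(fwhm, "results/psf_fwhm.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("PSF FWHM along phase encoding (nominal voxels):\n"))
cat(sprintf("  zero-filled 5/8 partial Fourier : %.3f (~2 voxels)\n",
            zf$fwhm_voxels))
cat(sprintf("  POCS (8 iterations)             : %.3f\n", pocs$fwhm_voxels))
cat(sprintf("  fully sampled                   : %.3f\n", full$fwhm_voxels))
cat("wrote results/psf_profiles.tsv, results/psf_fwhm.tsv\n")
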