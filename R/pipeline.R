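#' Default pipeline configuration
#'
#' All numeric defaults are the study conditions of the modelled acquisition:
#' a 30 s lead-in, ten 20 s-on / 40 s-off blocks, TR 2.85 s, 230 volumes
#' (~11 min) per run, 28 runs in total (emulating 7 participants x 4 runs,
#' ~44 min of averaged data per region); a boundary extension of 30% of
#' cortical thickness and 21 intermediate equi-volume surfaces (23 sampling
#' depths); a 14-28 s steady-state interval and ~10 s pre-stimulus baseline;
#' venous physiology as in [physiology_params()]. The synthetic ground truth
#' emulates the measured laminar pattern: baseline perfusion rising from 0.8%
#' (WM-side) to 2.2% (CSF-side) of the baseline signal (mean 1.5%, inside the
#' 1-2% microvascular density band, rising toward the vascularised surface);
#' a BOLD plateau amplitude rising from 2% (WM-side) to 5% (CSF-side); a
#' relative perfusion response falling from 60% (WM-side) to 30% (CSF-side) —
#' jointly making the absolute perfusion change rise modestly (~35%) toward
#' the surface while the relative change halves, the measured dissociation;
#' a small linear drift; and white noise giving a single-run perfusion tSNR
#' of about 2-3, typical of sub-millimetre ASL.
#'
#' The laminar time-courses of a study are averages over all ROI vertices of a
#' lamina, not single voxels; `n_columns` (default 50) is the number of
#' independent cortical columns entering that average. Since the noise is
#' white Gaussian, the ROI-averaged series is generated directly with noise SD
#' `noise_sd / sqrt(n_columns)` (exact in distribution), while voxelwise
#' outputs (GLM, tSNR, baseline perfusion maps) keep single-voxel noise.
#'
#' @param seed integer seed; run r uses `seed + r - 1`.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    design = list(lead_in = 30, n_blocks = 10, on_duration = 20,
                  off_duration = 40, tr = 2.85, n_volumes = 230L),
    n_runs = 28L,
    n_columns = 50L,
    truth = list(n_voxels = 12L, baseline_signal = 100,
                 baseline_perfusion_frac = c(wm = 0.008, csf = 0.022),
                 bold_amplitude = c(wm = 0.02, csf = 0.05),
                 perfusion_amplitude = c(wm = 0.6, csf = 0.3),
                 drift_slope = 1e-4, noise_sd = 0.5),
    geometry = list(thickness = 2, area_inner = 1, area_outer = 1.2,
                    extend_fraction = 0.3),
    layering = list(n_intermediate = 21L),
    glm = list(threshold = 3.1),
    windows = list(era = c(-10, 40), prestim_s = 10,
                   steady_state = c(14, 28)),
    physiology = list(),
    first_parity = "label",
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

# Per-voxel ground truth on the extended depth grid of a config.
config_truth <- function(config) {
  nv <- config$truth$n_voxels
  # normalised voxel-centre depths over the extended span
  xc <- (seq_len(nv) - 0.5) / nv
  lerp <- function(ab) ab[["wm"]] + (ab[["csf"]] - ab[["wm"]]) * xc
  bs <- rep(config$truth$baseline_signal, nv)
  laminar_truth(
    baseline_signal = bs,
    baseline_perfusion = bs * lerp(config$truth$baseline_perfusion_frac),
    bold_amplitude = lerp(config$truth$bold_amplitude),
    perfusion_amplitude = lerp(config$truth$perfusion_amplitude),
    drift_slope = config$truth$drift_slope,
    noise_sd = config$truth$noise_sd)
}

#' Run the laminar ASL analysis pipeline end-to-end
#'
#' Stages, mirroring the analysis of a laminar ASL study: synthetic
#' generation of `n_runs` runs -> surround separation (perfusion/BOLD) ->
#' three-regressor GLM per run with fixed-effects combination and the
#' BOLD/perfusion overlap mask -> boundary extension and equi-volume layering
#' -> nearest-neighbour depth sampling, event-related averaging and laminar
#' profiles (percent BOLD, absolute and relative perfusion change),
#' group-averaged across runs -> steady-state profile line fits -> forward
#' laminar BOLD simulation from the measured-synthetic perfusion profiles and
#' Pearson comparison against the measured-synthetic BOLD profile. Identical
#' seeds give identical outputs. When `outdir` is given, the first run's
#' series and all profiles/fits are written (NIfTI, TSV, YAML).
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param outdir optional output directory for artefacts.
#' @return list with `profiles` (group `laminar_profile`s: bold, abs_perf,
#'   rel_perf, simulated_bold), `fits` (line fits), `summary` (slopes, R^2,
#'   Pearson r, depth count, CBF scaling, overlap count), and intermediates
#'   (`series` of run 1, `glm` combined t, `depths`, `tsnr`, ...).
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  d <- do.call(make_block_design, config$design)
  truth <- config_truth(config)
  w <- config$windows

  # --- layering (run-independent) ---------------------------------------
  g <- config$geometry
  geom <- make_column_geometry(g$thickness, g$area_inner, g$area_outer)
  ext <- extend_boundaries(geom, g$extend_fraction)
  depths <- equivolume_depths(ext, config$layering$n_intermediate)
  span <- ext$pial_position - ext$wm_position
  nv <- config$truth$n_voxels
  centres <- ext$wm_position + ((seq_len(nv) - 0.5) / nv) * span
  dn <- depths$normalized
  X <- NULL

  # ROI-averaged laminar ground truth: white noise shrinks by sqrt(columns)
  truth_roi <- truth
  truth_roi$noise_sd <- truth$noise_sd / sqrt(config$n_columns)

  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    series <- generate_laminar_asl(d, truth, seed = config$seed + r - 1L,
                                   first_parity = config$first_parity)
    roi <- generate_laminar_asl(d, truth_roi,
                                seed = config$seed + 100000L + r,
                                first_parity = config$first_parity)
    perf <- surround_subtract(roi)
    bold <- surround_average(roi)
    t_i <- volume_times(roi)
    bl_perf <- baseline_perfusion(roi, which(t_i < config$design$lead_in))
    mean_epi <- rowMeans(roi$values)
    if (is.null(X)) X <- build_design(d, series$parity)
    fit <- fit_glm(series, X)

    sample_rows <- function(v) sample_to_depths(v, centres, depths)
    bold_d <- list(values = sample_rows(bold$values), tr = bold$tr)
    perf_d <- list(values = sample_rows(perf$values), tr = perf$tr)
    mean_epi_d <- sample_rows(matrix(mean_epi, ncol = 1))
    bl_perf_d <- sample_rows(matrix(bl_perf, ncol = 1))

    era_bold <- event_related_average(bold_d, d, w$era)
    era_perf <- event_related_average(perf_d, d, w$era)
    pbc <- percent_bold_change(era_bold, w$prestim_s)
    apc <- absolute_perfusion_change(era_perf, w$prestim_s, mean_epi_d)
    rpc <- relative_perfusion_change(era_perf, w$prestim_s)

    runs[[r]] <- list(
      series = if (r == 1) series else NULL,
      perf = if (r == 1) perf else NULL,
      tsnr = perfusion_tsnr(surround_subtract(series)),
      betas = fit$betas, se = fit$se,
      prof_bold = steady_state_profile(pbc, dn, w$steady_state),
      prof_abs = steady_state_profile(apc, dn, w$steady_state),
      prof_rel = steady_state_profile(rpc, dn, w$steady_state),
      baseline_abs = bl_perf_d / mean_epi_d)
  }

  # --- fixed-effects GLM combination and overlap mask -------------------
  sum_betas <- Reduce(`+`, lapply(runs, `[[`, "betas"))
  sum_var <- Reduce(`+`, lapply(runs, function(x) x$se^2))
  t_comb <- sum_betas / sqrt(sum_var)
  mask <- overlap_mask(t_comb[, "bold"], t_comb[, "perfusion_activation"],
                       config$glm$threshold)

  # --- group profiles ----------------------------------------------------
  prof_bold <- group_profile(lapply(runs, `[[`, "prof_bold"))
  prof_abs <- group_profile(lapply(runs, `[[`, "prof_abs"))
  prof_rel <- group_profile(lapply(runs, `[[`, "prof_rel"))
  fits <- list(bold = profile_linefit(prof_bold),
               abs_perf = profile_linefit(prof_abs),
               rel_perf = profile_linefit(prof_rel))

  # --- forward model -----------------------------------------------------
  phys <- do.call(physiology_params, config$physiology)
  base_abs <- rowMeans(vapply(runs, `[[`, numeric(depths$n_depths),
                              "baseline_abs"))
  active_abs <- base_abs + prof_abs$value
  perf_in <- laminar_perfusion_input(base_abs, active_abs, dn)
  sim_bold <- simulate_bold_profile(perf_in, phys)
  r_sim <- pearson_r(prof_bold, sim_bold)

  summary <- list(
    bold_slope = fits$bold$slope, bold_r2 = fits$bold$r_squared,
    abs_perf_slope = fits$abs_perf$slope, abs_perf_r2 = fits$abs_perf$r_squared,
    rel_perf_slope = fits$rel_perf$slope, rel_perf_r2 = fits$rel_perf$r_squared,
    pearson_r_sim_vs_measured = r_sim,
    n_depths = depths$n_depths,
    cbf_scaling_x = attr(sim_bold, "x"),
    mean_cbf0_ml_per_min_100g = mean(attr(sim_bold, "cbf0")) * 60,
    n_overlap_voxels = sum(mask),
    n_runs = config$n_runs,
    mean_perfusion_tsnr = mean(vapply(runs, function(x) mean(x$tsnr),
                                      numeric(1))),
    seed = config$seed)

  res <- list(config = config, design = d, truth = truth,
              series = runs[[1]]$series, perfusion = runs[[1]]$perf,
              tsnr = runs[[1]]$tsnr, glm_t = t_comb, mask = mask,
              depths = depths,
              profiles = list(bold = prof_bold, abs_perf = prof_abs,
                              rel_perf = prof_rel, simulated_bold = sim_bold),
              fits = fits, summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_asl_dataset(runs[[1]]$series, file.path(outdir, "synthetic_run1"),
                      seed = config$seed)
    for (nm in c("bold", "abs_perf", "rel_perf", "simulated_bold"))
      write_profile_tsv(res$profiles[[nm]],
                        file.path(outdir, paste0("profile_", nm, ".tsv")))
    fitdf <- do.call(rbind, lapply(names(fits), function(nm)
      data.frame(signal = nm, slope = fits[[nm]]$slope,
                 slope_se = fits[[nm]]$slope_se,
                 r_squared = fits[[nm]]$r_squared)))
    utils::write.table(fitdf, file.path(outdir, "profile_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(summary, file.path(outdir, "summary.yaml"))
  }
  res
}
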