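#' Block stimulus design
#'
#' Describes a block-design run: an initial rest (lead-in), `n_blocks`
#' stimulus on/off cycles, and the scan timing. Volumes beyond the last block
#' are rest. The defaults elsewhere in the package follow a 30 s lead-in, ten
#' 20 s-on / 40 s-off blocks, TR 2.85 s and 230 volumes (an approximately
#' 11-minute run).
#'
#' @param lead_in initial rest duration, seconds.
#' @param n_blocks number of stimulus on/off blocks (0 allowed: pure rest).
#' @param on_duration stimulus-on duration per block, seconds.
#' @param off_duration stimulus-off duration per block, seconds.
#' @param tr repetition time, seconds per volume.
#' @param n_volumes number of acquired volumes.
#' @return An object of class `stimulus_design`.
#' @export
make_block_design <- function(lead_in, n_blocks, on_duration, off_duration,
                              tr, n_volumes) {
  if (!is.numeric(tr) || tr <= 0) stop("`tr` must be positive")
  if (!is.numeric(n_volumes) || n_volumes < 1 || n_volumes != round(n_volumes))
    stop("`n_volumes` must be a positive integer")
  if (lead_in < 0 || n_blocks < 0 || on_duration <= 0 || off_duration <= 0)
    stop("durations must be positive and lead_in/n_blocks non-negative")
  if (n_blocks != round(n_blocks)) stop("`n_blocks` must be an integer")
  structure(list(lead_in = lead_in, n_blocks = n_blocks,
                 on_duration = on_duration, off_duration = off_duration,
                 tr = tr, n_volumes = as.integer(n_volumes)),
            class = "stimulus_design")
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat("Block design:", x$lead_in, "s lead-in,", x$n_blocks, "x (",
      x$on_duration, "s on /", x$off_duration, "s off ), TR =", x$tr,
      "s,", x$n_volumes, "volumes (", x$n_volumes * x$tr, "s )\n")
  invisible(x)
}

#' Stimulus onset times
#' @param design a `stimulus_design`.
#' @return numeric vector of block onset times in seconds.
#' @export
block_onsets <- function(design) {
  if (design$n_blocks == 0) return(numeric(0))
  design$lead_in +
    (seq_len(design$n_blocks) - 1) * (design$on_duration + design$off_duration)
}

#' Boxcar stimulus indicator sampled at volume times
#'
#' `boxcar(design)[i]` is 1 iff volume timestamp `t_i = (i-1)*tr` falls inside
#' a stimulus-on interval `[onset, onset + on_duration)`.
#'
#' @param design a `stimulus_design`.
#' @return numeric 0/1 vector of length `n_volumes`.
#' @export
boxcar <- function(design) {
  t <- volume_times(design)
  on <- rep(0, design$n_volumes)
  for (onset in block_onsets(design))
    on[t >= onset & t < onset + design$on_duration] <- 1
  on
}

#' Laminar ground truth for the synthetic generator
#'
#' Per-depth generative quantities: an M0-like baseline signal, the baseline
#' perfusion modulation depth (the label/control zig-zag amplitude; the
#' microvascular density argument puts it at about 1-2 percent of the baseline
#' signal), fractional BOLD and perfusion activation amplitudes, a linear
#' drift slope (fraction of baseline signal per volume) and white-noise SD.
#'
#' @param baseline_signal numeric vector, one value per depth (a.u.).
#' @param baseline_perfusion numeric vector or scalar (a.u.), non-negative and
#'   small relative to `baseline_signal`.
#' @param bold_amplitude fractional BOLD plateau change per depth.
#' @param perfusion_amplitude fractional perfusion change per depth (relative
#'   to `baseline_perfusion`).
#' @param drift_slope linear drift, fraction of baseline signal per volume.
#' @param noise_sd Gaussian noise SD (a.u.).
#' @return An object of class `laminar_truth`.
#' @export
laminar_truth <- function(baseline_signal, baseline_perfusion,
                          bold_amplitude = 0, perfusion_amplitude = 0,
                          drift_slope = 0, noise_sd = 0) {
  k <- length(baseline_signal)
  if (k < 1) stop("need at least one depth")
  rep_k <- function(v, nm) {
    if (length(v) == 1) v <- rep(v, k)
    if (length(v) != k) stop("`", nm, "` must have length 1 or n_depths")
    v
  }
  baseline_perfusion <- rep_k(baseline_perfusion, "baseline_perfusion")
  bold_amplitude <- rep_k(bold_amplitude, "bold_amplitude")
  perfusion_amplitude <- rep_k(perfusion_amplitude, "perfusion_amplitude")
  if (any(baseline_signal <= 0)) stop("baseline_signal must be positive")
  if (any(baseline_perfusion < 0)) stop("baseline_perfusion must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_depths = k, baseline_signal = baseline_signal,
                 baseline_perfusion = baseline_perfusion,
                 bold_amplitude = bold_amplitude,
                 perfusion_amplitude = perfusion_amplitude,
                 drift_slope = drift_slope, noise_sd = noise_sd),
            class = "laminar_truth")
}

#' Unit-plateau haemodynamic envelope of a design
#'
#' The boxcar convolved with the canonical HRF kernel. The kernel sums to 1,
#' so wherever a block has been on for at least the kernel length the envelope
#' equals exactly 1 (the plateau); the generator's truth amplitudes are
#' therefore plateau fractional changes. The envelope transiently overshoots 1
#' early in a block, before the undershoot lobe accumulates, as the canonical
#' response does.
#'
#' @param design a `stimulus_design`.
#' @return numeric vector of length `n_volumes` (all zero if no blocks).
#' @export
hrf_envelope <- function(design) {
  b <- boxcar(design)
  if (all(b == 0)) return(b)
  convolve_hrf(b, canonical_hrf(design$tr))
}

#' Generate a synthetic laminar ASL time-series
#'
#' Generative model per depth d and volume i (timestamp `t_i`):
#' \deqn{s_{d,i} = B_d(t_i) - [parity_i = label] P_d(t_i) +
#'   drift_d(i) + \epsilon_{d,i}}
#' with BOLD envelope `B_d(t) = baseline_signal_d (1 + bold_amplitude_d h(t))`,
#' perfusion modulation
#' `P_d(t) = baseline_perfusion_d (1 + perfusion_amplitude_d h(t))`,
#' `h(t)` the unit-plateau HRF-convolved boxcar, linear drift
#' `baseline_signal_d * drift_slope * (i-1)` and white Gaussian noise.
#' Labels are modelled as control minus perfusion (control volumes are
#' unperturbed), so control - label equals the perfusion-weighted signal and
#' baseline perfusion is non-negative by construction.
#'
#' @param design a `stimulus_design`.
#' @param truth a `laminar_truth`.
#' @param seed optional integer; when given the noise is reproducible and the
#'   caller's RNG state is untouched.
#' @param first_parity parity of the first volume (the acquisition order is
#'   scanner-dependent); default `"label"`.
#' @return An `asl_timeseries` with attributes `design` and `truth`.
#' @export
generate_laminar_asl <- function(design, truth, seed = NULL,
                                 first_parity = c("label", "control")) {
  first_parity <- match.arg(first_parity)
  if (!inherits(design, "stimulus_design")) stop("`design` must be a stimulus_design")
  if (!inherits(truth, "laminar_truth")) stop("`truth` must be a laminar_truth")
  n <- design$n_volumes
  k <- truth$n_depths
  h <- hrf_envelope(design)
  parity <- rep(c(first_parity, setdiff(c("label", "control"), first_parity)),
                length.out = n)
  B <- truth$baseline_signal %o% rep(1, n) *
    (1 + truth$bold_amplitude %o% h)
  P <- truth$baseline_perfusion %o% rep(1, n) *
    (1 + truth$perfusion_amplitude %o% h)
  lab <- as.numeric(parity == "label")
  drift <- (truth$baseline_signal * truth$drift_slope) %o% (seq_len(n) - 1)
  noise <- 0
  if (truth$noise_sd > 0) {
    draw <- function() matrix(stats::rnorm(k * n, 0, truth$noise_sd), k, n)
    noise <- if (is.null(seed)) draw() else
      local_seed_eval(seed, draw)
  }
  values <- B - sweep(P, 2, lab, `*`) + drift + noise
  out <- asl_timeseries(values, parity, design$tr)
  attr(out, "design") <- design
  attr(out, "truth") <- truth
  out
}

# Evaluate fn() under a temporary RNG seed, restoring the caller's state.
local_seed_eval <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Idealised cortical column geometry
#'
#' A cortical patch with the white-matter boundary at depth coordinate 0 and
#' the pial boundary at `thickness`, whose cross-sectional area varies
#' linearly between the two boundary areas. Curved cortex maps onto unequal
#' boundary areas (a wedge); flat cortex onto equal areas.
#'
#' @param thickness cortical thickness (mm), positive.
#' @param area_inner cross-sectional area at the WM boundary (a.u.), positive.
#' @param area_outer cross-sectional area at the pial boundary (a.u.), positive.
#' @return An object of class `column_geometry` with fields `wm_position`,
#'   `pial_position`, `area_inner`, `area_outer`.
#' @export
make_column_geometry <- function(thickness, area_inner, area_outer) {
  if (!is.numeric(thickness) || thickness <= 0) stop("`thickness` must be positive")
  column_geometry(0, thickness, area_inner, area_outer)
}

column_geometry <- function(wm_position, pial_position, area_inner, area_outer) {
  if (pial_position <= wm_position)
    stop("pial position must exceed WM position")
  if (area_inner <= 0 || area_outer <= 0) stop("boundary areas must be positive")
  structure(list(wm_position = wm_position, pial_position = pial_position,
                 area_inner = area_inner, area_outer = area_outer),
            class = "column_geometry")
}

#' @export
print.column_geometry <- function(x, ...) {
  cat("Column geometry: WM at", x$wm_position, "mm, pial at", x$pial_position,
      "mm; areas", x$area_inner, "->", x$area_outer, "\n")
  invisible(x)
}
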