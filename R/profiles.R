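#' Event-related average of a time-series
#'
#' Aligns the series at each stimulus block onset, extracts a fixed-length
#' window of volumes per trial (the first volume acquired at or after
#' `onset + window_s[1]`, then `floor(diff(window_s)/tr)` volumes) and averages
#' pointwise across trials. Trials whose window is not fully contained in the
#' series (including the pre-stimulus part) are dropped; if no complete trial
#' remains an error is raised.
#'
#' @param series a `perfusion_series`, `bold_series`, `asl_timeseries`, or a
#'   list with `values` (matrix, series in rows) and `tr`.
#' @param design the `stimulus_design` that produced the run.
#' @param window_s length-2 numeric: window relative to onset in seconds,
#'   default `c(-10, 40)` (10 s pre-stimulus baseline, 40 s response).
#' @return An object of class `event_average`: list with `time` (seconds
#'   relative to onset, spacing = tr), `mean` and `sem` (matrices, series in
#'   rows), `n_trials`, `tr`.
#' @export
event_related_average <- function(series, design, window_s = c(-10, 40)) {
  v <- series$values
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  tr <- series$tr
  if (length(window_s) != 2 || diff(window_s) <= 0)
    stop("`window_s` must be an increasing length-2 window")
  onsets <- block_onsets(design)
  if (length(onsets) == 0) stop("design has no stimulus blocks")
  n <- ncol(v)
  t_i <- (seq_len(n) - 1) * tr
  len <- floor(diff(window_s) / tr)
  if (len < 1) stop("window shorter than one TR")
  starts <- integer(0)
  rel0 <- numeric(0)
  for (onset in onsets) {
    i0 <- match(TRUE, t_i >= onset + window_s[1])
    if (is.na(i0) || i0 + len - 1 > n) next # incomplete trial: drop
    starts <- c(starts, i0)
    rel0 <- c(rel0, t_i[i0] - onset)
  }
  if (length(starts) == 0)
    stop("no stimulus block with a complete window inside the series")
  k <- nrow(v)
  trials <- array(NA_real_, c(k, len, length(starts)))
  for (j in seq_along(starts))
    trials[, , j] <- v[, starts[j] + seq_len(len) - 1, drop = FALSE]
  mu <- apply(trials, c(1, 2), mean)
  sem <- if (length(starts) > 1)
    apply(trials, c(1, 2), stats::sd) / sqrt(length(starts))
  else matrix(0, k, len)
  structure(list(time = mean(rel0) + (seq_len(len) - 1) * tr,
                 mean = mu, sem = sem,
                 n_trials = length(starts), tr = tr),
            class = "event_average")
}

#' @export
print.event_average <- function(x, ...) {
  cat("Event-related average:", nrow(x$mean), "series,", length(x$time),
      "timepoints (", round(x$time[1], 2), "to",
      round(x$time[length(x$time)], 2), "s ),", x$n_trials, "trials\n")
  invisible(x)
}

era_baseline <- function(era, prestim_window_s) {
  cols <- era$time < 0 & era$time >= -prestim_window_s
  if (!any(cols)) stop("no samples in the pre-stimulus window")
  rowMeans(era$mean[, cols, drop = FALSE])
}

rescale_era <- function(era, offset, scale) {
  era$mean <- (era$mean - offset) * scale
  era$sem <- era$sem * abs(scale)
  era
}

#' Percent BOLD signal change
#'
#' Rescales an event-related average to percent change relative to its
#' pre-stimulus baseline: `100 (mean - baseline) / baseline`, per series.
#'
#' @param era an `event_average` of a BOLD series.
#' @param prestim_window_s pre-stimulus baseline duration in seconds
#'   (default 10).
#' @return an `event_average` in percent units.
#' @export
percent_bold_change <- function(era, prestim_window_s = 10) {
  b <- era_baseline(era, prestim_window_s)
  if (any(b == 0)) stop("zero pre-stimulus baseline")
  rescale_era(era, b, 100 / b)
}

#' Absolute perfusion change
#'
#' Change in the perfusion-weighted signal from its pre-stimulus baseline,
#' normalised by the mean EPI signal to remove transmit/receive bias and
#' baseline T2* weighting. The result is in arbitrary units proportional to
#' the quantitative perfusion change.
#'
#' @param perf_era an `event_average` of a perfusion-weighted series.
#' @param prestim_window_s pre-stimulus baseline duration (default 10 s).
#' @param mean_epi temporal mean of the raw EPI signal, scalar or one value
#'   per series; must be positive.
#' @return an `event_average` in a.u.
#' @export
absolute_perfusion_change <- function(perf_era, prestim_window_s = 10,
                                      mean_epi) {
  if (any(mean_epi <= 0)) stop("`mean_epi` must be positive")
  b <- era_baseline(perf_era, prestim_window_s)
  rescale_era(perf_era, b, 1 / mean_epi)
}

#' Relative perfusion change
#'
#' Percent change of the perfusion-weighted signal relative to its own
#' pre-stimulus baseline per depth; the mean-EPI normalisation cancels in the
#' ratio, so none is applied.
#'
#' @inheritParams absolute_perfusion_change
#' @return an `event_average` in percent units.
#' @export
relative_perfusion_change <- function(perf_era, prestim_window_s = 10) {
  b <- era_baseline(perf_era, prestim_window_s)
  if (any(b <= 0)) stop("non-positive perfusion baseline")
  rescale_era(perf_era, b, 100 / b)
}

#' Laminar profile container
#'
#' A value with dispersion per cortical depth, depths normalised 0 (WM-side
#' boundary) to 1 (CSF-side boundary) and strictly increasing.
#'
#' @param depth normalised depths.
#' @param value signal values (percent change or a.u.).
#' @param dispersion SEM per depth (default 0).
#' @return a data frame of class `laminar_profile`.
#' @export
laminar_profile <- function(depth, value, dispersion = 0) {
  if (length(value) != length(depth))
    stop("`depth` and `value` lengths differ")
  if (is.unsorted(depth, strictly = TRUE))
    stop("depths must be strictly increasing")
  structure(data.frame(depth = depth, value = value,
                       dispersion = rep_len(dispersion, length(depth))),
            class = c("laminar_profile", "data.frame"))
}

#' Steady-state laminar profile from event-related averages
#'
#' Averages each depth's event-related response over the steady-state interval
#' following stimulus onset (default 14 to 28 s, half-open `[14, 28)`), when
#' the haemodynamic response has plateaued.
#'
#' @param era an `event_average` with one row per depth.
#' @param depth_norm normalised depth per row of `era$mean`.
#' @param interval_s length-2 steady-state interval in seconds after onset.
#' @return a `laminar_profile`; dispersion is the across-trial SEM averaged
#'   over the interval.
#' @export
steady_state_profile <- function(era, depth_norm, interval_s = c(14, 28)) {
  cols <- era$time >= interval_s[1] & era$time < interval_s[2]
  if (!any(cols)) stop("no event-average samples inside the steady-state interval")
  laminar_profile(depth_norm,
                  rowMeans(era$mean[, cols, drop = FALSE]),
                  rowMeans(era$sem[, cols, drop = FALSE]))
}

#' Least-squares line through a laminar profile
#'
#' Fits `value ~ depth` (depth normalised 0 = WM-side to 1 = CSF-side) and
#' reports the slope in value units per unit depth, its standard error, and
#' the coefficient of determination (defined as 0 for a zero-variance
#' profile).
#'
#' @param profile a `laminar_profile` with at least 3 depths.
#' @return list with `slope`, `slope_se`, `intercept`, `r_squared`.
#' @export
profile_linefit <- function(profile) {
  if (nrow(profile) < 3) stop("line fit needs at least 3 depths")
  if (stats::var(profile$value) == 0)
    return(list(slope = 0, slope_se = 0, intercept = profile$value[1],
                r_squared = 0))
  fit <- stats::lm(value ~ depth, data = profile)
  # noiseless synthetic profiles can be exactly linear; summary.lm warns then
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)["depth"]),
       slope_se = sm$coefficients["depth", "Std. Error"],
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared)
}

#' Pearson correlation between two laminar profiles
#'
#' @param a,b `laminar_profile`s on identical depth grids (>= 3 depths).
#' @return sample Pearson correlation of the value vectors.
#' @export
pearson_r <- function(a, b) {
  if (nrow(a) != nrow(b) || max(abs(a$depth - b$depth)) > 1e-9)
    stop("profiles must share the same depth grid")
  if (nrow(a) < 3) stop("correlation needs at least 3 depths")
  if (stats::var(a$value) == 0 || stats::var(b$value) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a$value, b$value)
}

#' Group-average laminar profile
#'
#' Unweighted mean across replicates (participants/runs) with SEM per depth.
#'
#' @param profiles list of `laminar_profile`s on identical depth grids.
#' @return a `laminar_profile` whose dispersion is the across-replicate SEM.
#' @export
group_profile <- function(profiles) {
  if (length(profiles) < 1) stop("empty profile list")
  d <- profiles[[1]]$depth
  vals <- vapply(profiles, function(p) {
    if (max(abs(p$depth - d)) > 1e-9) stop("profiles on different depth grids")
    p$value
  }, numeric(length(d)))
  vals <- matrix(vals, nrow = length(d))
  sem <- if (ncol(vals) > 1) apply(vals, 1, stats::sd) / sqrt(ncol(vals)) else 0
  laminar_profile(d, rowMeans(vals), sem)
}
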