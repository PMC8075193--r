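#' Perfusion-weighted series by surround subtraction
#'
#' Separates the label/control zig-zag from an interleaved ASL series. For an
#' interior volume i, `p_i = sigma_i * (s_i - (s_{i-1} + s_{i+1}) / 2)` with
#' `sigma_i = +1` for control and `-1` for label volumes, so `p` measures the
#' control-minus-label modulation depth (positive for physiologically sensible
#' input). Endpoints use the single available neighbour
#' (`p_1 = sigma_1 (s_1 - s_2)`, symmetric at the end), keeping the output the
#' same length as the input. Any component affine in time cancels exactly at
#' interior volumes (the second difference of a line is zero), which is why
#' surround subtraction suppresses drift and reduces BOLD contamination.
#'
#' @param series an `asl_timeseries` with at least 3 volumes.
#' @return An object of class `perfusion_series`: list with `values` (same
#'   shape as the input values) and `tr`.
#' @export
surround_subtract <- function(series) {
  stopifnot(inherits(series, "asl_timeseries"))
  s <- series$values
  n <- ncol(s)
  if (n < 3) stop("surround subtraction needs at least 3 volumes")
  p <- s
  p[, 2:(n - 1)] <- s[, 2:(n - 1)] - (s[, 1:(n - 2)] + s[, 3:n]) / 2
  p[, 1] <- s[, 1] - s[, 2]
  p[, n] <- s[, n] - s[, n - 1]
  p <- sweep(p, 2, sign_of_parity(series$parity), `*`)
  structure(list(values = p, tr = series$tr), class = "perfusion_series")
}

#' BOLD series by surround averaging
#'
#' Removes the alternating label/control component while preserving the slow
#' signal envelope: interior `b_i = s_i/2 + (s_{i-1} + s_{i+1})/4`; endpoints
#' are the mean of the volume and its single neighbour. On noiseless synthetic
#' data the result equals the BOLD envelope minus half the perfusion
#' modulation at interior volumes with locally constant perfusion.
#'
#' @param series an `asl_timeseries` with at least 3 volumes.
#' @return An object of class `bold_series`: list with `values`, `tr`.
#' @export
surround_average <- function(series) {
  stopifnot(inherits(series, "asl_timeseries"))
  s <- series$values
  n <- ncol(s)
  if (n < 3) stop("surround averaging needs at least 3 volumes")
  b <- s
  b[, 2:(n - 1)] <- s[, 2:(n - 1)] / 2 + (s[, 1:(n - 2)] + s[, 3:n]) / 4
  b[, 1] <- (s[, 1] + s[, 2]) / 2
  b[, n] <- (s[, n] + s[, n - 1]) / 2
  structure(list(values = b, tr = series$tr), class = "bold_series")
}

#' Baseline perfusion from rest-period label/control pairs
#'
#' Mean of simple control-minus-label differences over adjacent volume pairs
#' restricted to a baseline selection (typically the initial rest period and
#' pre-stimulus intervals). Lone volumes without an adjacent partner in the
#' selection are ignored.
#'
#' @param series an `asl_timeseries`.
#' @param baseline_volumes integer vector of 1-based volume indices considered
#'   baseline.
#' @param pairing `"adjacent"` (default): greedy disjoint adjacent pairs within
#'   the selection; `"control_with_preceding"` / `"control_with_following"`
#'   pair each selected control volume with its preceding/following label
#'   volume (the acquisition literature is agnostic on the direction).
#' @return numeric vector: mean control-minus-label difference per depth/voxel.
#' @export
baseline_perfusion <- function(series, baseline_volumes,
                               pairing = c("adjacent",
                                           "control_with_preceding",
                                           "control_with_following")) {
  stopifnot(inherits(series, "asl_timeseries"))
  pairing <- match.arg(pairing)
  n <- ncol(series$values)
  sel <- sort(unique(as.integer(baseline_volumes)))
  if (any(sel < 1 | sel > n)) stop("baseline volume indices out of range")
  in_sel <- logical(n)
  in_sel[sel] <- TRUE
  pairs <- list()
  if (pairing == "adjacent") {
    i <- 1
    while (i < length(sel)) {
      if (sel[i + 1] == sel[i] + 1) {
        pairs[[length(pairs) + 1]] <- c(sel[i], sel[i] + 1)
        i <- i + 2
      } else i <- i + 1
    }
  } else {
    off <- if (pairing == "control_with_preceding") -1L else 1L
    for (i in sel[series$parity[sel] == "control"]) {
      j <- i + off
      if (j >= 1 && j <= n && in_sel[j])
        pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  if (length(pairs) == 0)
    stop("no complete label-control pair in the baseline selection")
  diffs <- vapply(pairs, function(pr) {
    ctrl <- pr[series$parity[pr] == "control"]
    lab <- pr[series$parity[pr] == "label"]
    series$values[, ctrl] - series$values[, lab]
  }, numeric(nrow(series$values)))
  diffs <- matrix(diffs, nrow = nrow(series$values))
  rowMeans(diffs)
}

#' Temporal SNR of a perfusion-weighted series
#'
#' Ratio of the temporal mean to the temporal (sample) standard deviation of
#' the perfusion-weighted time-series, per depth/voxel.
#'
#' @param perf a `perfusion_series` (or any list with a `values` matrix).
#' @return numeric vector of tSNR values.
#' @export
perfusion_tsnr <- function(perf) {
  v <- perf$values
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  if (ncol(v) < 2) stop("tSNR needs at least 2 volumes")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) stop("zero temporal variance: tSNR undefined")
  rowMeans(v) / sds
}
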