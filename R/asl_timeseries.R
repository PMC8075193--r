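#' ASL time-series container
#'
#' An interleaved label/control ASL time-series: a numeric matrix of signal
#' values (rows = cortical depths or voxels, columns = volumes), a per-volume
#' parity tag (`"label"` or `"control"`) and the repetition time. The parity
#' must strictly alternate, which is what produces the characteristic zig-zag
#' modulation of raw ASL signal.
#'
#' @param values numeric matrix (depths/voxels x volumes) or a vector for a
#'   single depth, in arbitrary MRI signal units.
#' @param parity character vector, one of `"label"`/`"control"` per volume.
#' @param tr repetition time in seconds per volume.
#' @return An object of class `asl_timeseries` with elements `values`,
#'   `parity`, `tr`.
#' @export
asl_timeseries <- function(values, parity, tr) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix or vector")
  parity <- as.character(parity)
  if (length(parity) != ncol(values))
    stop("length of `parity` (", length(parity),
         ") must equal the number of volumes (", ncol(values), ")")
  if (!all(parity %in% c("label", "control")))
    stop("parity tags must be 'label' or 'control'")
  if (length(parity) >= 2 && any(parity[-1] == parity[-length(parity)]))
    stop("parity must strictly alternate between label and control")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop("`tr` must be a single positive number")
  structure(list(values = values, parity = parity, tr = tr),
            class = "asl_timeseries")
}

#' @export
print.asl_timeseries <- function(x, ...) {
  cat("ASL time-series:", nrow(x$values), "depth(s) x", ncol(x$values),
      "volumes, TR =", x$tr, "s, first volume =", x$parity[1], "\n")
  invisible(x)
}

#' Volume acquisition times of a series
#'
#' Timestamps are `t_i = i * tr` with `i` starting at 0 (first volume at 0 s).
#'
#' @param x an `asl_timeseries` or a `stimulus_design`.
#' @return numeric vector of acquisition times in seconds.
#' @export
volume_times <- function(x) {
  n <- if (inherits(x, "asl_timeseries")) ncol(x$values) else x$n_volumes
  (seq_len(n) - 1) * x$tr
}

sign_of_parity <- function(parity) ifelse(parity == "control", 1, -1)
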