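#' Canonical double-gamma HRF kernel
#'
#' `h(t) = (t/6)^6 exp(6 - t) - (1/6) (t/16)^16 exp(16 - t)`: a positive
#' response peaking at 6 s and an undershoot peaking at 16 s with 1/6 relative
#' amplitude, sampled at the TR and normalised to unit sum, so convolving a
#' regressor with the kernel preserves its plateau level.
#'
#' @param tr sampling interval (seconds), positive.
#' @param length_s kernel support in seconds (default 32).
#' @return numeric kernel summing to 1.
#' @export
canonical_hrf <- function(tr, length_s = 32) {
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop("`tr` must be a single positive number")
  t <- seq(0, length_s, by = tr)
  h <- (t / 6)^6 * exp(6 - t) - (1 / 6) * (t / 16)^16 * exp(16 - t)
  h / sum(h)
}

# Causal convolution of a regressor with a kernel, truncated to input length.
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")
  out[seq_len(n)]
}

#' Three-regressor ASL design matrix
#'
#' The full perfusion signal model for interleaved ASL data:
#' \itemize{
#'   \item `bold`: the stimulus boxcar convolved with the canonical HRF,
#'     mean-centred;
#'   \item `baseline_perfusion`: the alternating label/control acquisition,
#'     +1/2 for control and -1/2 for label volumes;
#'   \item `perfusion_activation`: the elementwise product of the parity
#'     regressor with the (un-centred) HRF-convolved boxcar, capturing the
#'     stimulus-driven change in zig-zag modulation depth;
#'   \item `intercept`: all ones.
#' }
#' Centring the BOLD regressor but not the interaction keeps the parity beta
#' interpretable as baseline perfusion and the interaction beta as perfusion
#' change (the usual ASL-GLM convention); `centre_interaction = TRUE` switches
#' to a centred interaction.
#'
#' @param design a `stimulus_design`.
#' @param parity character vector of per-volume `"label"`/`"control"` tags.
#' @param centre_interaction logical; default FALSE.
#' @return numeric matrix `n_volumes x 4` with the column names above.
#' @export
build_design <- function(design, parity, centre_interaction = FALSE) {
  stopifnot(inherits(design, "stimulus_design"))
  if (length(parity) != design$n_volumes)
    stop("`parity` length must equal n_volumes")
  conv <- convolve_hrf(boxcar(design), canonical_hrf(design$tr))
  if (all(conv == 0))
    stop("degenerate design: no stimulus blocks, BOLD and interaction regressors are zero")
  x2 <- ifelse(parity == "control", 0.5, -0.5)
  x3 <- x2 * (if (centre_interaction) conv - mean(conv) else conv)
  X <- cbind(bold = conv - mean(conv), baseline_perfusion = x2,
             perfusion_activation = x3, intercept = 1)
  X
}

#' Ordinary least squares fit of the ASL GLM
#'
#' Voxelwise (or depthwise) OLS estimation of the three-regressor model with
#' t-statistics against zero. No temporal autocorrelation model is applied
#' (white-noise assumption).
#'
#' @param Y numeric matrix of series, depths/voxels in rows and volumes in
#'   columns (a vector is treated as one series), or an `asl_timeseries`.
#' @param X design matrix from [build_design()].
#' @return An object of class `glm_result`: list with matrices `betas`, `se`,
#'   `t` (rows = series, columns = regressors) and scalar `df`.
#' @export
fit_glm <- function(Y, X) {
  if (inherits(Y, "asl_timeseries")) Y <- Y$values
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  n <- ncol(Y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design and data have different numbers of volumes")
  if (n <= p) stop("need more volumes than regressors")
  qx <- qr(X)
  if (qx$rank < p) stop("singular design matrix")
  coef <- t(qr.coef(qx, t(Y)))          # k x p
  fitted <- coef %*% t(X)
  resid <- Y - fitted
  df <- n - p
  sigma2 <- rowSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  colnames(se) <- colnames(X)
  structure(list(betas = coef, se = se, t = coef / se, df = df),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("ASL GLM fit:", nrow(x$betas), "series,", x$df, "residual df\n")
  print(round(x$betas, 4))
  invisible(x)
}

#' Overlap mask of BOLD and perfusion activation
#'
#' A voxel is retained iff both its BOLD t-statistic and its perfusion
#' activation t-statistic reach the threshold, ensuring both signals are
#' sampled from the same voxels.
#'
#' @param bold_t,perf_t congruent numeric arrays of t-statistics.
#' @param threshold scalar t threshold.
#' @return logical array of the common shape.
#' @export
overlap_mask <- function(bold_t, perf_t, threshold) {
  if (!identical(dim(bold_t), dim(perf_t)) ||
      length(bold_t) != length(perf_t))
    stop("t maps must have identical shape")
  bold_t >= threshold & perf_t >= threshold
}
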