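#' Partial-Fourier k-space sampling mask (1-D)
#'
#' Builds the asymmetric coverage used by phase partial-Fourier acquisitions:
#' one full half of k-space plus a contiguous strip of the other half, so that
#' `fraction` of the lines are acquired. k-space indices run from `-length/2`
#' to `length/2 - 1` with the centre at index 0; the positive side (including
#' the centre) is the fully sampled half.
#'
#' @param length number of k-space samples (even).
#' @param fraction acquired fraction, in (0.5, 1]. A fraction of 5/8 matches
#'   the phase partial-Fourier factor of the acquisition modelled here.
#' @param full_side which half is fully sampled: `"positive"` (default) or
#'   `"negative"`. Arbitrary in the physics; fixed for reproducibility.
#' @return An object of class `sampling_mask`: list with `length`, `acquired`
#'   (logical per index), `fraction` (realised fraction), `k_index`.
#' @export
partial_fourier_mask <- function(length, fraction,
                                 full_side = c("positive", "negative")) {
  full_side <- match.arg(full_side)
  if (length %% 2 != 0 || length < 4) stop("`length` must be even and >= 4")
  if (fraction <= 0.5)
    stop("`fraction` must exceed 1/2: the phase cannot be estimated otherwise")
  if (fraction > 1) stop("`fraction` cannot exceed 1")
  k <- seq(-length / 2, length / 2 - 1)
  n_extra <- round((fraction - 0.5) * length)
  acquired <- if (full_side == "positive") k >= -n_extra else k < n_extra
  structure(list(length = length, acquired = acquired,
                 fraction = sum(acquired) / length, k_index = k),
            class = "sampling_mask")
}

# fftshift/ifftshift for even-length vectors (swap halves).
fftshift <- function(x) {
  n <- length(x)
  c(x[(n %/% 2 + 1):n], x[seq_len(n %/% 2)])
}

# Image-domain profile from a centred k-space vector, optionally evaluated on
# an oversampled grid by zero-padding k-space symmetrically.
image_from_kspace <- function(kspace, oversample = 1) {
  n <- length(kspace)
  m <- n * oversample
  kp <- complex(m)
  kp[(m / 2 - n / 2 + 1):(m / 2 + n / 2)] <- kspace
  fftshift(stats::fft(fftshift(kp), inverse = TRUE)) / n
}

kspace_from_image <- function(image, n) {
  m <- length(image)
  kfull <- fftshift(stats::fft(fftshift(image))) # centred
  kfull[(m / 2 - n / 2 + 1):(m / 2 + n / 2)]
}

#' Zero-fill reconstruction of partially sampled 1-D k-space
#'
#' Sets unacquired samples to zero and inverse-Fourier-transforms. This is the
#' default vendor behaviour that the nominal point-spread-function simulation
#' assumes.
#'
#' @param kspace complex (or numeric) vector of centred k-space samples.
#' @param mask a `sampling_mask` of the same length.
#' @param oversample integer image-grid oversampling factor (zero-padding of
#'   k-space); 1 returns the native grid.
#' @return complex image-domain profile of length `length(kspace) * oversample`.
#' @export
zero_fill_recon <- function(kspace, mask, oversample = 1) {
  if (length(kspace) != mask$length)
    stop("`kspace` and `mask` lengths differ")
  k <- as.complex(kspace)
  k[!mask$acquired] <- 0
  image_from_kspace(k, oversample)
}

#' POCS reconstruction of partial-Fourier 1-D k-space
#'
#' Projection-onto-convex-sets homodyne-type reconstruction: a low-resolution
#' phase map is estimated from the symmetric central band of k-space (width
#' `2 (fraction - 1/2) length`, Hann-apodised); each iteration projects the
#' current image onto the set of images with that phase, then restores the
#' acquired k-space samples (data consistency). Eight iterations is the
#' vendor default reproduced here.
#'
#' @inheritParams zero_fill_recon
#' @param n_iter number of POCS iterations (>= 1, default 8).
#' @return complex image-domain profile (acquired k-space samples of its
#'   transform match the input exactly).
#' @export
pocs_recon <- function(kspace, mask, n_iter = 8, oversample = 1) {
  if (length(kspace) != mask$length)
    stop("`kspace` and `mask` lengths differ")
  if (mask$fraction <= 0.5) stop("mask fraction must exceed 1/2")
  if (n_iter < 1) stop("`n_iter` must be >= 1")
  n <- mask$length
  data <- as.complex(kspace)
  data[!mask$acquired] <- 0
  n_extra <- max(1, round((mask$fraction - 0.5) * n))
  # symmetric central band, Hann-apodised with its peak at the k-space centre
  # so the estimate carries no phase ramp
  w <- ifelse(abs(mask$k_index) <= n_extra,
              0.5 * (1 + cos(pi * mask$k_index / n_extra)), 0)
  phase <- Arg(image_from_kspace(data * w, 1))
  kcur <- data
  for (it in seq_len(n_iter)) {
    img <- image_from_kspace(kcur, 1)
    img <- Re(img * exp(-1i * phase)) * exp(1i * phase) # phase projection
    kcur <- kspace_from_image(img, n)
    kcur[mask$acquired] <- kspace[mask$acquired]        # data consistency
  }
  image_from_kspace(kcur, oversample)
}

#' Full width at half maximum of a point-spread profile
#'
#' Peak-normalised width at half the maximum magnitude, measured with linear
#' interpolation between samples and divided by the oversampling factor, so
#' the result is in nominal voxel units.
#'
#' @param profile numeric or complex image-domain profile (magnitude is used).
#' @param oversample the factor relating profile samples to nominal voxels.
#' @return FWHM in nominal voxels.
#' @export
psf_fwhm <- function(profile, oversample = 1) {
  mag <- Mod(profile)
  if (diff(range(mag)) == 0) stop("flat profile: FWHM undefined")
  peak <- which.max(mag)
  half <- mag[peak] / 2
  li <- peak
  while (li > 1 && mag[li] > half) li <- li - 1
  ri <- peak
  while (ri < length(mag) && mag[ri] > half) ri <- ri + 1
  if (mag[li] > half || mag[ri] > half)
    stop("half-maximum level not reached within the profile")
  xl <- li + (half - mag[li]) / (mag[li + 1] - mag[li])
  xr <- ri - (half - mag[ri]) / (mag[ri - 1] - mag[ri])
  (xr - xl) / oversample
}

#' Simulate the 1-D partial-Fourier point spread function
#'
#' Convenience wrapper reproducing the nominal PSF computation along the
#' phase-encoding direction: a centred point object (unit k-space), a
#' partial-Fourier sampling mask, zero-fill or POCS reconstruction, and the
#' magnitude profile on an oversampled grid.
#'
#' @param matrix_size number of phase-encode lines (even), default 64.
#' @param fraction partial-Fourier fraction, default 5/8.
#' @param recon `"zerofill"` (default, the nominal simulation) or `"pocs"`.
#' @param n_iter POCS iterations (default 8).
#' @param oversample image-grid oversampling factor (default 16).
#' @return list with `profile` (magnitude), `fwhm_voxels`, `oversample`,
#'   `mask`.
#' @export
simulate_psf <- function(matrix_size = 64, fraction = 5 / 8,
                         recon = c("zerofill", "pocs"), n_iter = 8,
                         oversample = 16) {
  recon <- match.arg(recon)
  kspace <- rep(1 + 0i, matrix_size) # point object at the grid centre
  mask <- partial_fourier_mask(matrix_size, fraction)
  img <- switch(recon,
    zerofill = zero_fill_recon(kspace, mask, oversample),
    pocs = pocs_recon(kspace, mask, n_iter, oversample))
  prof <- Mod(img)
  list(profile = prof, fwhm_voxels = psf_fwhm(prof, oversample),
       oversample = oversample, mask = mask)
}
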