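#' Extend cortical boundaries into WM and CSF
#'
#' Moves the WM boundary into white matter and the pial boundary into CSF by
#' `fraction` of the cortical thickness each (default 30%), to guard against
#' boundary placement errors and to sample away from the pial surface. The
#' linear area profile is extrapolated to the extended boundaries.
#'
#' @param geometry a `column_geometry`.
#' @param fraction extension as a fraction of cortical thickness, in [0, 1).
#' @return A new `column_geometry` spanning the extended range.
#' @export
extend_boundaries <- function(geometry, fraction = 0.3) {
  stopifnot(inherits(geometry, "column_geometry"))
  if (!is.numeric(fraction) || fraction < 0) stop("`fraction` must be >= 0")
  if (fraction >= 1) stop("`fraction` must be < 1")
  thick <- geometry$pial_position - geometry$wm_position
  slope <- (geometry$area_outer - geometry$area_inner) / thick
  a_in <- geometry$area_inner - fraction * thick * slope
  a_out <- geometry$area_outer + fraction * thick * slope
  if (a_in <= 0 || a_out <= 0)
    stop("extension makes an extrapolated boundary area non-positive")
  column_geometry(geometry$wm_position - fraction * thick,
                  geometry$pial_position + fraction * thick,
                  a_in, a_out)
}

#' Equi-volume cortical depth set
#'
#' Places `n_intermediate` surfaces inside the column so that consecutive
#' surfaces bound slabs of equal tissue volume, compensating curvature: for a
#' column with cross-sectional area linear in depth between `area_inner` and
#' `area_outer`, the depth (normalised x in [0,1] from the WM-side boundary)
#' enclosing volume fraction rho solves
#' `A_in x + (A_out - A_in) x^2 / 2 = rho (A_in + A_out) / 2`, giving
#' \deqn{x = \frac{-A_{in} + \sqrt{(1-\rho) A_{in}^2 + \rho A_{out}^2}}
#'            {A_{out} - A_{in}}}
#' and reducing to the equidistant `x = rho` when the areas are equal (flat
#' cortex). The returned set includes both boundaries, so 21 intermediate
#' surfaces yield 23 sampling depths.
#'
#' @param geometry a `column_geometry` (typically already boundary-extended).
#' @param n_intermediate number of intermediate surfaces (>= 1; default 21).
#' @return An object of class `depth_set`: list with `positions` (physical
#'   depth coordinates, WM-side first), `normalized` (fractions in [0, 1] over
#'   the span) and `n_depths`.
#' @export
equivolume_depths <- function(geometry, n_intermediate = 21) {
  stopifnot(inherits(geometry, "column_geometry"))
  if (n_intermediate < 1 || n_intermediate != round(n_intermediate))
    stop("`n_intermediate` must be a positive integer")
  a_in <- geometry$area_inner
  a_out <- geometry$area_outer
  rho <- seq_len(n_intermediate) / (n_intermediate + 1)
  x <- if (abs(a_out - a_in) < 1e-12 * max(a_in, a_out)) rho else
    (-a_in + sqrt((1 - rho) * a_in^2 + rho * a_out^2)) / (a_out - a_in)
  normalized <- c(0, x, 1)
  span <- geometry$pial_position - geometry$wm_position
  structure(list(positions = geometry$wm_position + normalized * span,
                 normalized = normalized,
                 n_depths = n_intermediate + 2L),
            class = "depth_set")
}

#' @export
print.depth_set <- function(x, ...) {
  cat("Depth set:", x$n_depths, "depths from", x$positions[1], "to",
      x$positions[x$n_depths], "mm\n")
  invisible(x)
}

#' Cumulative tissue volume of a column up to a depth
#'
#' Analytic integral of the linear area profile from the WM-side boundary;
#' used to verify the equi-volume property.
#'
#' @param geometry a `column_geometry`.
#' @param position physical depth coordinate(s) within the column.
#' @return cumulative volume (area units x mm).
#' @export
column_volume_to <- function(geometry, position) {
  stopifnot(inherits(geometry, "column_geometry"))
  span <- geometry$pial_position - geometry$wm_position
  x <- (position - geometry$wm_position) / span
  if (any(x < -1e-12 | x > 1 + 1e-12)) stop("position outside the column")
  span * (geometry$area_inner * x +
            (geometry$area_outer - geometry$area_inner) * x^2 / 2)
}

#' Nearest-neighbour sampling of a depth-resolved source at given depths
#'
#' Each requested depth takes the value of the voxel whose centre is nearest;
#' ties are broken toward the WM side (the lower coordinate). Depths outside
#' the voxel extent (centres +/- half a voxel) raise an error.
#'
#' @param values numeric vector (one value per voxel along depth) or matrix
#'   with voxels in rows (e.g. a time-series: voxels x volumes).
#' @param centres voxel-centre depth coordinates, strictly increasing.
#' @param depths a `depth_set` or numeric vector of depth coordinates.
#' @return values at the requested depths: vector, or matrix with one row per
#'   depth.
#' @export
sample_to_depths <- function(values, centres, depths) {
  if (inherits(depths, "depth_set")) depths <- depths$positions
  if (is.unsorted(centres, strictly = TRUE))
    stop("`centres` must be strictly increasing")
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (nrow(values) != length(centres))
    stop("`values` must have one row per voxel centre")
  halfvox <- if (length(centres) > 1) stats::median(diff(centres)) / 2 else Inf
  lo <- centres[1] - halfvox
  hi <- centres[length(centres)] + halfvox
  if (any(depths < lo - 1e-12 | depths > hi + 1e-12))
    stop("requested depth outside the source extent")
  idx <- vapply(depths, function(d) {
    dist <- abs(centres - d)
    which(dist <= min(dist) + 1e-12)[1] # tie -> WM side (lower centre)
  }, integer(1))
  out <- values[idx, , drop = FALSE]
  if (ncol(out) == 1) drop(out) else out
}
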