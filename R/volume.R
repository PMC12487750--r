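# ImageVolume: a 3-D activity-concentration grid in Bq/mL. Axis order is
# (x, y, z) with z the scanner axis; `origin` is the world coordinate (mm) of
# the center of voxel [1, 1, 1].

#' Create an image volume
#'
#' @param voxels 3-D numeric array of activity concentrations in Bq/mL.
#' @param spacing 3-vector of voxel spacings in mm (> 0).
#' @param origin 3-vector, world coordinate (mm) of the first voxel center.
#' @param acquisition_start Timestamp of the acquisition start (decay
#'   reference for all ground-truth concentrations).
#' @param radionuclide Radionuclide name (registry entry).
#' @param meta Optional named list of extra metadata (kept on round-trips).
#' @return Object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin, acquisition_start,
                         radionuclide, meta = list()) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("spacing components must be > 0", call. = FALSE)
  if (!all(is.finite(voxels))) stop("all voxel values must be finite",
                                    call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 acquisition_start = .as_time(acquisition_start),
                 radionuclide = .as_nuclide(radionuclide)$name,
                 units = "Bq/mL", meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %dx%dx%d voxels, %.3g x %.3g x %.3g mm, %s, %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$radionuclide, x$units))
  cat(sprintf("  acquired %s; range %.4g to %.4g Bq/mL\n",
              format(x$acquisition_start, "%Y-%m-%d %H:%M:%S %Z"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# World coordinates of voxel centers along axis k
.axis_coords <- function(vol, k) {
  vol$origin[k] + (seq_len(dim(vol$voxels)[k]) - 1) * vol$spacing[k]
}

# Voxel volume in mL (mm^3 / 1000)
.voxel_ml <- function(vol) prod(vol$spacing) / 1000

# Trilinear interpolation of vol$voxels at world points (n x 3 matrix, mm).
# Points outside the grid take the nearest-edge value (clamped); callers
# restrict to interior use.
.interp3 <- function(vol, pts) {
  d <- dim(vol$voxels)
  g <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")  # 0-based
  g <- pmin(pmax(g, 0), matrix(rep(d - 1, each = nrow(pts)), ncol = 3))
  i0 <- pmin(floor(g), matrix(rep(d - 2, each = nrow(pts)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- g - i0
  i0 <- i0 + 1  # 1-based lower corner
  A <- vol$voxels
  idx <- function(dx, dy, dz) {
    A[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  (idx(0, 0, 0) * (1 - f[, 1]) + idx(1, 0, 0) * f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
  (idx(0, 1, 0) * (1 - f[, 1]) + idx(1, 1, 0) * f[, 1]) * f[, 2] * (1 - f[, 3]) +
  (idx(0, 0, 1) * (1 - f[, 1]) + idx(1, 0, 1) * f[, 1]) * (1 - f[, 2]) * f[, 3] +
  (idx(0, 1, 1) * (1 - f[, 1]) + idx(1, 1, 1) * f[, 1]) * f[, 2] * f[, 3]
}
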