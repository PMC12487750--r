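# Calibration-bias analysis of uniform phantom volumes: slice-wise circular
# ROIs with a radial margin (2 cm by default, avoiding wall partial-volume
# effects), per-slice and global bias, and axial uniformity.

#' Per-slice circular ROI means
#'
#' For every transaxial slice, the mean of the voxels whose centers fall
#' inside a circular ROI of diameter `phantom_diameter_mm - margin_mm`
#' centered at `axis_center`.
#'
#' @param volume An [image_volume()].
#' @param axis_center 2-vector, world (x, y) of the ROI center in mm.
#' @param phantom_diameter_mm Phantom interior diameter in mm.
#' @param margin_mm Diameter reduction in mm (default 20: the ROI diameter is
#'   2 cm less than the phantom diameter).
#' @return Data frame with `slice_index`, `z_mm`, `mean` (Bq/mL), `n_voxels`.
#' @export
slice_roi_means <- function(volume, axis_center = c(0, 0), phantom_diameter_mm,
                            margin_mm = 20) {
  stopifnot(inherits(volume, "image_volume"))
  roi_d <- phantom_diameter_mm - margin_mm
  if (roi_d <= 0) stop("ROI diameter (phantom diameter - margin) must be > 0",
                       call. = FALSE)
  cx <- .axis_coords(volume, 1)
  cy <- .axis_coords(volume, 2)
  cz <- .axis_coords(volume, 3)
  r <- roi_d / 2
  if (axis_center[1] - r < min(cx) - volume$spacing[1] / 2 ||
      axis_center[1] + r > max(cx) + volume$spacing[1] / 2 ||
      axis_center[2] - r < min(cy) - volume$spacing[2] / 2 ||
      axis_center[2] + r > max(cy) + volume$spacing[2] / 2) {
    stop("ROI extends outside the image grid", call. = FALSE)
  }
  inside <- outer(cx - axis_center[1], cy - axis_center[2],
                  function(x, y) x^2 + y^2) <= r^2
  n <- sum(inside)
  if (n == 0) stop("ROI contains no voxel centers", call. = FALSE)
  means <- vapply(seq_along(cz),
                  function(iz) mean(volume$voxels[, , iz][inside]), 0)
  data.frame(slice_index = seq_along(cz), z_mm = cz, mean = means,
             n_voxels = n)
}

#' Calibration bias from measured and true background concentration
#'
#' `bias = C_bkg / A_bkg`: the image-derived background concentration divided
#' by the fill-derived true concentration. Unity means a perfectly calibrated
#' scanner.
#'
#' @param C_bkg_kbq_ml Image-derived concentration, kBq/mL.
#' @param A_bkg_kbq_ml Fill-derived true concentration, kBq/mL (> 0).
#' @return Dimensionless bias.
#' @export
calibration_bias <- function(C_bkg_kbq_ml, A_bkg_kbq_ml) {
  if (any(A_bkg_kbq_ml <= 0)) stop("A_bkg must be > 0", call. = FALSE)
  C_bkg_kbq_ml / A_bkg_kbq_ml
}

#' Analyze a calibration phantom acquisition
#'
#' Decay-corrects the background fill to the acquisition start, computes
#' per-slice circular-ROI means over the included slice range, and reports
#' the per-slice biases, their global (slice-averaged) value, and the axial
#' uniformity `max |per-slice bias - global| / global`.
#'
#' Slices whose centers lie within `end_exclusion_mm` of either physical
#' phantom end are excluded (axial partial volume at the ends); the radial
#' margin handles the transaxial direction.
#'
#' @param volume An [image_volume()] of the uniform phantom.
#' @param fill Background [fill_record()] (same radionuclide as the volume).
#' @param spec A [phantom_spec()] of `uniform_cylinder` kind.
#' @param axis_center 2-vector, phantom axis position in world mm.
#' @param margin_mm Radial ROI margin (default 20 mm).
#' @param end_exclusion_mm Axial end exclusion (default 10 mm).
#' @return Object of class `calibration_result`: list with `per_slice`
#'   (data frame of slice, mean, bias), `global_bias`, `axial_uniformity`,
#'   `roi_diameter_mm`, `slices_used`, `A_bkg_kbq_ml`, `acquisition_start`.
#' @export
analyze_calibration <- function(volume, fill, spec, axis_center = c(0, 0),
                                margin_mm = 20, end_exclusion_mm = 10) {
  stopifnot(inherits(volume, "image_volume"), inherits(fill, "fill_record"),
            inherits(spec, "phantom_spec"))
  if (spec$kind != "uniform_cylinder") {
    stop("calibration analysis requires a uniform_cylinder phantom ",
         "(or a declared uniform subregion)", call. = FALSE)
  }
  if (!identical(fill$nuclide$name, volume$radionuclide)) {
    stop("radionuclide mismatch between fill (", fill$nuclide$name,
         ") and volume (", volume$radionuclide, ")", call. = FALSE)
  }
  A_bkg <- concentration_at(fill, volume$acquisition_start)
  sl <- slice_roi_means(volume, axis_center, spec$cylinder_diameter_mm,
                        margin_mm)
  half_L <- spec$axial_length_mm / 2
  keep <- abs(sl$z_mm) <= half_L - end_exclusion_mm
  if (!any(keep)) stop("empty slice range after end exclusion", call. = FALSE)
  sl <- sl[keep, , drop = FALSE]
  sl$bias <- calibration_bias(sl$mean / 1000, A_bkg)
  global <- mean(sl$bias)
  structure(list(per_slice = sl, global_bias = global,
                 axial_uniformity = max(abs(sl$bias - global)) / global,
                 roi_diameter_mm = spec$cylinder_diameter_mm - margin_mm,
                 slices_used = range(sl$slice_index),
                 A_bkg_kbq_ml = A_bkg,
                 acquisition_start = volume$acquisition_start,
                 radionuclide = volume$radionuclide),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> global bias %.4f (%+.2f%%), %s\n",
              x$global_bias, 100 * (x$global_bias - 1), x$radionuclide))
  cat(sprintf("  A_bkg %.4g kBq/mL, ROI diameter %g mm, slices %d-%d, axial uniformity %.3g\n",
              x$A_bkg_kbq_ml, x$roi_diameter_mm, x$slices_used[1],
              x$slices_used[2], x$axial_uniformity))
  invisible(x)
}

#' Summarize calibration results from multiple axial positions
#'
#' For long axial field-of-view systems the calibration phantom is scanned at
#' several axial positions (1/4, 1/2 and 3/4 of the FOV); this summarizes the
#' per-position global biases and their maximum pairwise relative difference
#' (relative to the smaller of each pair).
#'
#' @param results Named list (>= 2) of [analyze_calibration()] results; names
#'   label the axial positions.
#' @return Data frame of per-position biases with attribute
#'   `max_pairwise_rel_diff`.
#' @export
multi_position_summary <- function(results) {
  if (length(results) < 2) stop("at least 2 axial positions required",
                                call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "calibration_result")))
  pos <- names(results) %||% as.character(seq_along(results))
  if (is.null(names(results))) names(results) <- pos
  b <- vapply(results, function(r) r$global_bias, 0)
  combs <- utils::combn(length(b), 2)
  rel <- apply(combs, 2, function(ij) {
    abs(b[ij[1]] - b[ij[2]]) / min(b[ij[1]], b[ij[2]])
  })
  out <- data.frame(position = pos, global_bias = as.numeric(b))
  attr(out, "max_pairwise_rel_diff") <- max(rel)
  out
}
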