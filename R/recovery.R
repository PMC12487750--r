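# Sphere VOI statistics and the CRC/RC machinery: centroid placement,
# exact-inner-diameter sphere VOI, maximum voxel, 1-cm3 peak, and curve
# assembly. VOI placement is image-driven (PET centroid); CT-based placement
# is deliberately not implemented (coregistration errors of up to 2 mm are
# common and would bias mean measurements).

#' Locate a hot sphere by iterated intensity-weighted centroid
#'
#' Computes the intensity-weighted centroid of background-subtracted voxels
#' within a search ball of radius `nominal_diameter_mm` around the current
#' center, iterating until the center shifts by less than `tol_mm` (default
#' 0.01 mm) or `max_iter` iterations.
#'
#' @param volume An [image_volume()].
#' @param seed_center 3-vector, world mm; starting point (e.g. the nominal
#'   sphere position from the phantom specification).
#' @param nominal_diameter_mm Nominal sphere inner diameter in mm.
#' @param background Background level in Bq/mL subtracted before weighting
#'   (negative residuals are clamped to zero).
#' @param tol_mm,max_iter Convergence controls.
#' @return 3-vector, estimated sphere center in world mm.
#' @export
locate_sphere_centroid <- function(volume, seed_center, nominal_diameter_mm,
                                   background = 0, tol_mm = 0.01,
                                   max_iter = 20L) {
  stopifnot(inherits(volume, "image_volume"), length(seed_center) == 3L)
  cx <- .axis_coords(volume, 1)
  cy <- .axis_coords(volume, 2)
  cz <- .axis_coords(volume, 3)
  if (seed_center[1] < min(cx) || seed_center[1] > max(cx) ||
      seed_center[2] < min(cy) || seed_center[2] > max(cy) ||
      seed_center[3] < min(cz) || seed_center[3] > max(cz)) {
    stop("seed_center lies outside the image grid", call. = FALSE)
  }
  ctr <- as.numeric(seed_center)
  Rs <- nominal_diameter_mm
  for (it in seq_len(max_iter)) {
    ix <- which(abs(cx - ctr[1]) <= Rs)
    iy <- which(abs(cy - ctr[2]) <= Rs)
    iz <- which(abs(cz - ctr[3]) <= Rs)
    if (!length(ix) || !length(iy) || !length(iz)) {
      stop("detection error: search ball contains no voxels", call. = FALSE)
    }
    pts <- as.matrix(expand.grid(cx[ix], cy[iy], cz[iz]))
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 + (pts[, 3] - ctr[3])^2
    inb <- d2 <= Rs^2
    w <- pmax(as.vector(volume$voxels[ix, iy, iz]) - background, 0)
    w[!inb] <- 0
    if (sum(w) <= 0) {
      stop("detection error: no signal above background in search ball",
           call. = FALSE)
    }
    new_ctr <- colSums(pts * w) / sum(w)
    shift <- sqrt(sum((new_ctr - ctr)^2))
    ctr <- new_ctr
    if (shift < tol_mm) break
  }
  ctr
}

#' Diameter of the spherical peak VOI for a given volume
#'
#' @param peak_volume_ml VOI volume in mL (default 1 mL, the SUVpeak
#'   convention; diameter about 12.407 mm).
#' @return Diameter in mm: `(6000 * v / pi)^(1/3)`.
#' @export
peak_voi_diameter <- function(peak_volume_ml = 1) {
  (6000 * peak_volume_ml / pi)^(1 / 3)
}

#' Sphere VOI statistics: mean, maximum voxel, and peak
#'
#' Computes, for a spherical VOI of the sphere's exact inner diameter centered
#' at `center`:
#' * `C_mean`: mean of voxel values whose centers fall inside the VOI (when
#'   `supersample > 1`, the mean of trilinearly interpolated values on a
#'   lattice refined by that factor per axis);
#' * `C_max`: maximum original-resolution voxel value in the VOI;
#' * `C_peak`: the highest mean of a `peak_volume_ml` sphere whose center
#'   lies inside the exact-size VOI, searched on a half-voxel grid; the peak
#'   mean is taken over original-resolution voxel centers. Ties in `C_max`
#'   resolve to the first voxel in array scan order.
#'
#' @param volume An [image_volume()].
#' @param center 3-vector, world mm (typically from
#'   [locate_sphere_centroid()]).
#' @param diameter_mm Sphere inner diameter in mm.
#' @param peak_volume_ml Peak VOI volume (default 1 mL).
#' @param supersample Sampling refinement factor per axis for `C_mean`
#'   (default 1 = voxel centers; 2 is the recommended refinement when voxels
#'   are coarse relative to the sphere).
#' @return Object of class `sphere_measurement`: list with
#'   `nominal_diameter_mm`, `center_estimate`, `C_mean`, `C_max`, `C_peak`
#'   (all concentrations in Bq/mL) and `n_voxels`.
#' @export
sphere_voi_stats <- function(volume, center, diameter_mm, peak_volume_ml = 1,
                             supersample = 1L) {
  stopifnot(inherits(volume, "image_volume"), length(center) == 3L,
            diameter_mm > 0, supersample >= 1)
  h <- volume$spacing
  R <- diameter_mm / 2
  cx <- .axis_coords(volume, 1)
  cy <- .axis_coords(volume, 2)
  cz <- .axis_coords(volume, 3)
  ix <- which(abs(cx - center[1]) <= R + h[1])
  iy <- which(abs(cy - center[2]) <= R + h[2])
  iz <- which(abs(cz - center[3]) <= R + h[3])
  if (!length(ix) || !length(iy) || !length(iz)) {
    stop("VOI lies outside the image grid", call. = FALSE)
  }
  pts <- as.matrix(expand.grid(cx[ix], cy[iy], cz[iz]))
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
        (pts[, 3] - center[3])^2
  inside <- d2 <= R^2
  vals <- as.vector(volume$voxels[ix, iy, iz])
  if (!any(inside)) {
    stop("empty VOI: sphere diameter ", diameter_mm, " mm is below the voxel ",
         "size; supersample the image before extraction", call. = FALSE)
  }
  C_max <- max(vals[inside])

  # mean: voxel centers, or refined lattice with trilinear interpolation
  if (supersample == 1L) {
    C_mean <- mean(vals[inside])
    n_mean <- sum(inside)
  } else {
    step <- h / supersample
    gx <- seq(center[1] - R, center[1] + R, by = step[1])
    gy <- seq(center[2] - R, center[2] + R, by = step[2])
    gz <- seq(center[3] - R, center[3] + R, by = step[3])
    gp <- as.matrix(expand.grid(gx, gy, gz))
    gin <- (gp[, 1] - center[1])^2 + (gp[, 2] - center[2])^2 +
           (gp[, 3] - center[3])^2 <= R^2
    C_mean <- mean(.interp3(volume, gp[gin, , drop = FALSE]))
    n_mean <- sum(gin)
  }

  # peak: candidate centers on a half-voxel lattice inside the exact VOI
  r_pk <- peak_voi_diameter(peak_volume_ml) / 2
  sx <- seq(center[1] - R, center[1] + R, by = h[1] / 2)
  sy <- seq(center[2] - R, center[2] + R, by = h[2] / 2)
  sz <- seq(center[3] - R, center[3] + R, by = h[3] / 2)
  cand <- as.matrix(expand.grid(sx, sy, sz))
  cin <- (cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2 +
         (cand[, 3] - center[3])^2 <= R^2
  cand <- cand[cin, , drop = FALSE]
  if (nrow(cand) == 0) cand <- matrix(center, nrow = 1)
  C_peak <- .peak_search(volume, cand, r_pk)

  structure(list(nominal_diameter_mm = diameter_mm,
                 center_estimate = as.numeric(center),
                 C_mean = C_mean, C_max = C_max, C_peak = C_peak,
                 n_voxels = sum(inside), n_mean_samples = n_mean,
                 supersample = as.integer(supersample)),
            class = "sphere_measurement")
}

#' @export
print.sphere_measurement <- function(x, ...) {
  cat(sprintf("<sphere_measurement> d=%g mm: mean %.4g, max %.4g, peak %.4g Bq/mL (%d voxels)\n",
              x$nominal_diameter_mm, x$C_mean, x$C_max, x$C_peak, x$n_voxels))
  invisible(x)
}

# Highest mean over original voxel centers within radius r_pk of any
# candidate center. Candidates are grouped by their fractional offset from
# the voxel lattice so each group shares one integer-offset stencil.
.peak_search <- function(volume, cand, r_pk) {
  h <- volume$spacing
  d <- dim(volume$voxels)
  A <- volume$voxels
  # voxel index (real-valued) of each candidate
  gi <- sweep(sweep(cand, 2, volume$origin, "-"), 2, h, "/")
  base <- round(gi * 2) / 2            # snap to half-voxel lattice in index space
  frac <- base - floor(base)           # 0 or 0.5 per axis
  key <- frac[, 1] * 4 + frac[, 2] * 2 + frac[, 3]  # 8 classes (0,.5 -> 0,2,..)
  best <- -Inf
  for (k in unique(key)) {
    sel <- which(key == k)
    fr <- frac[sel[1], ]
    # integer stencil offsets o with |(o - fr) * h| <= r_pk
    rng <- lapply(1:3, function(ax) {
      lo <- floor(fr[ax] - r_pk / h[ax])
      hi <- ceiling(fr[ax] + r_pk / h[ax])
      lo:hi
    })
    off <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    dd <- sweep(off, 2, fr, "-")
    dd <- sweep(dd, 2, h, "*")
    keep <- rowSums(dd^2) <= r_pk^2
    off <- off[keep, , drop = FALSE]
    if (nrow(off) == 0) next
    b0 <- floor(base[sel, , drop = FALSE]) + 1  # 1-based base voxel
    sums <- numeric(length(sel))
    counts <- integer(length(sel))
    ok_all <- rep(TRUE, length(sel))
    for (j in seq_len(nrow(off))) {
      iix <- b0[, 1] + off[j, 1]
      iiy <- b0[, 2] + off[j, 2]
      iiz <- b0[, 3] + off[j, 3]
      ok <- iix >= 1 & iix <= d[1] & iiy >= 1 & iiy <= d[2] &
            iiz >= 1 & iiz <= d[3]
      ok_all <- ok_all & ok
      v <- numeric(length(sel))
      v[ok] <- A[cbind(iix[ok], iiy[ok], iiz[ok])]
      sums <- sums + v
      counts <- counts + as.integer(ok)
    }
    valid <- counts > 0
    if (any(valid)) best <- max(best, max(sums[valid] / counts[valid]))
  }
  best
}

#' Contrast recovery coefficient (CRC)
#'
#' `CRC = ((C_sphere - C_bkg) / C_bkg) / ((A_sphere - A_bkg) / A_bkg)`: the
#' measured contrast divided by the true (fill-derived) contrast. CRC is
#' invariant to scanner calibration bias, which scales `C_sphere` and
#' `C_bkg` jointly and cancels.
#'
#' @param C_sphere,C_bkg Measured sphere and background concentrations
#'   (any common unit; `C_bkg > 0`).
#' @param A_sphere,A_bkg True sphere and background concentrations from the
#'   fills (any common unit; `A_bkg > 0`, `A_sphere != A_bkg`).
#' @return Dimensionless CRC.
#' @export
crc <- function(C_sphere, C_bkg, A_sphere, A_bkg) {
  if (any(C_bkg <= 0)) stop("C_bkg must be > 0", call. = FALSE)
  if (any(A_bkg <= 0)) stop("A_bkg must be > 0", call. = FALSE)
  if (any(A_sphere == A_bkg)) {
    stop("A_sphere equals A_bkg: true contrast is undefined", call. = FALSE)
  }
  ((C_sphere - C_bkg) / C_bkg) / ((A_sphere - A_bkg) / A_bkg)
}

#' Recovery coefficient (RC)
#'
#' `RC = C_sphere / A_sphere`, computed without regard to contrast. Unlike
#' the CRC, the RC scales linearly with the scanner calibration bias.
#'
#' @param C_sphere Measured sphere concentration.
#' @param A_sphere True sphere concentration (> 0, same unit).
#' @return Dimensionless RC.
#' @export
rc <- function(C_sphere, A_sphere) {
  if (any(A_sphere <= 0)) stop("A_sphere must be > 0", call. = FALSE)
  C_sphere / A_sphere
}

#' Convert between RC and CRC
#'
#' `CRC = (RC * contrast / calibration_bias - 1) / (contrast - 1)` and its
#' algebraic inverse. The two metrics are uniquely computable from one
#' another given the contrast and the measured calibration bias.
#'
#' @param rc,crc Recovery metrics (dimensionless).
#' @param contrast True sphere-to-background contrast (> 1).
#' @param calibration_bias Measured calibration bias (> 0).
#' @return The converted metric.
#' @examples
#' rc_to_crc(0.9, 8, 1.05)   # about 0.8367
#' crc_to_rc(rc_to_crc(0.9, 8, 1.05), 8, 1.05)  # 0.9
#' @export
rc_to_crc <- function(rc, contrast, calibration_bias = 1) {
  if (any(contrast <= 1)) stop("contrast must exceed 1", call. = FALSE)
  if (any(calibration_bias <= 0)) stop("calibration_bias must be > 0",
                                       call. = FALSE)
  (rc * contrast / calibration_bias - 1) / (contrast - 1)
}

#' @rdname rc_to_crc
#' @export
crc_to_rc <- function(crc, contrast, calibration_bias = 1) {
  if (any(contrast <= 1)) stop("contrast must exceed 1", call. = FALSE)
  if (any(calibration_bias <= 0)) stop("calibration_bias must be > 0",
                                       call. = FALSE)
  (crc * (contrast - 1) + 1) * calibration_bias / contrast
}

#' Default background ROI set for torso recovery phantoms
#'
#' Twelve 30-mm circular ROIs in the uniform background at the sphere-plane
#' axial position, on a 95-mm ring at angles offset from the sphere ring so
#' every ROI keeps at least ~4 sigma clearance (FWHM 5 mm) from the nearest
#' sphere wall and from the phantom wall. This layout is a documented
#' package default, not a standard.
#'
#' @param spec A [phantom_spec()] with spheres.
#' @param n Number of ROIs (default 12).
#' @param ring_radius_mm Ring radius (default 95).
#' @param roi_diameter_mm ROI diameter (default 30).
#' @return Data frame with `x_mm`, `y_mm`, `z_mm`, `diameter_mm`.
#' @export
default_background_rois <- function(spec, n = 12, ring_radius_mm = 95,
                                    roi_diameter_mm = 30) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$spheres) >= 1)
  z <- mean(vapply(spec$spheres, function(s) s$center[3], 0))
  ang <- (pi / 12) + (seq_len(n) - 1) * 2 * pi / n   # 15, 45, ... degrees
  data.frame(x_mm = ring_radius_mm * cos(ang),
             y_mm = ring_radius_mm * sin(ang),
             z_mm = z, diameter_mm = roi_diameter_mm)
}

# Mean of one circular 2-D ROI on the slice nearest z_mm
.circle_roi_mean <- function(volume, x, y, z, diameter_mm) {
  cx <- .axis_coords(volume, 1)
  cy <- .axis_coords(volume, 2)
  cz <- .axis_coords(volume, 3)
  iz <- which.min(abs(cz - z))
  r2 <- (diameter_mm / 2)^2
  inside <- outer(cx - x, cy - y, function(a, b) a^2 + b^2) <= r2
  if (!any(inside)) stop("background ROI contains no voxel centers",
                         call. = FALSE)
  mean(volume$voxels[, , iz][inside])
}

#' Measure a recovery (CRC/RC) curve from a sphere-phantom acquisition
#'
#' Decay-corrects the background and sphere-stock fills to the acquisition
#' start, estimates the measured background concentration `C_bkg` from the
#' background ROI set, locates each sphere by iterated centroid, extracts
#' mean / maximum-voxel / peak statistics from exact-inner-diameter VOIs, and
#' assembles the curve with all six metric columns (CRC and RC for each
#' statistic). The fill-derived true contrast `A_sphere / A_bkg` (not the
#' nominal ratio) enters the CRC definition; the measured calibration bias
#' `C_bkg / A_bkg` is recorded alongside.
#'
#' Spheres that fail detection are reported in the `failures` attribute and
#' excluded from the rows; the remaining curve is still returned.
#'
#' @param volume An [image_volume()] of the recovery phantom.
#' @param bkg_fill Background [fill_record()].
#' @param sphere_fill Sphere-stock [fill_record()].
#' @param spec A [phantom_spec()] with spheres (nominal centers seed the
#'   centroid search).
#' @param bkg_rois Background ROI set (data frame as from
#'   [default_background_rois()]).
#' @param peak_volume_ml Peak VOI volume (default 1 mL).
#' @param supersample Mean-extraction refinement factor (default 1; reported
#'   in the result metadata).
#' @return Object of class `recovery_curve`: a data frame with one row per
#'   sphere (`diameter_mm`, centroid, `C_mean`, `C_max`, `C_peak`,
#'   `CRC_mean`, `CRC_max`, `CRC_peak`, `RC_mean`, `RC_max`, `RC_peak`) and
#'   attributes `contrast`, `calibration_bias`, `A_bkg_kbq_ml`,
#'   `A_sphere_kbq_ml`, `C_bkg_bq_ml`, `supersample`, `failures`.
#' @export
analyze_recovery <- function(volume, bkg_fill, sphere_fill, spec,
                             bkg_rois = default_background_rois(spec),
                             peak_volume_ml = 1, supersample = 1L) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(bkg_fill, "fill_record"),
            inherits(sphere_fill, "fill_record"),
            inherits(spec, "phantom_spec"))
  if (length(spec$spheres) == 0) stop("phantom has no spheres", call. = FALSE)
  if (volume$units != "Bq/mL") stop("volume units must be Bq/mL", call. = FALSE)
  t0 <- volume$acquisition_start
  A_bkg <- concentration_at(bkg_fill, t0)        # kBq/mL
  A_sph <- concentration_at(sphere_fill, t0)     # kBq/mL
  contrast <- achieved_contrast(A_sph, A_bkg)
  C_bkg <- mean(vapply(seq_len(nrow(bkg_rois)), function(i) {
    .circle_roi_mean(volume, bkg_rois$x_mm[i], bkg_rois$y_mm[i],
                     bkg_rois$z_mm[i], bkg_rois$diameter_mm[i])
  }, 0))                                          # Bq/mL
  meas_bias <- calibration_bias(C_bkg / 1000, A_bkg)

  rows <- list()
  failures <- character(0)
  for (s in spec$spheres) {
    res <- tryCatch({
      ctr <- locate_sphere_centroid(volume, s$center, s$inner_diameter_mm,
                                    background = C_bkg)
      st <- sphere_voi_stats(volume, ctr, s$inner_diameter_mm,
                             peak_volume_ml = peak_volume_ml,
                             supersample = supersample)
      data.frame(diameter_mm = s$inner_diameter_mm,
                 cx_mm = ctr[1], cy_mm = ctr[2], cz_mm = ctr[3],
                 C_mean = st$C_mean, C_max = st$C_max, C_peak = st$C_peak,
                 CRC_mean = crc(st$C_mean, C_bkg, A_sph, A_bkg),
                 CRC_max  = crc(st$C_max,  C_bkg, A_sph, A_bkg),
                 CRC_peak = crc(st$C_peak, C_bkg, A_sph, A_bkg),
                 RC_mean = rc(st$C_mean / 1000, A_sph),
                 RC_max  = rc(st$C_max  / 1000, A_sph),
                 RC_peak = rc(st$C_peak / 1000, A_sph))
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%g mm: %s", s$inner_diameter_mm,
                             conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(out$diameter_mm), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(diameter_mm = numeric(0), cx_mm = numeric(0),
                      cy_mm = numeric(0), cz_mm = numeric(0),
                      C_mean = numeric(0), C_max = numeric(0),
                      C_peak = numeric(0), CRC_mean = numeric(0),
                      CRC_max = numeric(0), CRC_peak = numeric(0),
                      RC_mean = numeric(0), RC_max = numeric(0),
                      RC_peak = numeric(0))
  }
  structure(out, class = c("recovery_curve", "data.frame"),
            contrast = contrast, calibration_bias = meas_bias,
            A_bkg_kbq_ml = A_bkg, A_sphere_kbq_ml = A_sph,
            C_bkg_bq_ml = C_bkg, supersample = as.integer(supersample),
            peak_volume_ml = peak_volume_ml, failures = failures,
            acquisition_start = t0, radionuclide = volume$radionuclide)
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> contrast %.3f, measured bias %.4f, C_bkg %.4g Bq/mL\n",
              attr(x, "contrast"), attr(x, "calibration_bias"),
              attr(x, "C_bkg_bq_ml")))
  print.data.frame(x, digits = 4)
  f <- attr(x, "failures")
  if (length(f)) cat("  detection failures:", paste(f, collapse = "; "), "\n")
  invisible(x)
}

#' Write a recovery curve as CSV
#'
#' One row per sphere, wide metric format; curve-level attributes are
#' prepended as comment lines.
#'
#' @param curve A `recovery_curve`.
#' @param path Output path.
#' @export
write_recovery_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contrast=%.10g calibration_bias=%.10g A_bkg_kbq_ml=%.10g A_sphere_kbq_ml=%.10g C_bkg_bq_ml=%.10g supersample=%d",
                     attr(curve, "contrast"), attr(curve, "calibration_bias"),
                     attr(curve, "A_bkg_kbq_ml"), attr(curve, "A_sphere_kbq_ml"),
                     attr(curve, "C_bkg_bq_ml"), attr(curve, "supersample")),
             con)
  write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}
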