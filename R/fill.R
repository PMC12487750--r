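# Phantom fill accounting: assays, fill records, ground-truth activity
# concentrations at scan time, and the fill QC limits used at planning time.

#' Create an activity assay record
#'
#' A single radionuclide-calibrator measurement (e.g. syringe before or after
#' injection into the phantom).
#'
#' @param activity_mbq Measured activity in MBq (non-negative).
#' @param assay_time Timestamp of the measurement.
#' @param device_id Identifier of the radionuclide calibrator.
#' @param clock_offset_min Known offset of the device clock relative to the
#'   scanner clock, in minutes (device time - scanner time). Clocks should be
#'   synchronized to better than one minute; see [fill_qc()].
#' @return Object of class `activity_assay`.
#' @export
activity_assay <- function(activity_mbq, assay_time, device_id = NA_character_,
                           clock_offset_min = 0) {
  if (!is.numeric(activity_mbq) || length(activity_mbq) != 1L ||
      !is.finite(activity_mbq) || activity_mbq < 0) {
    stop("activity_mbq must be a single non-negative number", call. = FALSE)
  }
  structure(list(activity_mbq = as.numeric(activity_mbq),
                 assay_time = .as_time(assay_time),
                 device_id = device_id,
                 clock_offset_min = as.numeric(clock_offset_min)),
            class = "activity_assay")
}

#' Create a phantom fill record
#'
#' Book-keeping for one fill compartment: the syringe is assayed before
#' (`pre_assay`) and after (`post_assay`) injection, so the net injected
#' activity is their decay-corrected difference. Together with the measured
#' aqueous compartment volume this yields the ground-truth activity
#' concentration at any reference time.
#'
#' @param nuclide [radionuclide()] or registry name.
#' @param pre_assay,post_assay [activity_assay()] records (post = residual).
#' @param fill_time Timestamp at which the phantom was filled.
#' @param compartment_volume_ml Measured aqueous volume in mL (> 0).
#' @param compartment_kind `"background"` or `"sphere_stock"`.
#' @return Object of class `fill_record`.
#' @export
fill_record <- function(nuclide, pre_assay, post_assay, fill_time,
                        compartment_volume_ml,
                        compartment_kind = c("background", "sphere_stock")) {
  nuclide <- .as_nuclide(nuclide)
  compartment_kind <- match.arg(compartment_kind)
  stopifnot(inherits(pre_assay, "activity_assay"),
            inherits(post_assay, "activity_assay"))
  if (!is.numeric(compartment_volume_ml) || compartment_volume_ml <= 0) {
    stop("compartment_volume_ml must be > 0", call. = FALSE)
  }
  rec <- structure(list(nuclide = nuclide, pre_assay = pre_assay,
                        post_assay = post_assay, fill_time = .as_time(fill_time),
                        compartment_volume_ml = as.numeric(compartment_volume_ml),
                        compartment_kind = compartment_kind),
                   class = "fill_record")
  # invariant: residual cannot exceed the pre-injection assay
  if (net_activity_at(rec, rec$fill_time) < 0) {
    stop("fill-record error: decay-corrected residual exceeds pre-injection assay",
         call. = FALSE)
  }
  rec
}

#' Net injected activity at a reference time
#'
#' Decay-corrects the pre- and post-injection assays independently to
#' `reference_time` and returns their difference. The result is invariant to
#' the choice of any intermediate common correction time.
#'
#' @param fill A [fill_record()].
#' @param reference_time Timestamp.
#' @return Net activity in MBq.
#' @export
net_activity_at <- function(fill, reference_time) {
  stopifnot(inherits(fill, "fill_record"))
  pre  <- decay_correct(fill$pre_assay$activity_mbq, fill$pre_assay$assay_time,
                        reference_time, fill$nuclide)
  post <- decay_correct(fill$post_assay$activity_mbq, fill$post_assay$assay_time,
                        reference_time, fill$nuclide)
  pre - post
}

#' Phantom volume from gross and empty weight
#'
#' Weight-and-density is the recommended volume measurement technique (never
#' trust the manufacturer's nominal volume). The default density is distilled
#' water at 20 degrees C.
#'
#' @param gross_mass_g,empty_mass_g Filled and empty phantom mass in grams.
#' @param water_density_g_ml Density in g/mL.
#' @return Volume in mL.
#' @examples
#' volume_from_weight(11197, 1999)  # about 9214.6 mL
#' @export
volume_from_weight <- function(gross_mass_g, empty_mass_g,
                               water_density_g_ml = 0.9982) {
  if (water_density_g_ml <= 0) stop("density must be > 0", call. = FALSE)
  net <- gross_mass_g - empty_mass_g
  if (net <= 0) stop("nonpositive net mass: gross must exceed empty weight",
                     call. = FALSE)
  net / water_density_g_ml
}

#' Ground-truth activity concentration of a fill at a reference time
#'
#' @inheritParams net_activity_at
#' @return Concentration in kBq/mL.
#' @export
concentration_at <- function(fill, reference_time) {
  net <- net_activity_at(fill, reference_time)
  if (net < 0) stop("fill-record error: negative net activity", call. = FALSE)
  1000 * net / fill$compartment_volume_ml  # MBq -> kBq
}

#' Achieved sphere-to-background contrast
#'
#' @param sphere_conc_kbq_ml,bkg_conc_kbq_ml Concentrations in kBq/mL.
#' @return Dimensionless contrast ratio.
#' @export
achieved_contrast <- function(sphere_conc_kbq_ml, bkg_conc_kbq_ml) {
  if (any(bkg_conc_kbq_ml <= 0)) stop("background concentration must be > 0",
                                      call. = FALSE)
  sphere_conc_kbq_ml / bkg_conc_kbq_ml
}

#' Plan a recovery-phantom fill
#'
#' Computes the sphere fill concentration for a target background
#' concentration at imaging time and a sphere-to-background contrast ratio.
#' The recommended contrast is 8:1, which for the recommended 2 kBq/mL
#' background gives 16 kBq/mL in the spheres at scan time; sphere
#' concentrations scale linearly with the background.
#'
#' @param bkg_conc_kbq_ml Background concentration at scan time (default 2).
#' @param contrast Sphere-to-background ratio (default 8).
#' @return List with `bkg_conc_kbq_ml`, `sphere_conc_kbq_ml`, `contrast`.
#' @examples
#' plan_rc_fill(2)$sphere_conc_kbq_ml  # 16
#' @export
plan_rc_fill <- function(bkg_conc_kbq_ml = 2, contrast = 8) {
  if (bkg_conc_kbq_ml <= 0) stop("background concentration must be > 0",
                                 call. = FALSE)
  if (contrast <= 1) stop("contrast must exceed 1", call. = FALSE)
  list(bkg_conc_kbq_ml = bkg_conc_kbq_ml,
       sphere_conc_kbq_ml = bkg_conc_kbq_ml * contrast,
       contrast = contrast)
}

#' Default fill QC limits
#'
#' Configuration defaults: calibration background 3--7 kBq/mL, recovery
#' background 2--6 kBq/mL (dead-time correction may be challenged above
#' 6 kBq/mL), at most ~40 MBq in the scanner field of view (pulse pile-up /
#' dead-time warning), contrast within `contrast_rel_tol` of the 8:1 target,
#' and device-to-scanner clock offsets below 1 minute.
#'
#' @return Named list of limits; pass a modified copy to [fill_qc()].
#' @export
fill_qc_limits <- function() {
  list(calibration_bkg_kbq_ml = c(3, 7),
       rc_bkg_kbq_ml = c(2, 6),
       fov_activity_warn_mbq = 40,
       target_contrast = 8,
       contrast_rel_tol = 0.1,
       clock_offset_warn_min = 1)
}

#' QC-check a fill plan
#'
#' Pure advisory check: returns a character vector of flags and never raises.
#' An empty vector means the plan is within all recommended limits.
#'
#' @param scan_kind `"calibration"` or `"rc"`.
#' @param bkg_conc_kbq_ml Planned background concentration at scan time.
#' @param contrast Planned sphere-to-background contrast (rc scans; optional).
#' @param total_fov_activity_mbq Total activity in the scanner FOV (optional).
#' @param clock_offsets_min Device clock offsets in minutes (optional).
#' @param limits Limits configuration, see [fill_qc_limits()].
#' @return Character vector of QC flags (possibly empty).
#' @examples
#' fill_qc("rc", bkg_conc_kbq_ml = 2, contrast = 8, total_fov_activity_mbq = 20)
#' fill_qc("rc", bkg_conc_kbq_ml = 6.5)
#' @export
fill_qc <- function(scan_kind = c("calibration", "rc"), bkg_conc_kbq_ml,
                    contrast = NULL, total_fov_activity_mbq = NULL,
                    clock_offsets_min = NULL, limits = fill_qc_limits()) {
  scan_kind <- match.arg(scan_kind)
  flags <- character(0)
  rng <- if (scan_kind == "calibration") limits$calibration_bkg_kbq_ml
         else limits$rc_bkg_kbq_ml
  if (bkg_conc_kbq_ml < rng[1]) {
    flags <- c(flags, sprintf(
      "background %.3g kBq/mL below recommended minimum %.3g kBq/mL",
      bkg_conc_kbq_ml, rng[1]))
  }
  if (bkg_conc_kbq_ml > rng[2]) {
    flags <- c(flags, sprintf(
      "background %.3g kBq/mL exceeds limit %.3g kBq/mL",
      bkg_conc_kbq_ml, rng[2]))
  }
  if (!is.null(contrast) &&
      abs(contrast - limits$target_contrast) >
        limits$contrast_rel_tol * limits$target_contrast) {
    flags <- c(flags, sprintf(
      "contrast %.3g deviates from %g:1 target beyond %.0f%% tolerance",
      contrast, limits$target_contrast, 100 * limits$contrast_rel_tol))
  }
  if (!is.null(total_fov_activity_mbq) &&
      total_fov_activity_mbq > limits$fov_activity_warn_mbq) {
    flags <- c(flags, sprintf(
      "dead-time warning: %.3g MBq in FOV exceeds ~%g MBq",
      total_fov_activity_mbq, limits$fov_activity_warn_mbq))
  }
  if (!is.null(clock_offsets_min) &&
      any(abs(clock_offsets_min) >= limits$clock_offset_warn_min)) {
    flags <- c(flags, sprintf(
      "clock offset >= %g min between assay device and scanner",
      limits$clock_offset_warn_min))
  }
  flags
}

# ---- serialization ---------------------------------------------------------

.assay_to_list <- function(a) {
  list(activity_mbq = a$activity_mbq,
       assay_time = format(a$assay_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
       device_id = a$device_id, clock_offset_min = a$clock_offset_min)
}

#' Write / read fill records as JSON
#'
#' Times are ISO-8601 (UTC), activities MBq, volumes mL.
#'
#' @param fills Named list of [fill_record()] objects.
#' @param path File path.
#' @return `read_fill_json` returns a named list of fill records.
#' @export
write_fill_json <- function(fills, path) {
  if (inherits(fills, "fill_record")) fills <- list(fill = fills)
  out <- lapply(fills, function(f) {
    list(radionuclide = f$nuclide$name,
         half_life_min = f$nuclide$half_life_min,
         pre_assay = .assay_to_list(f$pre_assay),
         post_assay = .assay_to_list(f$post_assay),
         fill_time = format(f$fill_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         compartment_volume_ml = f$compartment_volume_ml,
         compartment_kind = f$compartment_kind)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fill_json
#' @export
read_fill_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) {
    fill_record(
      nuclide = radionuclide(x$radionuclide, x$half_life_min),
      pre_assay = activity_assay(x$pre_assay$activity_mbq,
                                 x$pre_assay$assay_time,
                                 x$pre_assay$device_id %||% NA_character_,
                                 x$pre_assay$clock_offset_min %||% 0),
      post_assay = activity_assay(x$post_assay$activity_mbq,
                                  x$post_assay$assay_time,
                                  x$post_assay$device_id %||% NA_character_,
                                  x$post_assay$clock_offset_min %||% 0),
      fill_time = x$fill_time,
      compartment_volume_ml = x$compartment_volume_ml,
      compartment_kind = x$compartment_kind)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import an assay table from CSV
#'
#' Expected columns: `activity_mbq`, `assay_time`, optionally `device_id`,
#' `clock_offset_min`.
#'
#' @param path CSV file path.
#' @return List of [activity_assay()] records.
#' @export
read_assays_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("activity_mbq", "assay_time")
  if (!all(need %in% names(df))) {
    stop("assay CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    activity_assay(df$activity_mbq[i], df$assay_time[i],
                   if ("device_id" %in% names(df)) df$device_id[i] else NA,
                   if ("clock_offset_min" %in% names(df)) df$clock_offset_min[i] else 0)
  })
}
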