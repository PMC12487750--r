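# Acceptance-criteria engine. The criteria tables are data (JSON), shipped
# with the harmonized defaults: tier-1 calibration tolerance 5% for F-18 and
# Ga-68 and 10% for other radionuclides, tier-2 10% for all; per-sphere
# maximum-voxel CRC limits at 8:1 contrast; quarterly/annual validity
# windows; and the revalidation trigger events. All bounds are inclusive at
# the printed value (a configurable strict mode excludes the boundary).

#' Load validation criteria
#'
#' `default_criteria()` loads the criteria configuration shipped with the
#' package; `read_criteria_json()` loads a custom configuration with the same
#' schema: `{contrast, metric, inclusive, calibration: {tier1, tier2},
#' frequency, quarter_months, revalidation_triggers,
#' crc_limits: [{diameter_mm, min, max}, ...]}`.
#'
#' @param path JSON file path.
#' @return Object of class `validation_criteria`.
#' @export
default_criteria <- function() {
  read_criteria_json(system.file("extdata", "default_criteria.json",
                                 package = "petvalid", mustWork = TRUE))
}

#' @rdname default_criteria
#' @export
read_criteria_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  stopifnot(is.data.frame(x$crc_limits),
            all(c("diameter_mm", "min", "max") %in% names(x$crc_limits)))
  if (any(x$crc_limits$min >= x$crc_limits$max)) {
    stop("criteria error: every CRC limit must have min < max", call. = FALSE)
  }
  structure(x, class = "validation_criteria")
}

#' @export
print.validation_criteria <- function(x, ...) {
  cat(sprintf("<validation_criteria> CRC metric: %s voxel, contrast %g:1, bounds %s\n",
              x$metric, x$contrast,
              if (isTRUE(x$inclusive)) "inclusive" else "strict"))
  cat("  calibration tolerance, tier 1: ",
      paste(sprintf("%s %.0f%%", names(x$calibration$tier1),
                    100 * unlist(x$calibration$tier1)), collapse = ", "),
      "\n  calibration tolerance, tier 2: ",
      paste(sprintf("%s %.0f%%", names(x$calibration$tier2),
                    100 * unlist(x$calibration$tier2)), collapse = ", "),
      "\n", sep = "")
  print(x$crc_limits, row.names = FALSE)
  invisible(x)
}

#' Calibration tolerance for a radionuclide and tier
#'
#' @param nuclide [radionuclide()] or registry name.
#' @param tier 1 (quantitative end points) or 2 (visual-only end points).
#' @param criteria A `validation_criteria` object.
#' @return Fractional tolerance (e.g. 0.05).
#' @export
calibration_tolerance <- function(nuclide, tier = 1,
                                  criteria = default_criteria()) {
  nuc <- .as_nuclide(nuclide)
  tbl <- if (tier == 1) criteria$calibration$tier1 else criteria$calibration$tier2
  tol <- tbl[[nuc$name]] %||% tbl[["other"]]
  if (is.null(tol)) stop("no tolerance configured for ", nuc$name,
                         " at tier ", tier, call. = FALSE)
  tol
}

.new_decision <- function(subject, findings, valid_from, valid_until,
                          provenance = list()) {
  passed <- !any(findings$verdict == "fail")
  structure(list(subject = subject, passed = passed, findings = findings,
                 valid_from = valid_from, valid_until = valid_until,
                 provenance = provenance,
                 visual_review = list(required = TRUE, signed_off = FALSE,
                                      reviewer = NA_character_)),
            class = "validation_decision")
}

#' @export
print.validation_decision <- function(x, ...) {
  cat(sprintf("<validation_decision> %s: %s\n", x$subject,
              if (x$passed) "PASS" else "FAIL"))
  print(x$findings, row.names = FALSE)
  if (!is.null(x$valid_from)) {
    cat(sprintf("  valid %s to %s\n", format(x$valid_from),
                format(x$valid_until)))
  }
  cat("  visual review sign-off:",
      if (isTRUE(x$visual_review$signed_off)) x$visual_review$reviewer
      else "PENDING", "\n")
  invisible(x)
}

#' Evaluate a calibration result against the tiered tolerance
#'
#' Pass if and only if `|global_bias - 1| <= tolerance` (inclusive by
#' default). The validity window starts on the scan date: 3 calendar months
#' for quarterly nuclides (F-18, Ga-68) at either tier, one year otherwise.
#'
#' @param result A [analyze_calibration()] result.
#' @param nuclide [radionuclide()] or registry name (must be registered).
#' @param tier 1 or 2.
#' @param criteria A `validation_criteria` object.
#' @return A `validation_decision`.
#' @export
evaluate_calibration <- function(result, nuclide, tier = 1,
                                 criteria = default_criteria()) {
  stopifnot(inherits(result, "calibration_result"), tier %in% c(1, 2))
  nuc <- .as_nuclide(nuclide)
  tol <- calibration_tolerance(nuc, tier, criteria)
  # signif() guards the inclusive boundary against float noise (1.05 - 1
  # exceeds 0.05 by 4e-17 in binary floating point)
  dev <- signif(abs(result$global_bias - 1), 12)
  ok <- if (isTRUE(criteria$inclusive)) dev <= tol else dev < tol
  findings <- data.frame(
    item = "calibration_bias",
    value = result$global_bias,
    bound = sprintf("within +/-%g%% of 1", 100 * tol),
    verdict = if (ok) "pass" else "fail",
    stringsAsFactors = FALSE)
  scan_date <- as.Date(result$acquisition_start)
  win <- validity_window(scan_date, nuc, "calibration", criteria)
  .new_decision("calibration", findings, win$valid_from, win$valid_until,
                provenance = list(radionuclide = nuc$name, tier = tier,
                                  A_bkg_kbq_ml = result$A_bkg_kbq_ml,
                                  axial_uniformity = result$axial_uniformity))
}

#' Evaluate a recovery curve against the harmonized CRC limits
#'
#' Per-sphere verdict: `min <= CRC_max <= max` (inclusive by default) for
#' every diameter in the criteria table; the overall decision passes when no
#' judged sphere fails. Spheres present in the curve but absent from the
#' criteria (e.g. a 7-mm characterization sphere) are reported as
#' `informational` and never judged. A mandated diameter missing from the
#' curve is an error.
#'
#' @param curve A [analyze_recovery()] result (or any data frame with
#'   `diameter_mm` and `CRC_max`).
#' @param criteria A `validation_criteria` object.
#' @return A `validation_decision`.
#' @export
evaluate_crc <- function(curve, criteria = default_criteria()) {
  stopifnot(all(c("diameter_mm", "CRC_max") %in% names(curve)))
  lim <- criteria$crc_limits
  missing_d <- setdiff(lim$diameter_mm, curve$diameter_mm)
  if (length(missing_d)) {
    stop("curve is missing mandated sphere diameters: ",
         paste(missing_d, collapse = ", "), " mm", call. = FALSE)
  }
  inc <- isTRUE(criteria$inclusive)
  findings <- do.call(rbind, lapply(seq_len(nrow(curve)), function(i) {
    d <- curve$diameter_mm[i]
    v <- curve$CRC_max[i]
    j <- match(d, lim$diameter_mm)
    if (is.na(j)) {
      data.frame(item = sprintf("CRC_max_%gmm", d), value = v,
                 bound = "not judged", verdict = "informational",
                 stringsAsFactors = FALSE)
    } else {
      vs <- signif(v, 12)  # same boundary guard as the calibration tolerance
      ok <- if (inc) vs >= lim$min[j] & vs <= lim$max[j]
            else vs > lim$min[j] & vs < lim$max[j]
      data.frame(item = sprintf("CRC_max_%gmm", d), value = v,
                 bound = sprintf("[%g, %g]", lim$min[j], lim$max[j]),
                 verdict = if (ok) "pass" else "fail",
                 stringsAsFactors = FALSE)
    }
  }))
  t0 <- attr(curve, "acquisition_start")
  win <- if (!is.null(t0)) {
    validity_window(as.Date(t0), attr(curve, "radionuclide") %||% "F-18",
                    "recovery", criteria)
  } else list(valid_from = NULL, valid_until = NULL)
  .new_decision("recovery", findings, win$valid_from, win$valid_until,
                provenance = list(contrast = attr(curve, "contrast"),
                                  calibration_bias = attr(curve, "calibration_bias"),
                                  metric = criteria$metric))
}

#' Validity window of a validation scan
#'
#' Quarterly (+3 calendar months by default) for F-18 and Ga-68 calibration;
#' one year for other-nuclide calibration and for all recovery validations.
#' The window begins on the validation scan date.
#'
#' @param scan_date Date of the validation scan.
#' @param nuclide [radionuclide()] or registry name.
#' @param purpose `"calibration"` or `"recovery"`.
#' @param criteria A `validation_criteria` object (sets `quarter_months`).
#' @return List with `valid_from` and `valid_until` (Dates).
#' @export
validity_window <- function(scan_date, nuclide,
                            purpose = c("calibration", "recovery"),
                            criteria = default_criteria()) {
  purpose <- match.arg(purpose)
  nuc <- .as_nuclide(nuclide)
  scan_date <- as.Date(scan_date)
  freq <- if (purpose == "recovery") criteria$frequency$recovery
          else criteria$frequency$calibration[[nuc$name]] %||%
               criteria$frequency$calibration[["other"]]
  until <- if (identical(freq, "quarterly")) {
    seq(scan_date, by = paste(criteria$quarter_months %||% 3, "months"),
        length.out = 2)[2]
  } else {
    seq(scan_date, by = "1 year", length.out = 2)[2]
  }
  list(valid_from = scan_date, valid_until = until)
}

#' Truncate a decision's validity window by revalidation-trigger events
#'
#' Software updates, major service, replacement of a Ge-68 calibration
#' source, and radionuclide-calibrator repair/maintenance all trigger
#' revalidation: the earliest such event inside the window truncates
#' `valid_until` to the event date. Other event kinds, and events outside
#' the window, are ignored.
#'
#' @param decision A `validation_decision`.
#' @param events Data frame with columns `date` and `kind`.
#' @param triggers Character vector of triggering event kinds.
#' @return The (possibly truncated) `validation_decision`.
#' @export
apply_events <- function(decision, events,
                         triggers = default_criteria()$revalidation_triggers) {
  stopifnot(inherits(decision, "validation_decision"),
            all(c("date", "kind") %in% names(events)))
  if (is.null(decision$valid_from)) return(decision)
  dates <- as.Date(events$date)
  hit <- events$kind %in% triggers & dates > decision$valid_from &
         dates < decision$valid_until
  if (any(hit)) decision$valid_until <- min(dates[hit])
  decision
}

#' Serialize a validation decision to JSON
#'
#' Deterministic, bit-stable serialization of the findings, verdict,
#' validity window and provenance (timestamps are inputs, not generated).
#'
#' @param decision A `validation_decision`.
#' @param path Output path.
#' @export
write_decision_json <- function(decision, path) {
  out <- list(subject = decision$subject, passed = decision$passed,
              findings = decision$findings,
              valid_from = if (!is.null(decision$valid_from))
                format(decision$valid_from) else NULL,
              valid_until = if (!is.null(decision$valid_until))
                format(decision$valid_until) else NULL,
              provenance = decision$provenance,
              visual_review = decision$visual_review)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
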