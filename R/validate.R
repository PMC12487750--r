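# End-to-end validation runs: fill QC -> analysis -> criteria -> report.
# Exit statuses follow QC-tool convention: 0 pass, 1 fail, 2 error.

#' Run a complete scanner validation
#'
#' Orchestrates the full workflow for one acquisition: reads the volume,
#' fills, phantom and criteria; runs fill QC; performs the calibration or
#' recovery analysis; evaluates the acceptance criteria; and writes the
#' decision JSON, result tables (CSV) and a structured log (one line per
#' stage, with SHA-256 input digests) to the output directory.
#'
#' @param config Either a named list or a path to a JSON file with fields:
#'   `mode` (`"calibration"` or `"recovery"`), `volume` (NIfTI path),
#'   `sidecar` (optional), `fills` (fill JSON path), `phantom` (builtin name
#'   or phantom JSON path), `criteria` (optional criteria JSON path),
#'   `nuclide` (optional; defaults to the volume's), `tier` (1 or 2, for
#'   calibration), `out_dir`, and optional analysis options `margin_mm`,
#'   `end_exclusion_mm`, `supersample`, `peak_volume_ml`.
#' @return Invisibly, the exit status: 0 = all criteria pass, 1 = analysis
#'   succeeded but a criterion failed, 2 = error. The decision object is
#'   attached as attribute `decision` when one was produced.
#' @export
run_validation <- function(config) {
  status <- tryCatch({
    cfg <- if (is.character(config)) jsonlite::read_json(config,
                                                         simplifyVector = TRUE)
           else config
    for (field in c("mode", "volume", "fills", "phantom", "out_dir")) {
      if (is.null(cfg[[field]])) stop("config missing field '", field, "'",
                                      call. = FALSE)
    }
    for (f in c("volume", "fills")) {
      if (!file.exists(cfg[[f]])) {
        stop("input file does not exist: ", cfg[[f]], call. = FALSE)
      }
    }
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(cfg$out_dir, "validation_log.txt")
    log_line <- function(stage, msg) {
      cat(sprintf("%s\t%s\n", stage, msg), file = log_path, append = TRUE)
    }
    log_line("start", sprintf("petvalid %s mode=%s",
                              as.character(utils::packageVersion("petvalid")),
                              cfg$mode))
    for (f in c("volume", "fills")) {
      log_line("input", sprintf("%s=%s sha256=%s", f, cfg[[f]],
                                .file_digest(cfg[[f]])))
    }

    volume <- read_volume(cfg$volume, cfg$sidecar %||% NULL)
    fills <- read_fill_json(cfg$fills)
    spec <- if (file.exists(cfg$phantom)) read_phantom_json(cfg$phantom)
            else builtin_phantom(cfg$phantom)
    criteria <- if (!is.null(cfg$criteria)) read_criteria_json(cfg$criteria)
                else default_criteria()
    nuclide <- cfg$nuclide %||% volume$radionuclide
    t0 <- volume$acquisition_start

    bkg_fill <- fills$background %||% fills[[1]]
    if (cfg$mode == "calibration") {
      qc <- fill_qc("calibration",
                    bkg_conc_kbq_ml = concentration_at(bkg_fill, t0),
                    total_fov_activity_mbq = net_activity_at(bkg_fill, t0))
      for (fl in qc) log_line("fill_qc", fl)
      result <- analyze_calibration(volume, bkg_fill, spec,
                                    margin_mm = cfg$margin_mm %||% 20,
                                    end_exclusion_mm = cfg$end_exclusion_mm %||% 10)
      write.csv(result$per_slice,
                file.path(cfg$out_dir, "slice_bias.csv"), row.names = FALSE)
      decision <- evaluate_calibration(result, nuclide,
                                       tier = cfg$tier %||% 1, criteria)
      log_line("analysis", sprintf("global_bias=%.6f axial_uniformity=%.6f",
                                   result$global_bias,
                                   result$axial_uniformity))
    } else if (cfg$mode == "recovery") {
      sph_fill <- fills$sphere_stock %||% fills[[2]]
      A_bkg <- concentration_at(bkg_fill, t0)
      qc <- fill_qc("rc", bkg_conc_kbq_ml = A_bkg,
                    contrast = achieved_contrast(
                      concentration_at(sph_fill, t0), A_bkg),
                    total_fov_activity_mbq = net_activity_at(bkg_fill, t0))
      for (fl in qc) log_line("fill_qc", fl)
      qc2 <- check_rc_phantom_compliance(spec)
      for (fl in qc2) log_line("phantom_compliance", fl)
      curve <- analyze_recovery(volume, bkg_fill, sph_fill, spec,
                                peak_volume_ml = cfg$peak_volume_ml %||% 1,
                                supersample = cfg$supersample %||% 1L)
      write_recovery_csv(curve, file.path(cfg$out_dir, "recovery_curve.csv"))
      decision <- evaluate_crc(curve, criteria)
      log_line("analysis", sprintf("contrast=%.4f measured_bias=%.6f",
                                   attr(curve, "contrast"),
                                   attr(curve, "calibration_bias")))
    } else {
      stop("unknown mode '", cfg$mode, "'", call. = FALSE)
    }
    write_decision_json(decision, file.path(cfg$out_dir, "decision.json"))
    log_line("decision", if (decision$passed) "PASS" else "FAIL")
    out <- if (decision$passed) 0L else 1L
    attr(out, "decision") <- decision
    out
  }, error = function(e) {
    message("validation error: ", conditionMessage(e))
    structure(2L, error = conditionMessage(e))
  })
  invisible(status)
}
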