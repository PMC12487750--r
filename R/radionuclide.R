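# Radionuclide registry and exponential decay correction. Half-lives are in
# minutes; every assay and concentration in the package is decay-corrected
# through these entries, so registry accuracy anchors all ground truth.

.nuclide_table <- data.frame(
  name          = c("F-18",  "Ga-68", "Cu-64",    "Zr-89",      "I-124"),
  half_life_min = c(109.77,  67.71,   12.7 * 60,  3.25 * 1440,  4.2 * 1440),
  stringsAsFactors = FALSE
)

# Accept common alias spellings (F18, 18F, f-18, ...).
.normalize_nuclide_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- toupper(gsub("[^A-Za-z0-9]", "", name))
  # move leading mass number to the back: 18F -> F18
  if (grepl("^[0-9]+[A-Z]+$", key)) {
    key <- paste0(gsub("^[0-9]+", "", key), gsub("[A-Z]+$", "", key))
  }
  hits <- toupper(gsub("-", "", .nuclide_table$name)) == key
  if (!any(hits)) {
    stop("Unknown radionuclide '", name, "'. Registry: ",
         paste(.nuclide_table$name, collapse = ", "), call. = FALSE)
  }
  .nuclide_table$name[hits]
}

#' Look up a radionuclide in the registry
#'
#' The registry holds the positron emitters in routine clinical-trial use:
#' F-18, Ga-68, Cu-64 (t1/2 = 12.7 h), Zr-89 (t1/2 = 3.25 d) and
#' I-124 (t1/2 = 4.2 d).
#'
#' @param name Radionuclide name, e.g. `"F-18"`, `"F18"` or `"18F"`.
#' @param half_life_min Optional custom half-life in minutes; when supplied a
#'   new entry (not necessarily in the registry) is returned.
#' @return An object of class `radionuclide`: a list with `name` and
#'   `half_life_min`.
#' @examples
#' radionuclide("Cu-64")$half_life_min / 60  # 12.7 h
#' @export
radionuclide <- function(name, half_life_min = NULL) {
  if (is.null(half_life_min)) {
    name <- .normalize_nuclide_name(name)
    half_life_min <- .nuclide_table$half_life_min[.nuclide_table$name == name]
  }
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      !is.finite(half_life_min) || half_life_min <= 0) {
    stop("half_life_min must be a positive number", call. = FALSE)
  }
  structure(list(name = name, half_life_min = as.numeric(half_life_min)),
            class = "radionuclide")
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s, half-life %.4g min\n", x$name, x$half_life_min))
  invisible(x)
}

#' Radionuclide registry
#'
#' @return Data frame of registered radionuclides with half-lives in minutes.
#' @export
radionuclide_registry <- function() .nuclide_table

.as_nuclide <- function(x) {
  if (inherits(x, "radionuclide")) x else radionuclide(x)
}

.as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (is.character(x)) {
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d"))
    if (!is.na(out)) return(out)
  }
  stop("Cannot interpret '", format(x), "' as a timestamp; use POSIXct or ISO-8601",
       call. = FALSE)
}

#' Decay-correct an activity between two times
#'
#' Exact exponential correction `A * 2^(-dt / half_life)`. Correcting
#' backwards in time (`to_time` before `from_time`) is permitted and inverts
#' the decay.
#'
#' @param activity_mbq Activity in MBq.
#' @param from_time,to_time Timestamps (POSIXct or ISO-8601 strings).
#' @param nuclide A [radionuclide()] or registry name.
#' @return Activity in MBq at `to_time`.
#' @examples
#' t0 <- as.POSIXct("2026-01-01 08:00", tz = "UTC")
#' decay_correct(100, t0, t0 + 12.7 * 3600, "Cu-64")  # 50
#' @export
decay_correct <- function(activity_mbq, from_time, to_time, nuclide) {
  nuc <- .as_nuclide(nuclide)
  if (nuc$half_life_min <= 0) stop("nonpositive half-life", call. = FALSE)
  dt_min <- as.numeric(difftime(.as_time(to_time), .as_time(from_time),
                                units = "mins"))
  activity_mbq * 2^(-dt_min / nuc$half_life_min)
}
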