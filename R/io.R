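# Volume I/O. NIfTI plus a JSON sidecar is the canonical interchange: the
# sidecar carries the acquisition metadata NIfTI cannot (units, radionuclide,
# acquisition start) and keeps fixtures bit-reproducible. Metadata is never
# guessed: a sidecar missing units, radionuclide or acquisition start is a
# hard error.

#' Write an image volume as NIfTI + JSON sidecar
#'
#' @param volume An [image_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param sidecar_path Sidecar path (default: `path` with `.json` extension).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, sidecar_path = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  if (is.null(sidecar_path)) sidecar_path <- .sidecar_for(path)
  nii <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(nii) <- volume$spacing
  RNifti::writeNifti(nii, path)
  side <- list(units = volume$units,
               radionuclide = volume$radionuclide,
               acquisition_start = format(volume$acquisition_start,
                                          "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               spacing_mm = volume$spacing,
               origin_mm = volume$origin)
  side <- c(side, volume$meta)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.sidecar_for <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read an image volume from NIfTI + JSON sidecar
#'
#' @param path `.nii` / `.nii.gz` path.
#' @param sidecar_path Sidecar path (default: derived from `path`).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- .sidecar_for(path)
  if (!file.exists(path)) stop("volume file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar_path)) {
    stop("sidecar not found: ", sidecar_path,
         " (units and acquisition metadata are required, never guessed)",
         call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("units", "radionuclide", "acquisition_start")) {
    if (is.null(side[[field]])) {
      stop("sidecar missing required field '", field, "'", call. = FALSE)
    }
  }
  if (!identical(side$units, "Bq/mL")) {
    stop("unsupported units '", side$units, "': volumes must be Bq/mL",
         call. = FALSE)
  }
  nii <- RNifti::readNifti(path)
  vox <- array(as.numeric(nii), dim = dim(nii))
  spacing <- RNifti::pixdim(nii)[1:3]
  if (!is.null(side$spacing_mm) &&
      any(abs(spacing - side$spacing_mm) > 1e-4)) {
    stop("spacing mismatch between NIfTI header and sidecar", call. = FALSE)
  }
  origin <- side$origin_mm %||% c(0, 0, 0)
  meta <- side[setdiff(names(side), c("units", "radionuclide",
                                      "acquisition_start", "spacing_mm",
                                      "origin_mm"))]
  image_volume(vox, spacing, origin, side$acquisition_start,
               side$radionuclide, meta = meta)
}

# SHA-256 digest for provenance logging; openssl ships with the usual
# toolchain but is optional here.
.file_digest <- function(path) {
  if (!file.exists(path)) return("missing")
  if (requireNamespace("openssl", quietly = TRUE)) {
    con <- file(path, "rb")
    on.exit(close(con))
    as.character(openssl::sha256(con))
  } else {
    "sha256-unavailable"
  }
}
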