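# Phantom geometry. World coordinates are right-handed millimetres with the
# origin at the phantom body centroid; the scanner axis is z. Sphere centers
# are stored explicitly so non-standard ring layouts are representable.

#' Create a fillable sphere insert
#'
#' @param inner_diameter_mm Inner diameter in mm (> 0).
#' @param center 3-vector, world coordinates in mm.
#' @param wall_thickness_mm Wall thickness in mm (>= 0, ideally <= 1).
#' @return Object of class `sphere_insert`.
#' @export
sphere_insert <- function(inner_diameter_mm, center = c(0, 0, 0),
                          wall_thickness_mm = 1) {
  stopifnot(inner_diameter_mm > 0, wall_thickness_mm >= 0, length(center) == 3L)
  structure(list(inner_diameter_mm = inner_diameter_mm,
                 center = as.numeric(center),
                 wall_thickness_mm = wall_thickness_mm),
            class = "sphere_insert")
}

#' Create a phantom specification
#'
#' Two body kinds are supported: `uniform_cylinder` (calibration phantoms;
#' circular cross-section of `cylinder_diameter_mm`) and `torso_iq`
#' (recovery phantoms; elliptical torso cross-section with semi-axes
#' `body_semiaxes_mm`, fillable spheres and optional low-density inserts).
#' `body_shape` is a declared attribute, not inferred from geometry.
#'
#' @param kind `"uniform_cylinder"` or `"torso_iq"`.
#' @param axial_length_mm Interior axial length in mm.
#' @param body_shape `"cylindrical"` or `"noncylindrical"`.
#' @param spheres List of [sphere_insert()] (empty for uniform phantoms).
#' @param cold_inserts List of cold (zero-activity) inserts; each a list with
#'   `shape = "cylinder"`, `diameter_mm`, `center` (mm) and `density_class`.
#' @param cylinder_diameter_mm Body diameter (uniform kind only).
#' @param body_semiaxes_mm Ellipse semi-axes `c(a, b)` in mm (torso kind only).
#' @param body_volume_l Interior fillable volume in L; computed from the
#'   geometry (minus cold inserts and sphere interiors for the background
#'   compartment is NOT subtracted here: this is the total body volume) when
#'   omitted.
#' @param name Optional phantom name.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("uniform_cylinder", "torso_iq"),
                         axial_length_mm, body_shape = NULL, spheres = list(),
                         cold_inserts = list(), cylinder_diameter_mm = NULL,
                         body_semiaxes_mm = NULL, body_volume_l = NULL,
                         name = NULL) {
  kind <- match.arg(kind)
  stopifnot(axial_length_mm > 0)
  if (kind == "uniform_cylinder") {
    if (is.null(cylinder_diameter_mm) || cylinder_diameter_mm <= 0) {
      stop("uniform_cylinder requires cylinder_diameter_mm > 0", call. = FALSE)
    }
    if (length(spheres) > 0) stop("uniform_cylinder must not carry spheres",
                                  call. = FALSE)
    if (is.null(body_shape)) body_shape <- "cylindrical"
    area <- pi * (cylinder_diameter_mm / 2)^2
  } else {
    if (is.null(body_semiaxes_mm) || length(body_semiaxes_mm) != 2L ||
        any(body_semiaxes_mm <= 0)) {
      stop("torso_iq requires body_semiaxes_mm = c(a, b) > 0", call. = FALSE)
    }
    if (length(spheres) < 1) stop("torso_iq requires at least one sphere",
                                  call. = FALSE)
    if (is.null(body_shape)) body_shape <- "noncylindrical"
    area <- pi * body_semiaxes_mm[1] * body_semiaxes_mm[2]
  }
  if (is.null(body_volume_l)) body_volume_l <- area * axial_length_mm / 1e6
  stopifnot(body_volume_l > 0)
  structure(list(kind = kind, name = name %||% kind,
                 body_volume_l = body_volume_l,
                 axial_length_mm = axial_length_mm, body_shape = body_shape,
                 spheres = spheres, cold_inserts = cold_inserts,
                 cylinder_diameter_mm = cylinder_diameter_mm,
                 body_semiaxes_mm = body_semiaxes_mm),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s (%s, %s), %.2f L, length %g mm\n",
              x$name, x$kind, x$body_shape, x$body_volume_l, x$axial_length_mm))
  if (length(x$spheres)) {
    cat("  spheres (mm): ",
        paste(vapply(x$spheres, function(s) s$inner_diameter_mm, 0),
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$cold_inserts)) {
    cat("  cold inserts:", length(x$cold_inserts), "\n")
  }
  invisible(x)
}

# NEMA-style ring layout: spheres coplanar (z = 0), centers on a ring of
# radius 57.2 mm, largest sphere at angle 0, decreasing counter-clockwise.
.ring_spheres <- function(diameters, ring_radius = 57.2, wall = 1) {
  ang <- (seq_along(diameters) - 1) * 2 * pi / length(diameters)
  mapply(function(d, a) {
    sphere_insert(d, c(ring_radius * cos(a), ring_radius * sin(a), 0), wall)
  }, sort(diameters, decreasing = TRUE), ang, SIMPLIFY = FALSE)
}

#' Built-in phantom geometries
#'
#' * `uniform20`: 20-cm diameter uniform cylinder, 20-cm interior length
#'   (about 6.3 L), the classic calibration phantom.
#' * `iq_nema`: torso-shaped image-quality phantom (about 9.8 L, 180-mm
#'   interior length) with the six standard spheres (10, 13, 17, 22, 28,
#'   37 mm inner diameter) on a 57.2-mm ring and a central 50-mm low-density
#'   cylinder insert.
#' * `ctn_like`: parameterized anthropomorphic-chest stand-in (not a replica
#'   of any commercial phantom): the six standard spheres plus a 7-mm sphere,
#'   and two low-density lung-like cylinder inserts.
#'
#' @param name One of `"uniform20"`, `"iq_nema"`, `"ctn_like"`.
#' @return A [phantom_spec()].
#' @export
builtin_phantom <- function(name = c("uniform20", "iq_nema", "ctn_like")) {
  name <- match.arg(name)
  switch(name,
    uniform20 = phantom_spec("uniform_cylinder", axial_length_mm = 200,
                             cylinder_diameter_mm = 200, name = "uniform20"),
    iq_nema = phantom_spec(
      "torso_iq", axial_length_mm = 180, body_semiaxes_mm = c(150, 115),
      spheres = .ring_spheres(c(10, 13, 17, 22, 28, 37)),
      cold_inserts = list(list(shape = "cylinder", diameter_mm = 50,
                               center = c(0, 0, 0), density_class = "low")),
      name = "iq_nema"),
    ctn_like = {
      sph <- .ring_spheres(c(10, 13, 17, 22, 28, 37))
      sph <- c(sph, list(sphere_insert(7, c(57.2 * cos(pi / 6),
                                            57.2 * sin(pi / 6), 0), 1)))
      phantom_spec(
        "torso_iq", axial_length_mm = 200, body_semiaxes_mm = c(170, 120),
        spheres = sph,
        cold_inserts = list(
          list(shape = "cylinder", diameter_mm = 50, center = c(60, -30, 0),
               density_class = "low"),
          list(shape = "cylinder", diameter_mm = 50, center = c(-60, -30, 0),
               density_class = "low")),
        name = "ctn_like")
    })
}

#' Check a phantom against the recovery-phantom requirements
#'
#' Requirements: body volume strictly greater than 9 L; axial length of at
#' least 18 cm; noncylindrical (ideally torso-shaped) body; at least five
#' fillable spheres spanning 10--28 mm inner diameter; wall thicknesses of
#' approximately 1 mm or less; at least one low-density insert.
#'
#' @param spec A [phantom_spec()].
#' @param wall_tol_mm Maximum acceptable sphere wall thickness (default 1).
#' @return Character vector of violations (empty when compliant).
#' @export
check_rc_phantom_compliance <- function(spec, wall_tol_mm = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- character(0)
  if (!(spec$body_volume_l > 9)) {
    v <- c(v, sprintf("body volume %.2f L not in excess of 9 L",
                      spec$body_volume_l))
  }
  if (spec$axial_length_mm < 180) {
    v <- c(v, sprintf("axial length %g mm below the 180 mm (18 cm) minimum",
                      spec$axial_length_mm))
  }
  if (spec$body_shape == "cylindrical") {
    v <- c(v, "body is cylindrical; a noncylindrical torso-like shape is required")
  }
  d <- vapply(spec$spheres, function(s) s$inner_diameter_mm, 0)
  n_core <- sum(d >= 10 & d <= 28)
  if (n_core < 5) {
    v <- c(v, sprintf("only %d fillable spheres within 10-28 mm (at least 5 required)",
                      n_core))
  }
  w <- vapply(spec$spheres, function(s) s$wall_thickness_mm, 0)
  if (length(w) && any(w > wall_tol_mm)) {
    v <- c(v, sprintf("sphere wall thickness up to %.2g mm exceeds ~%g mm",
                      max(w), wall_tol_mm))
  }
  if (length(spec$cold_inserts) == 0) {
    v <- c(v, "no low-density insert to challenge attenuation/scatter correction")
  }
  v
}

#' Check a phantom against the calibration-phantom requirements
#'
#' Uniform cylinders must be at least 150 mm in diameter (inclusive) and at
#' least 200 mm long (inclusive). Non-uniform phantoms are accepted for
#' calibration when they expose sufficient uniform regions; a `note:` flag
#' (not a violation) records that assumption.
#'
#' @param spec A [phantom_spec()].
#' @return Character vector of violations/notes (empty when compliant).
#' @export
check_calibration_phantom_compliance <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  v <- character(0)
  if (spec$kind == "uniform_cylinder") {
    if (spec$cylinder_diameter_mm < 150) {
      v <- c(v, sprintf("diameter %g mm below 150 mm minimum",
                        spec$cylinder_diameter_mm))
    }
    if (spec$axial_length_mm < 200) {
      v <- c(v, sprintf("length %g mm below 200 mm minimum",
                        spec$axial_length_mm))
    }
  } else {
    v <- c(v, "note: non-uniform phantom accepted assuming sufficient uniform regions")
  }
  v
}

#' Write / read a phantom specification as JSON
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `read_phantom_json` returns a [phantom_spec()].
#' @export
write_phantom_json <- function(spec, path) {
  out <- unclass(spec)
  out$spheres <- lapply(spec$spheres, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  phantom_spec(kind = x$kind, axial_length_mm = x$axial_length_mm,
               body_shape = x$body_shape,
               spheres = lapply(x$spheres, function(s) {
                 sphere_insert(s$inner_diameter_mm, unlist(s$center),
                               s$wall_thickness_mm)
               }),
               cold_inserts = x$cold_inserts %||% list(),
               cylinder_diameter_mm = x$cylinder_diameter_mm,
               body_semiaxes_mm = x$body_semiaxes_mm,
               body_volume_l = x$body_volume_l, name = x$name)
}
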