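# The mesh measurement chain: IPD metric scaling, apex-to-foot-plane
# height, and volumetric weight at a fixed average body density.
#
# The chain assumes a neutral, upright-pose mesh; it performs no reposing.

lm_point <- function(mesh, role) {
  idx <- mesh$landmarks[role]
  if (is.na(idx))
    stop_anthropix(sprintf("missing landmark role: %s", role),
                   "anthropix_landmark_error")
  mesh$vertices[idx, ]
}

#' Pupil centers of a body mesh
#'
#' Body meshes have no pupils; each pupil center is defined as the midway
#' point between the inner and outer corners of that eye.
#'
#' @param mesh An [anthro_mesh()] with eye-corner landmarks.
#' @return A list with 3-vectors `left` and `right`.
#' @export
pupil_centers <- function(mesh) {
  list(left = (lm_point(mesh, "left_eye_inner") +
                 lm_point(mesh, "left_eye_outer")) / 2,
       right = (lm_point(mesh, "right_eye_inner") +
                  lm_point(mesh, "right_eye_outer")) / 2)
}

#' Inter-pupillary distance of a mesh
#'
#' Euclidean distance between the two pupil centers, in the mesh's current
#' linear units. This is the quantity the metric scaling normalises to a
#' gender-specific population average.
#'
#' @param mesh An [anthro_mesh()].
#' @return A positive length in mesh units.
#' @export
measure_ipd <- function(mesh) {
  p <- pupil_centers(mesh)
  d <- sqrt(sum((p$left - p$right)^2))
  if (d <= 0)
    stop_anthropix("degenerate geometry: zero inter-pupillary distance",
                   "anthropix_degenerate_error")
  d
}

#' Scale a raw mesh to centimetres via the population-average IPD
#'
#' Multiplies every vertex by `s = ipd_mean(gender) / measure_ipd(mesh)`,
#' the unique uniform scale that makes the mesh's IPD equal the
#' gender-specific average adult IPD. After scaling, units are centimetres.
#' Because `s` absorbs any uniform pre-scaling of the input, the whole
#' measurement chain is invariant to the arbitrary units the mesh arrives
#' in.
#'
#' @param mesh An [anthro_mesh()] in raw units.
#' @param gender `"female"` or `"male"`.
#' @param constants An [anthropometry_constants()] object.
#' @return The scaled mesh, with units `"cm"` and the applied scale factor
#'   in attribute `"scale_factor"`.
#' @export
scale_to_ipd <- function(mesh, gender, constants = anthropometry_constants()) {
  check_gender(gender)
  if (mesh$units != "raw")
    stop_anthropix("scale_to_ipd() expects a mesh in raw units",
                   "anthropix_config_error")
  s <- ipd_mean(gender, constants) / measure_ipd(mesh)
  out <- mesh
  out$vertices <- mesh$vertices * s
  out$units <- "cm"
  out$scale <- NA_real_
  attr(out, "scale_factor") <- s
  out
}

#' Foot plane of a body mesh
#'
#' The plane through the three sole landmarks, with the unit normal
#' oriented toward the head apex (so apex distances are positive).
#'
#' @param mesh An [anthro_mesh()].
#' @return A list with `point` (on the plane) and unit `normal`.
#' @export
foot_plane <- function(mesh) {
  a <- lm_point(mesh, "foot_a")
  b <- lm_point(mesh, "foot_b")
  c3 <- lm_point(mesh, "foot_c")
  n <- cross3(b - a, c3 - a)
  nn <- sqrt(sum(n^2))
  extent <- max(sqrt(sum((b - a)^2)), sqrt(sum((c3 - a)^2)), 1e-300)
  if (nn <= 1e-9 * extent^2)
    stop_anthropix("degenerate geometry: collinear foot landmarks",
                   "anthropix_degenerate_error")
  n <- n / nn
  if (sum((lm_point(mesh, "head_apex") - a) * n) < 0) n <- -n
  list(point = a, normal = n)
}

#' Stature of a body mesh
#'
#' Height is the perpendicular distance from the head apex to the foot
#' plane — the rotation-invariant reading of "distance from the top of the
#' head to a plane through the soles". The apex is the supplied
#' `head_apex` landmark; with `fallback_apex = TRUE` the maximum
#' perpendicular distance over all vertices is used instead (a convenience
#' for meshes without an apex annotation; it is pose-dependent).
#'
#' @param mesh An [anthro_mesh()] in centimetres.
#' @param fallback_apex Use the farthest vertex instead of the `head_apex`
#'   landmark.
#' @return Height in cm (non-negative).
#' @export
estimate_height <- function(mesh, fallback_apex = FALSE) {
  if (mesh$units != "cm")
    stop_anthropix("estimate_height() expects a mesh in cm; scale it first",
                   "anthropix_config_error")
  pl <- foot_plane(mesh)
  if (fallback_apex) {
    max(sweep(mesh$vertices, 2L, pl$point) %*% pl$normal)
  } else {
    sum((lm_point(mesh, "head_apex") - pl$point) * pl$normal)
  }
}

#' Volumetric weight of a body mesh
#'
#' Weight is the enclosed mesh volume converted to mass at the average body
#' density (default 1023 kg/m^3): `kg = volume_cm3 * 1e-6 * density`.
#'
#' @param mesh An [anthro_mesh()] in centimetres.
#' @param constants An [anthropometry_constants()] object.
#' @return Weight in kg.
#' @export
estimate_weight <- function(mesh, constants = anthropometry_constants()) {
  if (mesh$units != "cm")
    stop_anthropix("estimate_weight() expects a mesh in cm; scale it first",
                   "anthropix_config_error")
  vol <- mesh_volume(mesh)
  if (vol <= 0)
    stop_anthropix("non-positive enclosed volume: inconsistent orientation",
                   "anthropix_orientation_error")
  vol * 1e-6 * constants$body_density
}

#' Full mesh anthropometry chain
#'
#' Scales a raw mesh to centimetres via the gendered population-average
#' IPD, then measures stature (apex to foot plane) and volumetric weight.
#'
#' @param mesh An [anthro_mesh()] in raw units.
#' @param gender `"female"` or `"male"`.
#' @param constants An [anthropometry_constants()] object.
#' @return A `body_measurement` list: `height_cm`, `weight_kg`, `ipd_raw`
#'   (mesh units), `scale_factor` (cm per mesh unit), `volume_m3`.
#' @examples
#' m <- generate_body_mesh(161.1, 60.9, "female")
#' measure(m, "female")
#' @export
measure <- function(mesh, gender, constants = anthropometry_constants()) {
  ipd_raw <- measure_ipd(mesh)
  scaled <- scale_to_ipd(mesh, gender, constants)
  w <- estimate_weight(scaled, constants)
  structure(list(height_cm = estimate_height(scaled),
                 weight_kg = w,
                 ipd_raw = ipd_raw,
                 scale_factor = attr(scaled, "scale_factor"),
                 volume_m3 = w / constants$body_density),
            class = "body_measurement")
}

#' @export
print.body_measurement <- function(x, ...) {
  cat(sprintf(
    "<body_measurement: height %.2f cm, weight %.2f kg (volume %.4f m^3, scale %.4g cm/unit)>\n",
    x$height_cm, x$weight_kg, x$volume_m3, x$scale_factor))
  invisible(x)
}
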