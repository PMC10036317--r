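# Parametric synthetic body meshes.
#
# The body is a single closed surface of revolution about the vertical axis
# with an anthropomorphic radius profile (feet, legs, hips, waist, chest,
# neck, head), capped by a flat sole disk at z = 0 and a head apex point at
# z = height. Using one closed lathe instead of unioned limb primitives
# keeps the surface watertight by construction while preserving everything
# the measurement chain touches: the apex, the sole plane, the eye
# landmarks, and the exact enclosed volume.
#
# Height is exact by construction (apex at z = height, soles on z = 0).
# Volume is made exact by solving for a radial scale factor k: scaling
# (x, y) by k is an affine map with determinant k^2, so the discrete
# signed-tetrahedron volume scales by exactly k^2 and
# k = sqrt(V_target / V_template) hits the target to machine precision.

# radius profile as fraction of height: (z / H, r / H) control polygon
BODY_PROFILE <- cbind(
  z = c(0.000, 0.030, 0.060, 0.250, 0.450, 0.520, 0.620, 0.720,
        0.790, 0.830, 0.870, 0.930, 0.975, 1.000),
  r = c(0.060, 0.062, 0.060, 0.070, 0.085, 0.095, 0.085, 0.095,
        0.070, 0.035, 0.055, 0.060, 0.040, 0.000))

EYE_WIDTH_CM <- 2.8       # palpebral fissure width: inner-to-outer corner
EYE_HEIGHT_FRAC <- 0.93   # eye line as a fraction of stature
RADIAL_SCALE_RANGE <- c(0.15, 3)  # plausibility bounds on the radial solve

#' Generate a synthetic landmark-annotated body mesh
#'
#' Builds a watertight humanoid surface of revolution whose measurable
#' anthropometry is exact: the head-apex to sole-plane distance equals
#' `height_cm`, the enclosed volume equals `weight_kg / body_density`
#' (so the volumetric weight reading is exact), and the eye-corner
#' landmarks are placed so the pupil-midpoint distance equals the subject's
#' inter-pupillary distance — the gender-specific population mean by
#' default, or a per-subject draw when `ipd_jitter_sd > 0`. IPD jitter is
#' what makes the downstream IPD-scaled measurement imperfect, emulating
#' the real spread of human IPDs around the population average.
#'
#' The mesh is emitted in arbitrary raw units (`raw_scale` cm per unit,
#' recorded in the `scale` field) so that the measurement chain must
#' recover the metric scale itself.
#'
#' @param height_cm,weight_kg Target stature (cm) and mass (kg).
#' @param gender `"female"` or `"male"`; selects the IPD population mean.
#' @param resolution Number of horizontal rings (default 48); the angular
#'   resolution follows as `ceiling(2/3 * resolution)`. Minimum 8.
#' @param seed Integer seed; only consumed when `ipd_jitter_sd > 0`, so
#'   jitter-free meshes are bit-identical across seeds.
#' @param ipd_jitter_sd SD (cm) of the subject's true IPD around the
#'   gendered mean; 0 (default) disables jitter.
#' @param constants An [anthropometry_constants()] object.
#' @param raw_scale Emission scale in cm per raw unit (default 100, i.e.
#'   metre-like model units).
#' @return An [anthro_mesh()] in raw units with all eight landmarks.
#' @examples
#' m <- generate_body_mesh(176.1, 78.4, "male")
#' measure(m, "male")
#' @export
generate_body_mesh <- function(height_cm, weight_kg,
                               gender = c("female", "male"),
                               resolution = 48L, seed = NULL,
                               ipd_jitter_sd = 0,
                               constants = anthropometry_constants(),
                               raw_scale = 100) {
  gender <- match.arg(gender)
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  check_positive(raw_scale, "raw_scale")
  resolution <- as.integer(resolution)
  if (resolution < 8L)
    stop_anthropix("'resolution' must be at least 8 for a watertight lathe",
                   "anthropix_config_error")
  n_z <- resolution
  n_t <- as.integer(ceiling(2 / 3 * resolution))

  H <- height_cm
  zf <- seq(0, 0.995, length.out = n_z)
  rf <- stats::approx(BODY_PROFILE[, "z"], BODY_PROFILE[, "r"], xout = zf,
                      rule = 2)$y
  z <- zf * H
  r <- rf * H

  theta <- 2 * pi * (seq_len(n_t) - 1L) / n_t
  ring <- function(j) cbind(r[j] * cos(theta), r[j] * sin(theta), z[j])
  v <- rbind(c(0, 0, 0),                       # 1: sole center
             do.call(rbind, lapply(seq_len(n_z), ring)),
             c(0, 0, H))                       # apex
  apex_idx <- nrow(v)
  ring_idx <- function(j, i) 1L + (j - 1L) * n_t + i   # i in 1..n_t
  nxt <- function(i) i %% n_t + 1L

  faces <- vector("list", 3L)
  i <- seq_len(n_t)
  # bottom cap (outward normal -z): center, then rim clockwise seen from +z
  faces[[1L]] <- cbind(1L, ring_idx(1L, nxt(i)), ring_idx(1L, i))
  # side walls
  side <- lapply(seq_len(n_z - 1L), function(j) {
    a <- ring_idx(j, i); b <- ring_idx(j, nxt(i))
    c2 <- ring_idx(j + 1L, i); d <- ring_idx(j + 1L, nxt(i))
    rbind(cbind(a, b, d), cbind(a, d, c2))
  })
  faces[[2L]] <- do.call(rbind, side)
  # top cone to the apex (outward normal up/outward)
  faces[[3L]] <- cbind(ring_idx(n_z, i), ring_idx(n_z, nxt(i)), apex_idx)
  f <- do.call(rbind, faces)
  storage.mode(f) <- "integer"

  # radial solve: template volume -> exact target volume
  v_target_cm3 <- weight_kg / constants$body_density * 1e6
  tmpl <- structure(list(vertices = v, faces = f), class = "anthro_mesh")
  v0 <- mesh_volume(tmpl, check = FALSE)
  k <- sqrt(v_target_cm3 / v0)
  if (k < RADIAL_SCALE_RANGE[1L] || k > RADIAL_SCALE_RANGE[2L])
    stop_anthropix(sprintf(
      "infeasible body template: 'weight_kg' = %g at 'height_cm' = %g needs radial scale %.3g (allowed %.2g-%.2g)",
      weight_kg, height_cm, k, RADIAL_SCALE_RANGE[1L], RADIAL_SCALE_RANGE[2L]),
      "anthropix_generation_error")
  v[, 1L] <- v[, 1L] * k
  v[, 2L] <- v[, 2L] * k

  # subject IPD: population mean, optionally jittered per subject
  ipd <- ipd_mean(gender, constants)
  if (ipd_jitter_sd > 0)
    ipd <- with_seed(seed, rnorm_pos(1L, ipd, ipd_jitter_sd))

  # eye-corner annotation vertices on (or near) the head surface, symmetric
  # about the sagittal plane so the pupil midpoints are exactly `ipd` apart
  z_e <- EYE_HEIGHT_FRAC * H
  r_e <- k * stats::approx(BODY_PROFILE[, "z"], BODY_PROFILE[, "r"],
                           xout = EYE_HEIGHT_FRAC, rule = 2)$y * H
  eye_y <- function(x) if (r_e > abs(x)) sqrt(r_e^2 - x^2) else r_e / 2
  xi <- ipd / 2 - EYE_WIDTH_CM / 2
  xo <- ipd / 2 + EYE_WIDTH_CM / 2
  eyes <- rbind(
    c(-xi, eye_y(xi), z_e),   # left_eye_inner  (subject's left = -x)
    c(-xo, eye_y(xo), z_e),   # left_eye_outer
    c(+xi, eye_y(xi), z_e),   # right_eye_inner
    c(+xo, eye_y(xo), z_e))   # right_eye_outer
  n_surf <- nrow(v)
  v <- rbind(v, eyes)

  landmarks <- c(left_eye_inner = n_surf + 1L, left_eye_outer = n_surf + 2L,
                 right_eye_inner = n_surf + 3L, right_eye_outer = n_surf + 4L,
                 head_apex = apex_idx,
                 foot_a = ring_idx(1L, 1L),
                 foot_b = ring_idx(1L, 1L + n_t %/% 3L),
                 foot_c = ring_idx(1L, 1L + (2L * n_t) %/% 3L))

  anthro_mesh(v / raw_scale, f, landmarks, units = "raw", scale = raw_scale)
}
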