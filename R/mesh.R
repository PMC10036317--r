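# The landmark-annotated triangle mesh container and its geometric core.
#
# Conventions: right-handed coordinates; faces are vertex-index triples wound
# counter-clockwise viewed from outside (positive signed volume); `units` is
# tracked explicitly ("raw" or "cm") and operations refuse unit-mismatched
# input rather than guessing.

LANDMARK_ROLES <- c("left_eye_inner", "left_eye_outer",
                    "right_eye_inner", "right_eye_outer",
                    "head_apex", "foot_a", "foot_b", "foot_c")

#' Construct a landmark-annotated body mesh
#'
#' A watertight triangulated body surface together with the eight named
#' landmarks the measurement chain needs: the four eye corners (from which
#' pupil centers are derived), the head apex, and three points on the soles
#' of the feet defining the foot plane.
#'
#' Landmark vertices may be annotation points that no face references; the
#' watertightness contract applies to the triangulated surface (every edge
#' shared by exactly two faces).
#'
#' @param vertices Numeric matrix, one row per vertex, columns x, y, z.
#' @param faces Integer matrix, one row per triangle, 1-based vertex indices
#'   wound counter-clockwise seen from outside.
#' @param landmarks Named integer vector mapping each of the eight landmark
#'   roles to a vertex index.
#' @param units `"raw"` (arbitrary linear units, pre-scaling) or `"cm"`.
#' @param scale Optional true scale (cm per raw unit) recorded by the
#'   synthetic generator; `NA` for meshes of unknown provenance.
#' @param validate Run the structural validity checks (default `TRUE`).
#' @return An object of class `anthro_mesh`.
#' @export
anthro_mesh <- function(vertices, faces, landmarks,
                        units = c("raw", "cm"), scale = NA_real_,
                        validate = TRUE) {
  units <- match.arg(units)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces,
                         landmarks = landmarks, units = units,
                         scale = scale),
                    class = "anthro_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate the structural invariants of a body mesh
#'
#' Checks dimensions, landmark completeness and range, watertightness (every
#' edge in exactly two faces), consistent outward orientation (positive
#' signed volume) and non-collinearity of the foot landmarks.
#'
#' @param mesh An [anthro_mesh()].
#' @return `mesh`, invisibly; errors are classed conditions.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (ncol(v) != 3L)
    stop_anthropix("vertices must have three columns", "anthropix_mesh_error")
  if (ncol(f) != 3L)
    stop_anthropix("faces must be triangles", "anthropix_mesh_error")
  if (any(f < 1L) || any(f > nrow(v)))
    stop_anthropix("face indices out of vertex range", "anthropix_mesh_error")
  lm <- mesh$landmarks
  missing_roles <- setdiff(LANDMARK_ROLES, names(lm))
  if (length(missing_roles) > 0L)
    stop_anthropix(paste0("missing landmark role(s): ",
                          paste(missing_roles, collapse = ", ")),
                   "anthropix_landmark_error")
  if (any(lm < 1L) || any(lm > nrow(v)))
    stop_anthropix("landmark index out of vertex range",
                   "anthropix_landmark_error")
  be <- boundary_edges(mesh)
  if (nrow(be) > 0L)
    stop_anthropix(sprintf(
      "mesh is not watertight: %d edge(s) not shared by exactly two faces (first: %d-%d)",
      nrow(be), be[1L, 1L], be[1L, 2L]), "anthropix_topology_error")
  if (mesh_volume(mesh, check = FALSE) <= 0)
    stop_anthropix("mesh orientation is inward (non-positive signed volume)",
                   "anthropix_orientation_error")
  ft <- v[lm[c("foot_a", "foot_b", "foot_c")], , drop = FALSE]
  n <- cross3(ft[2L, ] - ft[1L, ], ft[3L, ] - ft[1L, ])
  extent <- max(apply(v, 2L, function(z) diff(range(z))))
  if (sqrt(sum(n^2)) <= 1e-9 * extent^2)
    stop_anthropix("foot landmarks are collinear",
                   "anthropix_degenerate_error")
  invisible(mesh)
}

# Edges that are NOT shared by exactly two faces (directed-edge pairing).
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad) == 0L)
    return(matrix(integer(0), 0L, 2L))
  do.call(rbind, lapply(strsplit(bad, " "), as.integer))
}

#' Is a mesh watertight?
#'
#' @param mesh An [anthro_mesh()].
#' @return `TRUE` when every edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) nrow(boundary_edges(mesh)) == 0L

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Enclosed volume of a watertight triangle mesh
#'
#' Divergence-theorem volume: the sum over faces of the signed volumes of
#' tetrahedra spanned by each triangle and the coordinate origin,
#' `sum(det[a b c]) / 6`. Exact for watertight, consistently outward-wound
#' triangulations, positive for outward orientation, and invariant to
#' translation of the mesh.
#'
#' @param mesh An [anthro_mesh()].
#' @param check Verify watertightness first (default `TRUE`); the volume of
#'   an open surface is meaningless.
#' @return Volume in cubic mesh units.
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  if (check && !is_watertight(mesh)) {
    be <- boundary_edges(mesh)
    stop_anthropix(sprintf(
      "cannot compute enclosed volume of a non-watertight mesh (%d boundary edge(s), first: %d-%d)",
      nrow(be), be[1L, 1L], be[1L, 2L]), "anthropix_topology_error")
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  ch <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * ch[, 3L] - b[, 3L] * ch[, 2L]) -
          a[, 2L] * (b[, 1L] * ch[, 3L] - b[, 3L] * ch[, 1L]) +
          a[, 3L] * (b[, 1L] * ch[, 2L] - b[, 2L] * ch[, 1L])
  sum(det6) / 6
}

#' @export
print.anthro_mesh <- function(x, ...) {
  cat(sprintf("<anthro_mesh: %d vertices, %d faces, units=%s%s>\n",
              nrow(x$vertices), nrow(x$faces), x$units,
              if (is.na(x$scale)) "" else sprintf(", scale=%g cm/unit",
                                                  x$scale)))
  invisible(x)
}

#' Write / read a mesh as OBJ plus a JSON landmark sidecar
#'
#' The OBJ carries `v` and `f` lines only; the sidecar is a JSON object
#' mapping each landmark role to a 1-based vertex index, plus the unit tag
#' and recorded scale.
#'
#' @param mesh An [anthro_mesh()].
#' @param obj_path Path of the OBJ file.
#' @param landmark_path Path of the JSON sidecar; defaults to the OBJ path
#'   with extension `.landmarks.json`.
#' @return `write_mesh_obj`: the paths, invisibly. `read_mesh_obj`: an
#'   [anthro_mesh()].
#' @export
write_mesh_obj <- function(mesh, obj_path,
                           landmark_path = sub("\\.obj$", ".landmarks.json",
                                               obj_path)) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(obj_path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  jsonlite::write_json(
    list(landmarks = as.list(mesh$landmarks), units = mesh$units,
         scale = mesh$scale),
    landmark_path, auto_unbox = TRUE, digits = NA)
  invisible(c(obj = obj_path, landmarks = landmark_path))
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(obj_path,
                          landmark_path = sub("\\.obj$", ".landmarks.json",
                                              obj_path)) {
  lines <- readLines(obj_path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  ftok <- strsplit(sub("^f ", "", fl), "[ ]+")
  f <- t(vapply(ftok, function(t) as.integer(sub("/.*$", "", t[1:3])),
                integer(3L)))
  side <- jsonlite::read_json(landmark_path, simplifyVector = TRUE)
  lm <- unlist(side$landmarks)
  anthro_mesh(v, f, lm, units = side$units,
              scale = if (is.null(side$scale)) NA_real_ else side$scale)
}
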