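# Independent oracles and fixture builders for the test suite. Everything
# here is deliberately naive (enumeration, sampling, direct construction)
# and shares no code path with the package implementation it checks.

# --- analytic solids -------------------------------------------------------

# unit-cube-like box [0,a]x[0,b]x[0,c] as 12 outward-wound triangles
box_mesh <- function(a = 1, b = 1, c = 1) {
  v <- cbind(c(0, a, a, 0, 0, a, a, 0),
             c(0, 0, b, b, 0, 0, b, b),
             c(0, 0, 0, 0, c, c, c, c))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (normal -z)
             c(5, 6, 7), c(5, 7, 8),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(2, 3, 7), c(2, 7, 6),   # +x
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(4, 1, 5), c(4, 5, 8))   # -x
  dummy_landmark_mesh(v, f)
}

# icosphere: subdivided icosahedron with vertices projected onto radius r
icosphere_mesh <- function(r = 1, refine = 0L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2)) * r
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (step in seq_len(refine)) {
    edge_mid <- new.env()
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(edge_mid[[key]])) return(edge_mid[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2)) * r
      v <<- rbind(v, m)
      edge_mid[[key]] <- nrow(v)
      nrow(v)
    }
    f <- do.call(rbind, lapply(seq_len(nrow(f)), function(t) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }))
  }
  dummy_landmark_mesh(v, f)
}

# random watertight closed lathe (surface of revolution), independent of
# the package's body generator: fresh construction with its own winding
random_lathe_mesh <- function(n_z = 14L, n_t = 12L) {
  z <- sort(runif(n_z, 0, 2))
  z <- z - z[1L]
  r <- runif(n_z, 0.2, 1)
  theta <- 2 * pi * (seq_len(n_t) - 1L) / n_t
  v <- rbind(c(0, 0, z[1L] - runif(1, 0.1, 0.5)),
             do.call(rbind, lapply(seq_len(n_z), function(j)
               cbind(r[j] * cos(theta), r[j] * sin(theta), z[j]))),
             c(0, 0, z[n_z] + runif(1, 0.1, 0.5)))
  top <- nrow(v)
  idx <- function(j, i) 1L + (j - 1L) * n_t + i
  nx <- function(i) i %% n_t + 1L
  i <- seq_len(n_t)
  f <- rbind(cbind(1L, idx(1L, nx(i)), idx(1L, i)),
             do.call(rbind, lapply(seq_len(n_z - 1L), function(j)
               rbind(cbind(idx(j, i), idx(j, nx(i)), idx(j + 1L, nx(i))),
                     cbind(idx(j, i), idx(j + 1L, nx(i)), idx(j + 1L, i))))),
             cbind(idx(n_z, i), idx(n_z, nx(i)), top))
  dummy_landmark_mesh(v, f)
}

# wrap raw geometry as an anthro_mesh with placeholder landmarks so the
# container accepts it (landmark positions are irrelevant to volume tests)
dummy_landmark_mesh <- function(v, f) {
  lm <- c(left_eye_inner = 1L, left_eye_outer = 2L,
          right_eye_inner = 3L, right_eye_outer = 4L,
          head_apex = 5L, foot_a = 1L, foot_b = 2L, foot_c = 3L)
  anthro_mesh(v, f, lm, units = "raw", validate = FALSE)
}

# --- Monte-Carlo point-in-mesh volume oracle -------------------------------

# +z ray casting: a point is inside iff an odd number of triangles cross
# the vertical ray above it; volume = inside fraction x bounding-box volume
mc_volume_oracle <- function(mesh, n_points = 2e5) {
  v <- mesh$vertices
  f <- mesh$faces
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  p <- cbind(runif(n_points, lo[1], hi[1]),
             runif(n_points, lo[2], hi[2]),
             runif(n_points, lo[3], hi[3]))
  crossings <- integer(n_points)
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c3 <- v[f[t, 3], ]
    d <- (b[2] - c3[2]) * (a[1] - c3[1]) + (c3[1] - b[1]) * (a[2] - c3[2])
    if (abs(d) < 1e-13) next
    # xy bounding-box prefilter: only nearby points can cross this face
    cand <- which(p[, 1] >= min(a[1], b[1], c3[1]) &
                    p[, 1] <= max(a[1], b[1], c3[1]) &
                    p[, 2] >= min(a[2], b[2], c3[2]) &
                    p[, 2] <= max(a[2], b[2], c3[2]))
    if (length(cand) == 0L) next
    l1 <- ((b[2] - c3[2]) * (p[cand, 1] - c3[1]) +
             (c3[1] - b[1]) * (p[cand, 2] - c3[2])) / d
    l2 <- ((c3[2] - a[2]) * (p[cand, 1] - c3[1]) +
             (a[1] - c3[1]) * (p[cand, 2] - c3[2])) / d
    l3 <- 1 - l1 - l2
    ins <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(ins)) next
    hit <- cand[ins]
    zhit <- l1[ins] * a[3] + l2[ins] * b[3] + l3[ins] * c3[3]
    crossings[hit] <- crossings[hit] + (zhit > p[hit, 3])
  }
  mean(crossings %% 2L == 1L) * prod(hi - lo)
}

# --- nonparametric-test oracles --------------------------------------------

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  allW <- vapply(0:(2^n - 1), function(bits)
    sum(rk[bitwAnd(bits, bitwShiftL(1L, 0:(n - 1))) != 0L]), numeric(1))
  min(1, mean(abs(allW - mu) >= abs(W - mu) - 1e-12))
}

# tie-corrected Friedman statistic computed from first principles
friedman_stat_oracle <- function(mat) {
  r <- t(apply(mat, 1, rank))
  n <- nrow(mat); k <- ncol(mat)
  S <- sum((colSums(r) - n * (k + 1) / 2)^2)
  A <- sum(r^2); C <- n * k * (k + 1)^2 / 4
  if (A == C) 0 else (k - 1) * S / (A - C)
}

# permutation p for the Friedman statistic: shuffle within rows
friedman_perm_p <- function(mat, n_perm = 10000L) {
  obs <- friedman_stat_oracle(mat)
  k <- ncol(mat)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pm <- t(apply(mat, 1, sample, size = k))
    if (friedman_stat_oracle(pm) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# --- misc ------------------------------------------------------------------

random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

rigid_transform_mesh <- function(mesh, R = random_rotation(),
                                 t = rnorm(3, sd = 50)) {
  out <- mesh
  out$vertices <- sweep(mesh$vertices %*% t(R), 2, t, `+`)
  out
}

# minimal estimate table for hand-built statistics cases
make_estimates <- function(image_id, participant_id, est_h, est_w = NA,
                           group = "nonexpert",
                           estimator_id = paste0("r", seq_along(image_id))) {
  data.frame(image_id = image_id, participant_id = participant_id,
             estimator_id = estimator_id, group = group,
             height_est_cm = est_h, weight_est_kg = est_w,
             stringsAsFactors = FALSE)
}

make_truth <- function(participant_id, height, weight = 70,
                       gender = "female") {
  out <- data.frame(participant_id = participant_id, gender = gender,
                    true_height_cm = height, true_weight_kg = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("anthro_cohort", "data.frame")
  out
}
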