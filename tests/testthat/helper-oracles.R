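# Shared oracles and fixture builders, all independent of the package's
# production code paths they are used to check.

# canonical form of a triangle index matrix, for set comparison
canon_tri <- function(m) {
  m <- t(apply(m, 1, sort))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Moller-Trumbore barycentric ray/triangle oracle (scalar, pure R)
bary_hit <- function(origin, dir, v1, v2, v3, eps = 1e-12) {
  e1 <- v2 - v1; e2 <- v3 - v1
  p <- c(dir[2] * e2[3] - dir[3] * e2[2],
         dir[3] * e2[1] - dir[1] * e2[3],
         dir[1] * e2[2] - dir[2] * e2[1])
  det <- sum(e1 * p)
  if (abs(det) < eps) return(NULL)
  tv <- origin - v1
  u <- sum(tv * p) / det
  if (u < -1e-9 || u > 1 + 1e-9) return(NULL)
  q <- c(tv[2] * e1[3] - tv[3] * e1[2],
         tv[3] * e1[1] - tv[1] * e1[3],
         tv[1] * e1[2] - tv[2] * e1[1])
  v <- sum(dir * q) / det
  if (v < -1e-9 || u + v > 1 + 1e-9) return(NULL)
  t <- sum(e2 * q) / det
  if (t <= 1e-12) return(NULL)
  list(t = t, point = origin + t * dir)
}

# exhaustive pure-R first hit over a canopy mesh via ray_triangle_intersect
r_first_hit <- function(mesh, origin, dir, skip_facet = NA, skip_tree = NA) {
  best <- NULL; best_t <- Inf; best_j <- NA
  for (j in seq_len(nrow(mesh$triangles))) {
    if (!is.na(skip_facet) && j == skip_facet) next
    if (!is.na(skip_tree) && mesh$tree_index[j] == skip_tree) next
    v <- mesh$vertices
    h <- ray_triangle_intersect(origin, dir,
                                v[mesh$triangles[j, 1], ],
                                v[mesh$triangles[j, 2], ],
                                v[mesh$triangles[j, 3], ])
    if (is.null(h)) next
    if (h$t < best_t - 1e-9 || (h$t < best_t + 1e-9 && j < best_j)) {
      best <- h; best_t <- h$t; best_j <- j
    }
  }
  if (is.null(best)) NULL else c(best, triangle = best_j)
}

# small random scene for oracle-equivalence sweeps
rand_small_scene <- function(seed, n = 3, size = 14) {
  set.seed(seed)
  trees <- data.frame(
    tree_id = sprintf("r%02d", seq_len(n)),
    species_class = sample(c("conifer", "broadleaf"), n, replace = TRUE),
    center_x = runif(n, 3, size - 3),
    center_y = runif(n, 3, size - 3),
    clear_bole_height = runif(n, 1, 3),
    tree_height = runif(n, 6, 12),
    half_width_ew = runif(n, 1, 3),
    half_width_ns = runif(n, 1, 3),
    stringsAsFactors = FALSE)
  plot_scene(trees, plot_bounds = c(0, size, 0, size))
}

# brute-force circumcircle containment check for a triangulation
circumcircle_ok <- function(points, tri, tol = 1e-9) {
  for (k in seq_len(nrow(tri))) {
    a <- points[tri[k, 1], ]; b <- points[tri[k, 2], ]; c <- points[tri[k, 3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) return(FALSE)
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    dist2 <- (points[, 1] - ux)^2 + (points[, 2] - uy)^2
    if (any(dist2 < r2 * (1 - tol) - 1e-12)) return(FALSE)
  }
  TRUE
}
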