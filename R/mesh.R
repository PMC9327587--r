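#' Mesh resolution specification
#'
#' Either fix the number of concentric rings and points per ring for every
#' crown, or (default) derive both per crown from a target vertex spacing:
#' rings from the meridian arc length of the crown profile, points per ring
#' from the footprint perimeter, so that neighbouring vertices on the crown
#' surface are about `target_vertex_spacing` apart.
#'
#' @param target_vertex_spacing Target spacing between adjacent mesh
#'   vertices in metres (default 1.36, the accuracy/runtime tradeoff used
#'   for plot-scale runs).
#' @param n_rings Optional fixed ring count (>= 1) overriding the spacing.
#' @param points_per_ring Optional fixed points per ring (>= 3).
#' @return An object of class `mesh_resolution`.
#' @export
mesh_resolution <- function(target_vertex_spacing = 1.36, n_rings = NULL,
                            points_per_ring = NULL) {
  if (!is.null(n_rings) && (n_rings < 1 || n_rings != round(n_rings)))
    stop("`n_rings` must be a positive integer", call. = FALSE)
  if (!is.null(points_per_ring) &&
      (points_per_ring < 3 || points_per_ring != round(points_per_ring)))
    stop("`points_per_ring` must be an integer >= 3", call. = FALSE)
  if (!is.finite(target_vertex_spacing) || target_vertex_spacing <= 0)
    stop("`target_vertex_spacing` must be > 0", call. = FALSE)
  structure(list(target_vertex_spacing = target_vertex_spacing,
                 n_rings = n_rings, points_per_ring = points_per_ring),
            class = "mesh_resolution")
}

# Ring count and points per ring for one crown under a resolution spec.
crown_sampling <- function(tree, resolution) {
  a <- max(tree$half_width_ew, tree$half_width_ns)
  cc <- tree$tree_height - tree$clear_bole_height
  s <- resolution$target_vertex_spacing
  n_rings <- resolution$n_rings
  if (is.null(n_rings)) {
    if (identical(tree$species_class, "conifer")) {
      meridian <- sqrt(a^2 + cc^2)            # cone slant
    } else {
      # quarter arc of the profile ellipse (Ramanujan perimeter / 4)
      p <- a; q <- cc
      meridian <- pi * (3 * (p + q) - sqrt((3 * p + q) * (p + 3 * q))) / 4
    }
    n_rings <- max(1L, as.integer(round(meridian / s)))
  }
  xi <- resolution$points_per_ring
  if (is.null(xi)) {
    perimeter <- pi * (tree$half_width_ew + tree$half_width_ns)
    xi <- max(6L, as.integer(ceiling(perimeter / s)))
  }
  list(n_rings = as.integer(n_rings), points_per_ring = as.integer(xi))
}

#' Sample a crown footprint with concentric rings
#'
#' Returns the centre point plus `n_rings` concentric elliptical rings of
#' `points_per_ring` points each, ring `r` at fraction `r / n_rings` of the
#' crown half-widths, points equally spaced in parametric angle (equal arc
#' length when the footprint is circular). Consecutive rings are offset by
#' half an angular step to avoid slivers and cocircular degeneracies.
#'
#' @param tree One row of a scene's `trees` data.frame.
#' @param resolution A [mesh_resolution()].
#' @return A two-column matrix of plan coordinates; `1 + n_rings * xi` rows.
#' @export
sample_footprint <- function(tree, resolution = mesh_resolution()) {
  cs <- crown_sampling(tree, resolution)
  n <- cs$n_rings; xi <- cs$points_per_ring
  pts <- matrix(c(tree$center_x, tree$center_y), ncol = 2)
  step <- 2 * pi / xi
  for (r in seq_len(n)) {
    f <- r / n
    offset <- if (r %% 2 == 0) step / 2 else 0
    ang <- offset + step * (seq_len(xi) - 1)
    pts <- rbind(pts, cbind(tree$center_x + f * tree$half_width_ew * cos(ang),
                            tree$center_y + f * tree$half_width_ns * sin(ang)))
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Planar Delaunay triangulation of footprint samples
#'
#' Incremental (Bowyer-Watson) Delaunay triangulation of a 2-D point set,
#' returned as a matrix of vertex index triples. Every triangle satisfies
#' the empty-circumcircle property; cocircular point groups (concentric
#' ring samples of a circular footprint) are triangulated consistently.
#'
#' @param points Two-column matrix of plan coordinates (>= 3 points, not
#'   all collinear).
#' @return Integer matrix with one triangle per row (1-based indices into
#'   `points`).
#' @export
triangulate_projected <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop("need at least 3 points to triangulate", call. = FALSE)
  # collinearity check via the covariance rank
  sv <- svd(scale(points, scale = FALSE))$d
  if (sv[2] < 1e-10 * max(sv[1], 1))
    stop("points are collinear; triangulation is degenerate", call. = FALSE)
  tri <- cpp_delaunay(points)
  if (nrow(tri) == 0)
    stop("triangulation failed", call. = FALSE)
  colnames(tri) <- c("v1", "v2", "v3")
  tri
}

# Orient triangles so the Eq-style cross-product normal points outward
# (upward on the upper crown sheet); returns list(triangles, normals, areas)
# with degenerate facets dropped.
orient_facets <- function(vertices, triangles, center_xy) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nlen <- sqrt(nx^2 + ny^2 + nz^2)
  keep <- nlen > 1e-10
  flip <- nz < 0
  # near-vertical facets: orient away from the crown axis
  vert <- abs(nz) <= 1e-12 * nlen
  if (any(vert)) {
    cx <- (p1[, 1] + p2[, 1] + p3[, 1]) / 3 - center_xy[1]
    cy <- (p1[, 2] + p2[, 2] + p3[, 2]) / 3 - center_xy[2]
    flip[vert] <- (nx[vert] * cx[vert] + ny[vert] * cy[vert]) < 0
  }
  tr <- triangles
  tr[flip, c(2, 3)] <- tr[flip, c(3, 2)]
  sgn <- ifelse(flip, -1, 1)
  normals <- cbind(sgn * nx, sgn * ny, sgn * nz) / nlen
  list(triangles = tr[keep, , drop = FALSE],
       normals = normals[keep, , drop = FALSE],
       areas = (nlen / 2)[keep])
}

#' Lift a planar triangulation onto a crown surface
#'
#' Assigns each footprint sample its crown surface height, keeps the planar
#' connectivity, and computes per-facet outward unit normals (cross-product
#' normals re-oriented upward/outward) and areas. Zero-area facets (for
#' example slivers collapsing onto a cone apex) are dropped.
#'
#' @param tree One row of a scene's `trees` data.frame.
#' @param points Two-column matrix of footprint samples (inside the
#'   footprint).
#' @param triangles Triangle index matrix from [triangulate_projected()].
#' @return List with `vertices` (n x 3), `triangles`, `normals`, `areas`.
#' @export
lift_to_surface <- function(tree, points, triangles) {
  z <- surface_height(tree, points[, 1], points[, 2])
  if (any(is.na(z)))
    stop("footprint sample outside the crown footprint", call. = FALSE)
  vertices <- cbind(points[, 1], points[, 2], z)
  colnames(vertices) <- c("x", "y", "z")
  of <- orient_facets(vertices, triangles, c(tree$center_x, tree$center_y))
  list(vertices = vertices, triangles = of$triangles,
       normals = of$normals, areas = of$areas)
}

#' Triangulate every crown surface of a scene
#'
#' Runs the projected sampling / planar Delaunay / back-projection pipeline
#' for each tree and concatenates the fragments with global vertex indexing
#' and per-facet tree and species tags.
#'
#' @param scene A [plot_scene()].
#' @param resolution A [mesh_resolution()].
#' @return An object of class `canopy_mesh`: list with `vertices` (n x 3
#'   matrix, metres), `triangles` (m x 3 integer matrix), `normals`
#'   (m x 3 unit rows), `areas` (length m), `tree_id`, `species_class`,
#'   `tree_index` (per-facet), and `resolution`.
#' @export
build_canopy_mesh <- function(scene, resolution = mesh_resolution()) {
  stopifnot(inherits(scene, "plot_scene"))
  tr <- scene$trees
  if (nrow(tr) == 0)
    stop("cannot mesh an empty scene", call. = FALSE)
  verts <- list(); tris <- list(); normals <- list(); areas <- list()
  tree_id <- list(); species <- list(); tindex <- list()
  offset <- 0L
  for (i in seq_len(nrow(tr))) {
    tree <- tr[i, ]
    pts <- sample_footprint(tree, resolution)
    # triangulate in the axis-normalized footprint frame: rings become
    # concentric circles there, so elongated crowns do not produce lifted
    # sliver facets (connectivity, hence the back-projection property, is
    # unaffected)
    norm_pts <- cbind((pts[, 1] - tree$center_x) / tree$half_width_ew,
                      (pts[, 2] - tree$center_y) / tree$half_width_ns)
    tg <- triangulate_projected(norm_pts)
    frag <- lift_to_surface(tree, pts, tg)
    m <- nrow(frag$triangles)
    verts[[i]] <- frag$vertices
    tris[[i]] <- frag$triangles + offset
    normals[[i]] <- frag$normals
    areas[[i]] <- frag$areas
    tree_id[[i]] <- rep(tree$tree_id, m)
    species[[i]] <- rep(tree$species_class, m)
    tindex[[i]] <- rep(i, m)
    offset <- offset + nrow(frag$vertices)
  }
  structure(list(
    vertices = do.call(rbind, verts),
    triangles = do.call(rbind, tris),
    normals = do.call(rbind, normals),
    areas = unlist(areas),
    tree_id = unlist(tree_id),
    species_class = unlist(species),
    tree_index = unlist(tindex),
    resolution = resolution,
    scene = scene
  ), class = "canopy_mesh")
}

#' @export
print.canopy_mesh <- function(x, ...) {
  cat(sprintf("<canopy_mesh> %d facets / %d vertices over %d trees; surface area %.1f m2\n",
              nrow(x$triangles), nrow(x$vertices),
              length(unique(x$tree_index)), sum(x$areas)))
  invisible(x)
}

#' Total facet area of a canopy mesh
#' @param mesh A [build_canopy_mesh()] result.
#' @return Area in square metres.
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

#' Export a canopy mesh as Wavefront OBJ
#'
#' Plain ASCII OBJ with one object per tree; coordinates in metres,
#' plot-local frame.
#'
#' @param mesh A [build_canopy_mesh()] result.
#' @param path Output path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# canopyflux crown surface mesh", con)
  v <- mesh$vertices
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  ord <- order(mesh$tree_index)
  cur <- -1L
  for (j in ord) {
    ti <- mesh$tree_index[j]
    if (ti != cur) {
      writeLines(sprintf("o tree_%s", mesh$tree_id[j]), con)
      cur <- ti
    }
    writeLines(sprintf("f %d %d %d", mesh$triangles[j, 1],
                       mesh$triangles[j, 2], mesh$triangles[j, 3]), con)
  }
  invisible(path)
}

#' Export a canopy mesh as ASCII PLY with per-face attributes
#'
#' Writes face properties `tree` (tree index), `species` (0 = conifer,
#' 1 = broadleaf) and, when `face_scalar` is given, the scalar itself plus
#' a green-to-red colour ramp over its range.
#'
#' @param mesh A [build_canopy_mesh()] result.
#' @param path Output path.
#' @param face_scalar Optional numeric per-facet values (such as flux in W).
#' @param scalar_name Name of the scalar property (default "flux").
#' @export
write_ply <- function(mesh, path, face_scalar = NULL, scalar_name = "flux") {
  m <- nrow(mesh$triangles)
  if (!is.null(face_scalar) && length(face_scalar) != m)
    stop("`face_scalar` must have one value per facet", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0", "comment canopyflux crown surface mesh",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", m),
           "property list uchar int vertex_indices",
           "property int tree", "property uchar species")
  if (!is.null(face_scalar))
    hdr <- c(hdr, sprintf("property float %s", scalar_name),
             "property uchar red", "property uchar green", "property uchar blue")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  v <- mesh$vertices
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  sp <- as.integer(mesh$species_class == "broadleaf")
  if (is.null(face_scalar)) {
    writeLines(sprintf("3 %d %d %d %d %d",
                       mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                       mesh$triangles[, 3] - 1L, mesh$tree_index, sp), con)
  } else {
    rng <- range(face_scalar, finite = TRUE)
    f <- if (diff(rng) > 0) (face_scalar - rng[1]) / diff(rng) else rep(0, m)
    red <- as.integer(round(255 * f))
    green <- as.integer(round(255 * (1 - f)))
    writeLines(sprintf("3 %d %d %d %d %d %.6f %d %d 0",
                       mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                       mesh$triangles[, 3] - 1L, mesh$tree_index, sp,
                       face_scalar, red, green), con)
  }
  invisible(path)
}
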