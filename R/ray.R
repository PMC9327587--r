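#' Generate the parallel solar beam grid
#'
#' Beams start on a horizontal source plane (default 100 m) as a
#' cell-centred square lattice with the given spacing, all sharing the
#' solar beam direction. The conceptual source plane is a large square
#' (default 800 m on a side) centred on the plot; by default the lattice is
#' culled to the beams whose ray can intersect the scene's bounding box, an
#' optimization that does not change any canopy hit because the lattice is
#' anchored to the conceptual plane's absolute origin.
#'
#' @param state A [solar_position()] with altitude > 0.
#' @param scene A [plot_scene()] (its crowns define the culling box).
#' @param spacing Lattice spacing in metres (default 0.2, i.e. a beam
#'   density of 25 per square metre).
#' @param source_height Height of the source plane in metres (default 100).
#' @param plane_extent Side length of the conceptual source plane (default
#'   800 m).
#' @param cull If `FALSE`, emit the full lattice over the conceptual plane.
#' @return An object of class `beam_grid`: list with `origins` (n x 3
#'   matrix), `direction`, `spacing`, `density`, `source_height`.
#' @export
generate_beams <- function(state, scene, spacing = 0.2, source_height = 100,
                           plane_extent = 800, cull = TRUE) {
  stopifnot(inherits(state, "solar_state"))
  if (state$altitude <= 0)
    stop("sun is at or below the horizon; no beams to emit", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  d <- state$beam_direction
  pb <- scene$plot_bounds
  cx <- mean(pb[1:2]); cy <- mean(pb[3:4])
  half <- plane_extent / 2
  # absolute lattice anchored at the conceptual plane's lower-left corner
  ox <- cx - half; oy <- cy - half
  nmax <- floor(plane_extent / spacing)
  if (cull && nrow(scene$trees) > 0) {
    tr <- scene$trees
    bx <- range(c(tr$center_x - tr$half_width_ew, tr$center_x + tr$half_width_ew))
    by <- range(c(tr$center_y - tr$half_width_ns, tr$center_y + tr$half_width_ns))
    bz <- c(min(tr$clear_bole_height), max(tr$tree_height))
    # back-project the 8 box corners onto the source plane along -direction
    corners <- as.matrix(expand.grid(x = bx, y = by, z = bz))
    tt <- (source_height - corners[, 3]) / (-d[3])
    sx <- corners[, 1] - d[1] * tt
    sy <- corners[, 2] - d[2] * tt
    xr <- range(sx) + c(-spacing, spacing)
    yr <- range(sy) + c(-spacing, spacing)
  } else {
    xr <- c(ox, ox + plane_extent)
    yr <- c(oy, oy + plane_extent)
  }
  i0 <- max(0L, as.integer(floor((xr[1] - ox) / spacing)))
  i1 <- min(nmax - 1L, as.integer(floor((xr[2] - ox) / spacing)))
  k0 <- max(0L, as.integer(floor((yr[1] - oy) / spacing)))
  k1 <- min(nmax - 1L, as.integer(floor((yr[2] - oy) / spacing)))
  if (i1 < i0 || k1 < k0) {
    origins <- matrix(numeric(0), ncol = 3)
  } else {
    xs <- ox + (seq.int(i0, i1) + 0.5) * spacing
    ys <- oy + (seq.int(k0, k1) + 0.5) * spacing
    g <- expand.grid(x = xs, y = ys)
    origins <- cbind(g$x, g$y, source_height)
  }
  colnames(origins) <- c("x", "y", "z")
  structure(list(origins = origins, direction = d, spacing = spacing,
                 density = spacing^-2, source_height = source_height,
                 plane_extent = plane_extent, state = state),
            class = "beam_grid")
}

#' @export
print.beam_grid <- function(x, ...) {
  cat(sprintf("<beam_grid> %d beams at %.2f m spacing (%.0f per m2), source plane %g m\n",
              nrow(x$origins), x$spacing, x$density, x$source_height))
  invisible(x)
}

#' Intersect one ray with one triangle
#'
#' Plane-parameter intersection `t = N . (p1 - origin) / (N . direction)`
#' with a same-side inside test; misses when the ray is parallel to the
#' facet plane, the intersection lies behind the origin, or the point falls
#' outside the triangle.
#'
#' @param origin,direction Numeric length-3 vectors (direction need not be
#'   unit length; `t` is in units of its norm).
#' @param v1,v2,v3 Triangle vertices, numeric length-3.
#' @return `NULL` on a miss, otherwise a list with `t`, `point` and
#'   `incidence_cosine` (the absolute cosine of the angle between ray and
#'   facet normal).
#' @export
ray_triangle_intersect <- function(origin, direction, v1, v2, v3) {
  res <- cpp_ray_triangle(as.numeric(origin), as.numeric(direction),
                          as.numeric(v1), as.numeric(v2), as.numeric(v3))
  if (!isTRUE(res$hit)) return(NULL)
  res$hit <- NULL
  res
}

# Shared driver for first-hit queries. dirs: 1 x 3 or n x 3 matrix.
first_hits_impl <- function(mesh, origins, dirs, skip_facet = NULL,
                            skip_tree = NULL, method = c("grid", "brute"),
                            cell_size = 2) {
  method <- match.arg(method)
  origins <- matrix(as.numeric(origins), ncol = 3)
  dirs <- matrix(as.numeric(dirs), ncol = 3)
  n <- nrow(origins)
  sf <- if (is.null(skip_facet)) integer(0) else as.integer(skip_facet)
  sg <- if (is.null(skip_tree)) integer(0) else as.integer(skip_tree)
  res <- cpp_first_hits(mesh$vertices, mesh$triangles, origins, dirs,
                        sf, sg, as.integer(mesh$tree_index),
                        cell_size, method == "brute")
  hit <- !is.na(res$triangle)
  data.frame(beam_index = seq_len(n), triangle = res$triangle,
             tree_id = ifelse(hit, mesh$tree_id[res$triangle], NA),
             x = res$x, y = res$y, z = res$z, t = res$t,
             incidence_cosine = res$incidence_cosine)
}

#' First-hit resolution of a beam grid against a canopy mesh
#'
#' For each beam, finds the intersected facet with the smallest ray
#' parameter (ties broken by lowest facet index); beams that reach the
#' ground unobstructed get `NA` rows.
#'
#' @param beams A [generate_beams()] grid.
#' @param mesh A [build_canopy_mesh()] result.
#' @param method `"grid"` (uniform spatial-hash acceleration, default) or
#'   `"brute"` (exhaustive loop; identical results, used as oracle).
#' @param cell_size Acceleration grid cell size in metres.
#' @return A data.frame with one row per beam: `beam_index`, `triangle`,
#'   `tree_id`, hit coordinates `x`,`y`,`z`, ray parameter `t`, and
#'   `incidence_cosine`.
#' @export
first_hit <- function(beams, mesh, method = c("grid", "brute"), cell_size = 2) {
  stopifnot(inherits(beams, "beam_grid"), inherits(mesh, "canopy_mesh"))
  if (nrow(beams$origins) == 0)
    return(first_hits_impl(mesh, matrix(numeric(0), ncol = 3),
                           matrix(beams$direction, ncol = 3),
                           method = method, cell_size = cell_size)[0, ])
  first_hits_impl(mesh, beams$origins, matrix(beams$direction, ncol = 3),
                  method = method, cell_size = cell_size)
}

#' Specular reflection of a direction about a facet normal
#'
#' `r = d - 2 (d . n) n`; preserves the norm and the angle to the normal.
#'
#' @param incident Unit direction of the incoming ray.
#' @param normal Unit facet normal.
#' @return Unit reflected direction.
#' @export
reflect_direction <- function(incident, normal) {
  incident - 2 * sum(incident * normal) * normal
}

#' Snell refraction of a direction through a facet
#'
#' Vector form of Snell's law with refractive ratio `e`
#' (sin(theta_out) = e sin(theta_in)):
#' `t = e L + (e c1 - c2) N` with `c1 = -N . L` and
#' `c2 = sqrt(1 - e^2 (1 - c1^2))`. The incident direction must point into
#' the surface (`incident . normal < 0`).
#'
#' @param incident Unit incident direction.
#' @param normal Unit facet normal (pointing against the incident ray).
#' @param e Refractive ratio (default 0.5).
#' @return Unit refracted direction.
#' @export
refract_direction <- function(incident, normal, e = 0.5) {
  c1 <- -sum(normal * incident)
  if (c1 < 0)
    stop("`incident` must point into the surface (incident . normal < 0)",
         call. = FALSE)
  rad <- 1 - e^2 * (1 - c1^2)
  if (rad < 0)
    stop("total internal reflection: refraction undefined for these inputs",
         call. = FALSE)
  out <- e * incident + (e * c1 - sqrt(rad)) * normal
  out / sqrt(sum(out^2))
}

#' Trace single-bounce reflected and transmitted rays
#'
#' For every first hit, spawns one specularly reflected ray (which may hit
#' any facet except the one it left) and one refracted transmitted ray
#' (which skips every facet of the originating tree), and traces each to
#' its own first hit. Recursion depth is one: children do not spawn
#' grandchildren.
#'
#' @param hits First-pass hit table from [first_hit()].
#' @param mesh The [build_canopy_mesh()] the hits refer to.
#' @param beams The [generate_beams()] grid that produced the hits.
#' @param e Refractive ratio for transmission (default 0.5).
#' @param offset Origin offset along the child direction to avoid
#'   self-intersection (default 1e-6 m).
#' @param method,cell_size Passed to the first-hit query.
#' @return List with data.frames `reflected` and `transmitted`; each row is
#'   a child-ray hit with parent bookkeeping columns `parent_triangle`,
#'   `parent_tree_id`, `parent_species`.
#' @export
trace_secondary <- function(hits, mesh, beams, e = 0.5, offset = 1e-6,
                            method = c("grid", "brute"), cell_size = 2) {
  method <- match.arg(method)
  hh <- hits[!is.na(hits$triangle), , drop = FALSE]
  empty <- data.frame(beam_index = integer(0), triangle = integer(0),
                      tree_id = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), t = numeric(0),
                      incidence_cosine = numeric(0),
                      parent_triangle = integer(0), parent_tree_id = character(0),
                      parent_species = character(0))
  if (nrow(hh) == 0) return(list(reflected = empty, transmitted = empty))
  d <- beams$direction
  N <- mesh$normals[hh$triangle, , drop = FALSE]
  dn <- N[, 1] * d[1] + N[, 2] * d[2] + N[, 3] * d[3]
  # outward normals face the downward beam, so d.N < 0; flip any stragglers
  # so reflection and refraction see the against-the-ray normal
  flip <- dn > 0
  N[flip, ] <- -N[flip, ]
  dn <- -abs(dn)
  refl <- cbind(d[1] - 2 * dn * N[, 1], d[2] - 2 * dn * N[, 2],
                d[3] - 2 * dn * N[, 3])
  c1 <- -dn
  rad <- 1 - e^2 * (1 - c1^2)
  trans <- cbind(e * d[1] + (e * c1 - sqrt(rad)) * N[, 1],
                 e * d[2] + (e * c1 - sqrt(rad)) * N[, 2],
                 e * d[3] + (e * c1 - sqrt(rad)) * N[, 3])
  trans <- trans / sqrt(rowSums(trans^2))
  pts <- cbind(hh$x, hh$y, hh$z)
  parent <- data.frame(parent_triangle = hh$triangle,
                       parent_tree_id = mesh$tree_id[hh$triangle],
                       parent_species = mesh$species_class[hh$triangle],
                       stringsAsFactors = FALSE)
  rh <- first_hits_impl(mesh, pts + offset * refl, refl,
                        skip_facet = hh$triangle, method = method,
                        cell_size = cell_size)
  th <- first_hits_impl(mesh, pts + offset * trans, trans,
                        skip_tree = mesh$tree_index[hh$triangle],
                        method = method, cell_size = cell_size)
  rh <- cbind(rh, parent); th <- cbind(th, parent)
  rh$beam_index <- hh$beam_index; th$beam_index <- hh$beam_index
  list(reflected = rh[!is.na(rh$triangle), , drop = FALSE],
       transmitted = th[!is.na(th$triangle), , drop = FALSE])
}
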