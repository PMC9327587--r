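noon_state <- function() solar_position(site_time(32.076, 166, 12))
vertical_state <- function()
  solar_position(site_time(declination(166), 166, 12))  # altitude 90

test_that("beam grids have the prescribed density and anchoring", {
  sc <- plot_scene(data.frame(
    tree_id = "t1", species_class = "broadleaf", center_x = 1, center_y = 1,
    clear_bole_height = 1, tree_height = 3, half_width_ew = 1,
    half_width_ns = 1, stringsAsFactors = FALSE), plot_bounds = c(0, 2, 0, 2))
  g <- generate_beams(vertical_state(), sc, spacing = 0.2, cull = FALSE,
                      plane_extent = 2)
  expect_equal(nrow(g$origins), 100)            # 2 m x 2 m at 0.2 m spacing
  expect_equal(g$density, 25)
  expect_true(all(g$origins[, 3] == 100))
  # vertical sun: culled footprint stays within the crown box plus margin
  gc <- generate_beams(vertical_state(), sc, spacing = 0.2, plane_extent = 40)
  expect_true(all(gc$origins[, 1] >= -0.5 & gc$origins[, 1] <= 2.5))
  night <- solar_position(site_time(32.076, 166, 0.5))
  expect_error(generate_beams(night, sc), "horizon")
})

test_that("culling does not change the hit set", {
  sc <- rand_small_scene(4)
  mesh <- build_canopy_mesh(sc, mesh_resolution(1.2))
  st <- solar_position(site_time(32.076, 166, 9.5))
  g_cull <- generate_beams(st, sc, spacing = 0.5, plane_extent = 120)
  g_full <- generate_beams(st, sc, spacing = 0.5, plane_extent = 120,
                           cull = FALSE)
  h_cull <- first_hit(g_cull, mesh)
  h_full <- first_hit(g_full, mesh)
  key <- function(h, g) {
    hh <- h[!is.na(h$triangle), ]
    o <- g$origins[hh$beam_index, , drop = FALSE]
    df <- data.frame(ox = o[, 1], oy = o[, 2], tri = hh$triangle, t = hh$t)
    df[order(df$ox, df$oy), ]
  }
  expect_equal(key(h_cull, g_cull), key(h_full, g_full), ignore_attr = TRUE)
})

test_that("ray-triangle intersection matches its contract", {
  h <- ray_triangle_intersect(c(0.5, 0.5, 10), c(0, 0, -1),
                              c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  expect_equal(h$t, 10)
  expect_equal(h$point, c(0.5, 0.5, 0))
  expect_equal(h$incidence_cosine, 1)
  # parallel ray misses
  expect_null(ray_triangle_intersect(c(0, 0, 1), c(1, 0, 0),
                                     c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  # behind the origin
  expect_null(ray_triangle_intersect(c(0.5, 0.5, -1), c(0, 0, -1),
                                     c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  # degenerate facet
  expect_null(ray_triangle_intersect(c(0, 0, 1), c(0, 0, -1),
                                     c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
})

test_that("intersections agree with a barycentric oracle on random pairs", {
  set.seed(99)
  n <- 10000
  mismatches <- 0
  for (i in seq_len(n)) {
    v1 <- runif(3, -1, 1); v2 <- runif(3, -1, 1); v3 <- runif(3, -1, 1)
    o <- runif(3, -2, 2)
    d <- runif(3, -1, 1); d <- d / sqrt(sum(d^2))
    ours <- ray_triangle_intersect(o, d, v1, v2, v3)
    ref <- bary_hit(o, d, v1, v2, v3)
    if (is.null(ours) != is.null(ref)) {
      # edge-grazing hit/miss flips are tolerated below a tiny rate
      mismatches <- mismatches + 1
    } else if (!is.null(ours)) {
      expect_equal(ours$t, ref$t, tolerance = 1e-9)
      expect_equal(ours$point, ref$point, tolerance = 1e-9)
    }
  }
  expect_lte(mismatches, n * 1e-3)
})

test_that("first hits take the smallest ray parameter", {
  # two stacked horizontal facets: the upper one wins for a vertical beam
  verts <- rbind(c(0, 0, 5), c(2, 0, 5), c(0, 2, 5),
                 c(0, 0, 2), c(2, 0, 2), c(0, 2, 2))
  mesh <- structure(list(
    vertices = verts, triangles = rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)),
    tree_id = c("a", "b"), species_class = c("conifer", "conifer"),
    tree_index = c(1L, 2L)), class = "canopy_mesh")
  h <- canopyflux:::first_hits_impl(mesh, c(0.5, 0.5, 10),
                                    matrix(c(0, 0, -1), 1))
  expect_equal(h$triangle, 1L)
  expect_equal(h$z, 5)
  # a beam outside every footprint reaches the ground
  miss <- canopyflux:::first_hits_impl(mesh, c(5, 5, 10),
                                       matrix(c(0, 0, -1), 1))
  expect_true(is.na(miss$triangle))
})

test_that("accelerated and brute-force first hits are identical", {
  for (seed in 1:6) {
    sc <- rand_small_scene(seed)
    mesh <- build_canopy_mesh(sc, mesh_resolution(1.5))
    st <- solar_position(site_time(32.076, 166, 8 + seed))
    g <- generate_beams(st, sc, spacing = 0.6)
    hg <- first_hit(g, mesh, method = "grid")
    hb <- first_hit(g, mesh, method = "brute")
    expect_identical(hg, hb)
  }
})

test_that("first hits agree with a pure-R exhaustive loop", {
  sc <- rand_small_scene(17, n = 2)
  mesh <- build_canopy_mesh(sc, mesh_resolution(2.5))
  st <- solar_position(site_time(32.076, 166, 10))
  g <- generate_beams(st, sc, spacing = 2)
  hits <- first_hit(g, mesh)
  for (i in seq_len(nrow(g$origins))) {
    ref <- r_first_hit(mesh, g$origins[i, ], st$beam_direction)
    if (is.null(ref)) {
      expect_true(is.na(hits$triangle[i]))
    } else {
      expect_equal(hits$triangle[i], ref$triangle)
      expect_equal(hits$t[i], ref$t, tolerance = 1e-9)
    }
  }
})

test_that("hit sets are invariant under uniform scene translation", {
  sc <- rand_small_scene(8)
  mesh <- build_canopy_mesh(sc, mesh_resolution(1.4))
  st <- solar_position(site_time(32.076, 166, 14))
  g <- generate_beams(st, sc, spacing = 0.7)
  h0 <- first_hit(g, mesh)
  shift <- c(13.25, -4.5, 2.75)
  mesh2 <- mesh
  mesh2$vertices <- sweep(mesh$vertices, 2, shift, "+")
  g2 <- g
  g2$origins <- sweep(g$origins, 2, shift, "+")
  h1 <- first_hit(g2, mesh2)
  expect_equal(h0$triangle, h1$triangle)
  expect_equal(h0$t, h1$t, tolerance = 1e-7)
  hit <- !is.na(h0$triangle)
  expect_true(any(hit))
  expect_equal(h1$x[hit] - h0$x[hit], rep(shift[1], sum(hit)),
               tolerance = 1e-7)
})

test_that("reflection is a norm-preserving involution", {
  expect_equal(reflect_direction(c(0, 0, -1), c(0, 0, 1)), c(0, 0, 1))
  expect_equal(reflect_direction(c(1, 0, -1) / sqrt(2), c(0, 0, 1)),
               c(1, 0, 1) / sqrt(2))
  set.seed(31)
  for (i in 1:50) {
    d <- runif(3, -1, 1); d <- d / sqrt(sum(d^2))
    nrm <- runif(3, -1, 1); nrm <- nrm / sqrt(sum(nrm^2))
    r <- reflect_direction(d, nrm)
    expect_equal(sqrt(sum(r^2)), 1, tolerance = 1e-12)
    expect_equal(sum(r * nrm), -sum(d * nrm), tolerance = 1e-12)
    expect_equal(reflect_direction(r, nrm), d, tolerance = 1e-12)
  }
})

test_that("refraction obeys Snell's sine law", {
  # normal incidence passes straight through
  expect_equal(refract_direction(c(0, 0, -1), c(0, 0, 1), e = 0.37),
               c(0, 0, -1))
  # closed-form check at 60 degrees incidence, e = 0.5
  out <- refract_direction(c(sin(pi / 3), 0, -cos(pi / 3)), c(0, 0, 1), e = 0.5)
  expect_equal(out, c(0.4330127, 0, -0.9013878), tolerance = 1e-6)
  # e = 1 is the identity
  set.seed(14)
  for (i in 1:50) {
    nrm <- c(0, 0, 1)
    d <- c(runif(2, -1, 1), -runif(1, 0.1, 1)); d <- d / sqrt(sum(d^2))
    expect_equal(refract_direction(d, nrm, e = 1), d, tolerance = 1e-12)
    e <- runif(1, 0.2, 0.95)
    o <- refract_direction(d, nrm, e)
    expect_equal(sqrt(sum(o^2)), 1, tolerance = 1e-12)
    sin_in <- sqrt(max(0, 1 - sum(d * nrm)^2))
    sin_out <- sqrt(max(0, 1 - sum(o * nrm)^2))
    expect_equal(sin_out, e * sin_in, tolerance = 1e-9)
  }
  expect_error(refract_direction(c(0, 0, 1), c(0, 0, 1)), "incident")
})

test_that("secondary tracing spawns one child per kind per parent", {
  # isolated tree: transmitted rays have no second tree to hit
  sc <- toy_fixture("single_cone")
  mesh <- build_canopy_mesh(sc, mesh_resolution(1))
  st <- noon_state()
  g <- generate_beams(st, sc, spacing = 0.4)
  hits <- first_hit(g, mesh)
  sec <- trace_secondary(hits, mesh, g)
  expect_equal(nrow(sec$transmitted), 0)
  n_parents <- sum(!is.na(hits$triangle))
  expect_lte(nrow(sec$reflected), n_parents)
  # transmitted rays never land on the originating tree; reflected rays
  # never land on the originating facet
  sc2 <- toy_fixture("two_tree_shadow")
  mesh2 <- build_canopy_mesh(sc2, mesh_resolution(1))
  st2 <- solar_position(site_time(32.076, 355, 12))
  g2 <- generate_beams(st2, sc2, spacing = 0.25)
  hits2 <- first_hit(g2, mesh2)
  sec2 <- trace_secondary(hits2, mesh2, g2)
  expect_true(all(sec2$transmitted$tree_id != sec2$transmitted$parent_tree_id))
  expect_true(all(sec2$reflected$triangle != sec2$reflected$parent_triangle))
})

test_that("a shaded rear tree is lit only by transmitted beams", {
  sc <- toy_fixture("two_tree_shadow")
  mesh <- build_canopy_mesh(sc, mesh_resolution(0.8))
  st <- solar_position(site_time(32.076, 355, 12))  # low southern sun
  g <- generate_beams(st, sc, spacing = 0.25)
  hits <- first_hit(g, mesh)
  hh <- hits[!is.na(hits$triangle), ]
  expect_equal(sum(hh$tree_id == "rear"), 0)
  expect_gt(sum(hh$tree_id == "front"), 100)
  sec <- trace_secondary(hits, mesh, g)
  expect_gt(sum(sec$transmitted$tree_id == "rear"), 0)
})

test_that("side-by-side trees exchange reflected beams under low sun", {
  trees <- data.frame(
    tree_id = c("west", "east"), species_class = "conifer",
    center_x = c(8, 16), center_y = 12, clear_bole_height = 2,
    tree_height = 14, half_width_ew = 4, half_width_ns = 4,
    stringsAsFactors = FALSE)
  sc <- plot_scene(trees, plot_bounds = c(0, 24, 0, 24))
  mesh <- build_canopy_mesh(sc, mesh_resolution(0.8))
  st <- solar_position(site_time(32.076, 355, 12))
  g <- generate_beams(st, sc, spacing = 0.25)
  hits <- first_hit(g, mesh)
  sec <- trace_secondary(hits, mesh, g)
  cross <- sec$reflected$tree_id != sec$reflected$parent_tree_id
  expect_gt(sum(cross), 0)
})
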