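#' Scenario specification for synthetic plots
#'
#' Attribute ranges emulate the three study-plot configurations: a pure
#' conifer plot (60 trees), a pure broadleaf plot (60 trees) and a mixed
#' plot (61 trees, 33 conifer / 28 broadleaf), each on a 50 m x 50 m plot.
#' Tree heights, crown widths (east-west and north-south, full widths) and
#' clear bole heights are drawn uniformly within the per-kind ranges;
#' attribute draws are independent (the published ranges already guarantee
#' tree height > clear bole height). Stem centres are placed by
#' minimum-spacing rejection sampling.
#'
#' @param plot_kind `"conifer"`, `"broadleaf"` or `"mixed"`.
#' @param n_trees Number of trees (defaults 60/60/61 by kind).
#' @param n_conifer For mixed plots, the conifer count (default 33).
#' @param plot_size Plot side length in metres (default 50).
#' @param minimum_stem_spacing Minimum distance between stem centres in
#'   metres; defaults 4 (conifer) or 5 (broadleaf, mixed).
#' @param height_range,width_ew_range,width_ns_range,bole_range Optional
#'   overrides of the attribute ranges (metres; widths are full crown
#'   widths).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(plot_kind = c("conifer", "broadleaf", "mixed"),
                          n_trees = NULL, n_conifer = 33, plot_size = 50,
                          minimum_stem_spacing = NULL,
                          height_range = NULL, width_ew_range = NULL,
                          width_ns_range = NULL, bole_range = NULL) {
  plot_kind <- match.arg(plot_kind)
  defaults <- list(
    conifer   = list(n = 60, height = c(15.4, 31.4), ew = c(2.2, 18.2),
                     ns = c(2.5, 17.9), bole = c(4.9, 10.6), spacing = 4),
    broadleaf = list(n = 60, height = c(9.7, 18.2), ew = c(2.8, 12.6),
                     ns = c(3.3, 12.5), bole = c(2.1, 6.3), spacing = 5),
    mixed     = list(n = 61, height = c(10.3, 19.7), ew = c(2.1, 13.3),
                     ns = c(2.0, 14.1), bole = c(2.5, 7.1), spacing = 5))
  d <- defaults[[plot_kind]]
  n_trees <- if (is.null(n_trees)) d$n else as.integer(n_trees)
  if (n_trees < 0) stop("`n_trees` must be >= 0", call. = FALSE)
  spec <- list(
    plot_kind = plot_kind, n_trees = n_trees,
    n_conifer = if (plot_kind == "mixed") as.integer(n_conifer)
                else if (plot_kind == "conifer") n_trees else 0L,
    plot_size = plot_size,
    minimum_stem_spacing = if (is.null(minimum_stem_spacing)) d$spacing
                           else minimum_stem_spacing,
    height_range = if (is.null(height_range)) d$height else height_range,
    width_ew_range = if (is.null(width_ew_range)) d$ew else width_ew_range,
    width_ns_range = if (is.null(width_ns_range)) d$ns else width_ns_range,
    bole_range = if (is.null(bole_range)) d$bole else bole_range)
  if (spec$height_range[1] <= spec$bole_range[2])
    stop("height range must lie entirely above the clear-bole range",
         call. = FALSE)
  structure(spec, class = "scenario_spec")
}

# Minimum-spacing rejection placement of n points in [0, size]^2.
place_stems <- function(n, size, spacing, max_tries = 200L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    x <- stats::runif(1, 0, size); y <- stats::runif(1, 0, size)
    ok <- placed == 0 ||
      min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= spacing^2
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries * n)
        stop(sprintf("cannot place %d stems at %.1f m spacing in a %.0f m plot",
                     n, spacing, size), call. = FALSE)
    }
  }
  cbind(xs, ys)
}

#' Generate a random plot scene matching the study ranges
#'
#' Uniform attribute draws within the spec's ranges and rejection-sampled
#' stem positions. Reproducible: the same seed yields byte-identical tree
#' tables.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed for the draw (default 1).
#' @return A [plot_scene()].
#' @examples
#' generate_plot(scenario_spec("conifer"), seed = 1)
#' @export
generate_plot <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_trees
  bounds <- c(0, spec$plot_size, 0, spec$plot_size)
  if (n == 0) return(plot_scene(NULL, plot_bounds = bounds))
  set.seed(as.integer(seed))
  centers <- place_stems(n, spec$plot_size, spec$minimum_stem_spacing)
  species <- c(rep("conifer", spec$n_conifer),
               rep("broadleaf", n - spec$n_conifer))
  trees <- data.frame(
    tree_id = sprintf("t%03d", seq_len(n)),
    species_class = species,
    center_x = round(centers[, 1], 3),
    center_y = round(centers[, 2], 3),
    clear_bole_height = round(stats::runif(n, spec$bole_range[1], spec$bole_range[2]), 2),
    tree_height = round(stats::runif(n, spec$height_range[1], spec$height_range[2]), 2),
    half_width_ew = round(stats::runif(n, spec$width_ew_range[1], spec$width_ew_range[2]) / 2, 3),
    half_width_ns = round(stats::runif(n, spec$width_ns_range[1], spec$width_ns_range[2]) / 2, 3),
    stringsAsFactors = FALSE)
  plot_scene(trees, plot_bounds = bounds)
}

#' Deterministic toy scenes for testing and worked examples
#'
#' * `single_cone`: one conifer, half-widths 3 m, crown depth 10 m above a
#'   5 m bole, centred on a 20 m plot.
#' * `single_ellipsoid`: one broadleaf of the same dimensions.
#' * `two_tree_shadow`: a tall conifer due south of a short one, so a low
#'   southern sun shades the rear tree.
#' * `flat_slab`: one near-degenerate broadleaf crown (crown depth 1 cm)
#'   approximating a horizontal plane, for conservation checks.
#'
#' @param name Fixture name.
#' @return A [plot_scene()].
#' @export
toy_fixture <- function(name = c("single_cone", "single_ellipsoid",
                                 "two_tree_shadow", "flat_slab")) {
  name <- match.arg(name)
  tree <- function(id, sp, x, y, bole, h, a, b)
    data.frame(tree_id = id, species_class = sp, center_x = x, center_y = y,
               clear_bole_height = bole, tree_height = h,
               half_width_ew = a, half_width_ns = b, stringsAsFactors = FALSE)
  switch(name,
    single_cone = plot_scene(tree("cone1", "conifer", 10, 10, 5, 15, 3, 3),
                             plot_bounds = c(0, 20, 0, 20)),
    single_ellipsoid = plot_scene(tree("ell1", "broadleaf", 10, 10, 5, 15, 3, 3),
                                  plot_bounds = c(0, 20, 0, 20)),
    two_tree_shadow = plot_scene(
      rbind(tree("front", "conifer", 15, 8, 4, 20, 6, 6),
            tree("rear", "conifer", 15, 17, 3, 9, 3, 3)),
      plot_bounds = c(0, 30, 0, 30)),
    flat_slab = plot_scene(tree("slab", "broadleaf", 10, 10, 5, 5.01, 8, 8),
                           plot_bounds = c(0, 20, 0, 20)))
}
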