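#' Tree table column names
#'
#' Required columns of a plot tree table, in canonical order.
#' @keywords internal
tree_table_columns <- function() {
  c("tree_id", "species_class", "center_x", "center_y",
    "clear_bole_height", "tree_height", "half_width_ew", "half_width_ns")
}

validate_tree_rows <- function(df) {
  need <- tree_table_columns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("tree table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  numc <- setdiff(need, c("tree_id", "species_class"))
  for (cn in numc) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in column `%s` at row(s) %s", cn,
                   paste(which(is.na(v)), collapse = ", ")), call. = FALSE)
    df[[cn]] <- v
  }
  df$species_class <- as.character(df$species_class)
  bad_sp <- which(!df$species_class %in% c("conifer", "broadleaf"))
  if (length(bad_sp))
    stop("species_class must be 'conifer' or 'broadleaf'; offending row(s): ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  checks <- list(
    "tree_height <= clear_bole_height" = df$tree_height <= df$clear_bole_height,
    "clear_bole_height < 0"            = df$clear_bole_height < 0,
    "half_width_ew <= 0"               = df$half_width_ew <= 0,
    "half_width_ns <= 0"               = df$half_width_ns <= 0)
  for (msg in names(checks)) {
    bad <- which(checks[[msg]])
    if (length(bad))
      stop(sprintf("invalid tree record (%s) at row(s): %s", msg,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Build a plot scene from a per-tree attribute table
#'
#' Each row becomes one crown primitive: a cone for conifers, a
#' semiellipsoid (upper half-ellipsoid) for broadleaves. The crown occupies
#' `z` from the clear bole height to the tree height; its vertical extent is
#' `c = tree_height - clear_bole_height` and its footprint is the ellipse
#' with semi-axes `half_width_ew` (x, east) and `half_width_ns` (y, north)
#' centred on `(center_x, center_y)`.
#'
#' @param trees A data.frame with the columns named by
#'   `tree_table_columns()`: `tree_id`, `species_class`
#'   (conifer/broadleaf), `center_x`, `center_y`, `clear_bole_height`,
#'   `tree_height`, `half_width_ew`, `half_width_ns` (metres, plot-local,
#'   x east / y north).
#' @param plot_bounds Numeric length-4 vector `c(xmin, xmax, ymin, ymax)`
#'   in metres. Defaults to a 50 m x 50 m plot at the origin.
#' @return An object of class `plot_scene`: list with `trees` (validated
#'   data.frame including the derived `crown_depth` and `shape` columns),
#'   `plot_bounds`, `plot_area`.
#' @export
plot_scene <- function(trees, plot_bounds = c(0, 50, 0, 50)) {
  if (!is.numeric(plot_bounds) || length(plot_bounds) != 4 ||
      plot_bounds[2] <= plot_bounds[1] || plot_bounds[4] <= plot_bounds[3])
    stop("`plot_bounds` must be c(xmin, xmax, ymin, ymax) with positive extent",
         call. = FALSE)
  if (is.null(trees) || nrow(trees) == 0) {
    trees <- data.frame(matrix(nrow = 0, ncol = length(tree_table_columns())))
    names(trees) <- tree_table_columns()
  } else {
    trees <- validate_tree_rows(as.data.frame(trees))
  }
  trees$crown_depth <- trees$tree_height - trees$clear_bole_height
  trees$shape <- ifelse(trees$species_class == "conifer", "cone", "semiellipsoid")
  structure(list(
    trees = trees,
    plot_bounds = as.numeric(plot_bounds),
    plot_area = (plot_bounds[2] - plot_bounds[1]) * (plot_bounds[4] - plot_bounds[3])
  ), class = "plot_scene")
}

#' Read a tree table from delimited text
#'
#' @param path Path to a comma- (or `sep`-) delimited text file with a
#'   header naming the columns of `tree_table_columns()`.
#' @param plot_bounds Passed to [plot_scene()].
#' @param sep Field separator (default comma).
#' @return A [plot_scene()].
#' @export
load_tree_table <- function(path, plot_bounds = c(0, 50, 0, 50), sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  plot_scene(df, plot_bounds = plot_bounds)
}

#' Write a scene's tree table as delimited text
#'
#' Inverse of [load_tree_table()]; only the canonical columns are written.
#' @param scene A [plot_scene()].
#' @param path Output file path.
#' @export
write_tree_table <- function(scene, path) {
  stopifnot(inherits(scene, "plot_scene"))
  utils::write.table(scene$trees[, tree_table_columns(), drop = FALSE], path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Crown surface height above a footprint point
#'
#' Upper-sheet height of one crown at plan position `(x, y)`. Writing
#' `u = ((x - xc)/a)^2 + ((y - yc)/b)^2`, a semiellipsoid has
#' `z = z_bole + c sqrt(1 - u)` and a cone has
#' `z = tree_height - c sqrt(u)`, both defined for `u <= 1`; `NA` is
#' returned outside the footprint.
#'
#' @param tree One row of a scene's `trees` data.frame (list or data.frame
#'   row with the canonical fields).
#' @param x,y Plan coordinates in metres (vectorized).
#' @return Surface height(s) in metres, `NA` outside the footprint.
#' @export
surface_height <- function(tree, x, y) {
  u <- ((x - tree$center_x) / tree$half_width_ew)^2 +
       ((y - tree$center_y) / tree$half_width_ns)^2
  cc <- tree$tree_height - tree$clear_bole_height
  z <- rep(NA_real_, length(u))
  inside <- u <= 1 + 1e-12
  ui <- pmin(u[inside], 1)
  if (identical(tree$species_class, "conifer")) {
    z[inside] <- tree$tree_height - cc * sqrt(ui)
  } else {
    z[inside] <- tree$clear_bole_height + cc * sqrt(1 - ui)
  }
  z
}

#' Total crown volume of a scene
#'
#' Sum of closed-form primitive volumes, `(1/3) pi a b c` per cone and
#' `(2/3) pi a b c` per semiellipsoid, ignoring inter-crown overlap.
#'
#' @param scene A [plot_scene()].
#' @return Volume in cubic metres.
#' @export
scene_volume <- function(scene) {
  stopifnot(inherits(scene, "plot_scene"))
  tr <- scene$trees
  if (nrow(tr) == 0) return(0)
  coef <- ifelse(tr$shape == "cone", 1 / 3, 2 / 3)
  sum(coef * pi * tr$half_width_ew * tr$half_width_ns * tr$crown_depth)
}

#' @export
print.plot_scene <- function(x, ...) {
  tr <- x$trees
  cat(sprintf("<plot_scene> %d trees (%d conifer / %d broadleaf) on %.0f m2\n",
              nrow(tr), sum(tr$species_class == "conifer"),
              sum(tr$species_class == "broadleaf"), x$plot_area))
  if (nrow(tr) > 0)
    cat(sprintf("  heights %.1f-%.1f m, total crown volume %.0f m3\n",
                min(tr$tree_height), max(tr$tree_height), scene_volume(x)))
  invisible(x)
}

#' Summarise a scene's attribute ranges
#'
#' Per-class tree counts, attribute ranges (heights, crown widths, clear
#' bole heights) and total crown volume.
#'
#' @param object A [plot_scene()].
#' @param ... Unused.
#' @export
summary.plot_scene <- function(object, ...) {
  tr <- object$trees
  rng <- function(v) if (length(v)) c(min(v), max(v)) else c(NA_real_, NA_real_)
  out <- list(
    n_trees = nrow(tr),
    n_conifer = sum(tr$species_class == "conifer"),
    n_broadleaf = sum(tr$species_class == "broadleaf"),
    tree_height = rng(tr$tree_height),
    crown_width_ew = rng(2 * tr$half_width_ew),
    crown_width_ns = rng(2 * tr$half_width_ns),
    clear_bole_height = rng(tr$clear_bole_height),
    crown_volume = scene_volume(object),
    plot_area = object$plot_area)
  class(out) <- "summary.plot_scene"
  out
}

#' @export
print.summary.plot_scene <- function(x, ...) {
  cat(sprintf("Trees: %d (%d conifer / %d broadleaf)\n",
              x$n_trees, x$n_conifer, x$n_broadleaf))
  cat(sprintf("Tree height:      %.1f - %.1f m\n", x$tree_height[1], x$tree_height[2]))
  cat(sprintf("Crown width E-W:  %.1f - %.1f m\n", x$crown_width_ew[1], x$crown_width_ew[2]))
  cat(sprintf("Crown width N-S:  %.1f - %.1f m\n", x$crown_width_ns[1], x$crown_width_ns[2]))
  cat(sprintf("Clear bole:       %.1f - %.1f m\n", x$clear_bole_height[1], x$clear_bole_height[2]))
  cat(sprintf("Crown volume:     %.0f m3 over %.0f m2\n", x$crown_volume, x$plot_area))
  invisible(x)
}
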