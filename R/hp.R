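#' Canopy-intercepted radiation from a hemispherical-photo record
#'
#' Below-canopy radiation is reconstructed as
#' `S_below = S_dif * V_f + S_dir * tau_dir`, where `V_f` is the sky-view
#' fraction (weighted sky-pixel ratio over zenith rings) and `tau_dir` the
#' direct transmissivity (overall sky-pixel ratio); the intercepted
#' radiation is `S_above - S_below`, reported as computed (no clamping).
#'
#' @param S_above Above-canopy shortwave irradiance, W/m2.
#' @param S_dif,S_dir Diffuse and direct components of the above-canopy
#'   irradiance, W/m2. May be omitted (`NULL`) if `breakdown` is given.
#' @param V_f Sky view fraction in \[0, 1\].
#' @param tau_dir Direct transmissivity in \[0, 1\].
#' @param breakdown Optional `irradiance` object used to fill `S_above`,
#'   `S_dif`, `S_dir` from the clear-sky model when not supplied.
#' @return Intercepted radiation in W/m2.
#' @export
intercepted_radiation <- function(S_above = NULL, S_dif = NULL, S_dir = NULL,
                                  V_f, tau_dir, breakdown = NULL) {
  if (!is.null(breakdown)) {
    if (is.null(S_above)) S_above <- breakdown$total
    if (is.null(S_dif)) S_dif <- breakdown$diffuse_total
    if (is.null(S_dir)) S_dir <- breakdown$direct
  }
  if (is.null(S_above) || is.null(S_dif) || is.null(S_dir))
    stop("supply S_above, S_dif, S_dir or a `breakdown`", call. = FALSE)
  if (any(V_f < 0 | V_f > 1) || any(tau_dir < 0 | tau_dir > 1))
    stop("`V_f` and `tau_dir` must lie in [0, 1]", call. = FALSE)
  S_above - (S_dif * V_f + S_dir * tau_dir)
}

#' Plot-scale incident flux from hemispherical-photo stations
#'
#' Mean intercepted radiation over the stations times the plot area.
#'
#' @param records Data.frame with columns `V_f`, `tau_dir`, `S_above`,
#'   `S_dif`, `S_dir` (one row per station).
#' @param plot_area Plot area in m2 (default 2500).
#' @param n_stations Required station count (default 10).
#' @return Plot flux in W.
#' @export
plot_flux_from_hp <- function(records, plot_area = 2500, n_stations = 10) {
  records <- as.data.frame(records)
  if (nrow(records) != n_stations)
    stop(sprintf("expected %d station records, got %d", n_stations,
                 nrow(records)), call. = FALSE)
  s <- intercepted_radiation(records$S_above, records$S_dif, records$S_dir,
                             V_f = records$V_f, tau_dir = records$tau_dir)
  sum(s) * plot_area / n_stations
}

#' Plot-scale incident flux from paired pyranometer readings
#'
#' Mean above/below irradiance difference over the stations times the plot
#' area.
#'
#' @param records Data.frame with columns `I_above`, `I_below` (W/m2).
#' @inheritParams plot_flux_from_hp
#' @return Plot flux in W.
#' @export
plot_flux_from_pyranometer <- function(records, plot_area = 2500,
                                       n_stations = 10) {
  records <- as.data.frame(records)
  if (nrow(records) != n_stations)
    stop(sprintf("expected %d station records, got %d", n_stations,
                 nrow(records)), call. = FALSE)
  if (any(records$I_below < 0) || any(records$I_above < records$I_below))
    stop("need I_above >= I_below >= 0 for every station", call. = FALSE)
  sum(records$I_above - records$I_below) * plot_area / n_stations
}

#' Determination coefficient between two method series
#'
#' Squared Pearson correlation of the paired values (not
#' regression-through-origin).
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @param digits Rounding applied for display-style comparison; `NULL`
#'   (default) returns the unrounded value.
#' @return R-squared, unitless in \[0, 1\].
#' @export
determination_coefficient <- function(x, y, digits = NULL) {
  if (length(x) != length(y) || length(x) < 3)
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: determination coefficient undefined", call. = FALSE)
  r2 <- stats::cor(x, y)^2
  if (is.null(digits)) r2 else round(r2, digits)
}

#' Cross-method plot fluxes used for validation
#'
#' The nine plot-by-date radiant-flux values (kW) reported by the ray
#' tracing method, the hemispherical-photo HPEval workflow and the
#' pyranometer survey for three plots at noon on three summer dates;
#' shipped as a plain-text fixture for the cross-method determination
#' coefficients.
#'
#' @return Data.frame with columns `plot`, `date`, `ray_tracing`, `hpeval`,
#'   `pyranometer` (kW).
#' @export
crossmethod_fluxes <- function() {
  path <- system.file("extdata", "crossmethod_flux_kw.csv",
                      package = "canopyflux")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
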