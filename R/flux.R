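#' Optical properties of the two species classes
#'
#' Shortwave (0.3-3 um) crown optics: per-class reflectance and
#' transmittance plus the refractive ratio used for transmitted beams.
#' Defaults are the field values for conifer and broadleaf canopies.
#'
#' @param reflectance Named numeric, fraction reflected per class
#'   (defaults conifer 0.25, broadleaf 0.17).
#' @param transmittance Named numeric, fraction transmitted per class
#'   (defaults conifer 0.15, broadleaf 0.20).
#' @param refraction_index Refractive ratio `e` of the crown medium
#'   (default 0.5).
#' @param attribute_to Whether reflectance/transmittance are taken from the
#'   species of the crown that reflected or was penetrated (`"source"`,
#'   default) or of the facet finally hit (`"receiver"`).
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(reflectance = c(conifer = 0.25, broadleaf = 0.17),
                               transmittance = c(conifer = 0.15, broadleaf = 0.20),
                               refraction_index = 0.5,
                               attribute_to = c("source", "receiver")) {
  attribute_to <- match.arg(attribute_to)
  for (nm in c("conifer", "broadleaf")) {
    if (is.na(reflectance[nm]) || is.na(transmittance[nm]))
      stop("reflectance and transmittance must name conifer and broadleaf",
           call. = FALSE)
    if (reflectance[nm] < 0 || transmittance[nm] < 0 ||
        reflectance[nm] + transmittance[nm] > 1)
      stop(sprintf("class %s: need rho >= 0, tau >= 0, rho + tau <= 1", nm),
           call. = FALSE)
  }
  if (refraction_index <= 0 || refraction_index > 1)
    stop("`refraction_index` must be in (0, 1]", call. = FALSE)
  structure(list(reflectance = reflectance, transmittance = transmittance,
                 refraction_index = refraction_index,
                 attribute_to = attribute_to),
            class = "optical_properties")
}

# Sum per-facet contributions; returns named list(per_facet df, total).
facet_sums <- function(triangle, value) {
  if (length(triangle) == 0)
    return(list(per_facet = data.frame(triangle = integer(0), flux_W = numeric(0)),
                total = 0))
  s <- rowsum(value, group = triangle)
  list(per_facet = data.frame(triangle = as.integer(rownames(s)),
                              flux_W = as.numeric(s[, 1])),
       total = sum(value))
}

#' Incident radiant flux from first-pass hits
#'
#' Each intercepted beam contributes `(I_total / density) * cos(theta)`
#' watts to the facet it first hits, `theta` being the beam/facet-normal
#' angle folded to \[0, 90) degrees.
#'
#' @param hits First-pass hit table from [first_hit()].
#' @param irradiance An `irradiance` object (for `I_total`).
#' @param beams The [generate_beams()] grid (for the beam density).
#' @return List with `per_facet` (triangle, flux_W) and `total` (W).
#' @export
incident_flux <- function(hits, irradiance, beams) {
  hh <- hits[!is.na(hits$triangle), , drop = FALSE]
  power <- irradiance$total / beams$density
  facet_sums(hh$triangle, power * hh$incidence_cosine)
}

#' Reflected radiant flux from traced secondary hits
#'
#' Each reflected child ray that re-collides contributes
#' `(I_total / density) * cos(theta) * rho` watts to the facet it hits,
#' with `rho` the class reflectance attributed per
#' `optics$attribute_to`.
#'
#' @param secondary_hits `reflected` table from [trace_secondary()].
#' @param irradiance,beams As in [incident_flux()].
#' @param optics An [optical_properties()] object.
#' @param mesh The canopy mesh (to resolve receiver species).
#' @return List with `per_facet` and `total` (W).
#' @export
reflected_flux <- function(secondary_hits, irradiance, beams, optics, mesh) {
  hh <- secondary_hits
  power <- irradiance$total / beams$density
  species <- if (optics$attribute_to == "source") hh$parent_species
             else mesh$species_class[hh$triangle]
  rho <- unname(optics$reflectance[species])
  facet_sums(hh$triangle, power * hh$incidence_cosine * rho)
}

#' Transmitted radiant flux from traced secondary hits
#'
#' As [reflected_flux()] but with the class transmittance of the
#' penetrated crown.
#'
#' @inheritParams reflected_flux
#' @param secondary_hits `transmitted` table from [trace_secondary()].
#' @export
transmitted_flux <- function(secondary_hits, irradiance, beams, optics, mesh) {
  hh <- secondary_hits
  power <- irradiance$total / beams$density
  species <- if (optics$attribute_to == "source") hh$parent_species
             else mesh$species_class[hh$triangle]
  tau <- unname(optics$transmittance[species])
  facet_sums(hh$triangle, power * hh$incidence_cosine * tau)
}

zero_flux_report <- function(meta, n_beams = 0) {
  structure(list(
    per_facet = data.frame(triangle = integer(0), tree_id = character(0),
                           kind = character(0), flux_W = numeric(0)),
    E_incident = 0, E_reflect = 0, E_trans = 0,
    counts = c(num_beams = n_beams, num_incident = 0,
               num_reflected_hits = 0, num_transmitted_hits = 0,
               num_ground = n_beams),
    per_beam_power = 0, meta = meta), class = "flux_report")
}

#' Simulate the radiant flux of a plot at one instant
#'
#' Full pipeline: solar position and clear-sky irradiance, crown surface
#' meshing, beam generation, first-hit resolution, single-bounce reflected
#' and refracted transmitted tracing, and per-facet flux aggregation.
#' Deterministic given its inputs. Returns a zeroed report when the Sun is
#' at or below the horizon.
#'
#' @param scene A [plot_scene()].
#' @param st A [site_time()].
#' @param atmos An [atmosphere()].
#' @param optics An [optical_properties()].
#' @param beam_spacing Beam lattice spacing in metres (default 0.2).
#' @param resolution A [mesh_resolution()] (default 1.36 m vertex spacing).
#' @param mesh Optional prebuilt [build_canopy_mesh()] to reuse across
#'   instants.
#' @param source_height,plane_extent Passed to [generate_beams()].
#' @param method First-hit method, `"grid"` or `"brute"`.
#' @return An object of class `flux_report`: per-facet flux table, plot
#'   totals `E_incident`, `E_reflect`, `E_trans` (W), beam bookkeeping
#'   `counts`, `per_beam_power` (W), and `meta` (solar state, irradiance,
#'   parameters).
#' @export
simulate_instant <- function(scene, st, atmos = atmosphere(),
                             optics = optical_properties(),
                             beam_spacing = 0.2,
                             resolution = mesh_resolution(),
                             mesh = NULL, source_height = 100,
                             plane_extent = 800,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  irr <- total_irradiance(st, atmos)
  state <- irr$solar_state
  meta <- list(site_time = st, solar_state = state, irradiance = irr,
               beam_spacing = beam_spacing, resolution = resolution,
               optics = optics)
  if (state$altitude <= 0) return(zero_flux_report(meta))
  if (nrow(scene$trees) == 0) {
    beams <- generate_beams(state, scene, spacing = beam_spacing,
                            source_height = source_height,
                            plane_extent = plane_extent, cull = FALSE)
    return(zero_flux_report(meta, n_beams = nrow(beams$origins)))
  }
  if (is.null(mesh)) mesh <- build_canopy_mesh(scene, resolution)
  beams <- generate_beams(state, scene, spacing = beam_spacing,
                          source_height = source_height,
                          plane_extent = plane_extent)
  hits <- first_hit(beams, mesh, method = method)
  sec <- trace_secondary(hits, mesh, beams, e = optics$refraction_index,
                         method = method)
  inc <- incident_flux(hits, irr, beams)
  ref <- reflected_flux(sec$reflected, irr, beams, optics, mesh)
  tra <- transmitted_flux(sec$transmitted, irr, beams, optics, mesh)
  bind_kind <- function(fs, kind) {
    if (nrow(fs$per_facet) == 0)
      return(data.frame(triangle = integer(0), tree_id = character(0),
                        kind = character(0), flux_W = numeric(0)))
    data.frame(triangle = fs$per_facet$triangle,
               tree_id = mesh$tree_id[fs$per_facet$triangle],
               kind = kind, flux_W = fs$per_facet$flux_W,
               stringsAsFactors = FALSE)
  }
  n_inc <- sum(!is.na(hits$triangle))
  structure(list(
    per_facet = rbind(bind_kind(inc, "incident"), bind_kind(ref, "reflected"),
                      bind_kind(tra, "transmitted")),
    E_incident = inc$total, E_reflect = ref$total, E_trans = tra$total,
    counts = c(num_beams = nrow(beams$origins), num_incident = n_inc,
               num_reflected_hits = nrow(sec$reflected),
               num_transmitted_hits = nrow(sec$transmitted),
               num_ground = nrow(beams$origins) - n_inc),
    per_beam_power = irr$total / beams$density,
    meta = meta, mesh = mesh), class = "flux_report")
}

#' @export
print.flux_report <- function(x, ...) {
  st <- x$meta$solar_state
  cat(sprintf("<flux_report> day %d, %05.2f h solar time | altitude %.2f deg, I_total %.2f W/m2\n",
              x$meta$site_time$day_of_year, x$meta$site_time$solar_time,
              st$altitude, x$meta$irradiance$total))
  cat(sprintf("  E_incident %.2f kW | E_reflect %.2f kW | E_trans %.2f kW\n",
              x$E_incident / 1000, x$E_reflect / 1000, x$E_trans / 1000))
  cat(sprintf("  beams %d, intercepted %d, ground %d; reflected hits %d, transmitted hits %d\n",
              x$counts["num_beams"], x$counts["num_incident"],
              x$counts["num_ground"], x$counts["num_reflected_hits"],
              x$counts["num_transmitted_hits"]))
  invisible(x)
}

#' Simulate a date-by-hour schedule of flux reports
#'
#' Runs [simulate_instant()] for every (day, hour) combination, reusing one
#' canopy mesh.
#'
#' @param scene A [plot_scene()].
#' @param latitude Latitude in degrees north.
#' @param days Integer vector of days of year.
#' @param hours Numeric vector of local solar hours.
#' @param ... Passed to [simulate_instant()].
#' @return A list of `flux_report`s with class `flux_series`; see
#'   [as.data.frame.flux_series()].
#' @export
simulate_series <- function(scene, latitude, days, hours, ...) {
  if (length(days) == 0 || length(hours) == 0)
    stop("`days` and `hours` must be nonempty", call. = FALSE)
  dots <- list(...)
  mesh <- dots$mesh
  if (is.null(mesh) && nrow(scene$trees) > 0) {
    res <- if (!is.null(dots$resolution)) dots$resolution else mesh_resolution()
    mesh <- build_canopy_mesh(scene, res)
  }
  dots$mesh <- mesh
  out <- list()
  for (d in days) for (h in hours) {
    out[[length(out) + 1]] <-
      do.call(simulate_instant,
              c(list(scene = scene, st = site_time(latitude, d, h)), dots))
  }
  structure(out, class = "flux_series")
}

#' Flatten a flux series into a data.frame of plot totals
#'
#' @param x A [simulate_series()] result.
#' @param ... Unused.
#' @return Data.frame with one row per instant: `day_of_year`, `hour`,
#'   `altitude`, `I_total`, `E_incident_kW`, `E_reflect_kW`, `E_trans_kW`
#'   and the bookkeeping counts.
#' @export
as.data.frame.flux_series <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(day_of_year = r$meta$site_time$day_of_year,
               hour = r$meta$site_time$solar_time,
               altitude = r$meta$solar_state$altitude,
               I_total = r$meta$irradiance$total,
               E_incident_kW = r$E_incident / 1000,
               E_reflect_kW = r$E_reflect / 1000,
               E_trans_kW = r$E_trans / 1000,
               num_beams = unname(r$counts["num_beams"]),
               num_incident = unname(r$counts["num_incident"]),
               num_ground = unname(r$counts["num_ground"]))
  }))
}

#' Write a flux report as structured JSON
#'
#' Plot totals in W and kW, solar state, irradiance breakdown and beam
#' bookkeeping; per-facet fluxes can be exported with [write_ply()] or
#' [write_facet_fluxes()].
#'
#' @param report A `flux_report`.
#' @param path Output path.
#' @export
write_flux_report <- function(report, path) {
  st <- report$meta$solar_state
  irr <- report$meta$irradiance
  obj <- list(
    day_of_year = report$meta$site_time$day_of_year,
    solar_time = report$meta$site_time$solar_time,
    solar = list(declination = st$declination, hour_angle = st$hour_angle,
                 altitude = st$altitude, azimuth = st$azimuth),
    irradiance_W_m2 = list(direct = irr$direct,
                           diffuse_rayleigh = irr$diffuse_rayleigh,
                           diffuse_aerosol = irr$diffuse_aerosol,
                           diffuse_multireflect = irr$diffuse_multireflect,
                           total = irr$total),
    flux_W = list(incident = report$E_incident, reflected = report$E_reflect,
                  transmitted = report$E_trans),
    flux_kW = list(incident = round(report$E_incident / 1000, 2),
                   reflected = round(report$E_reflect / 1000, 2),
                   transmitted = round(report$E_trans / 1000, 2)),
    per_beam_power_W = report$per_beam_power,
    counts = as.list(report$counts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-facet fluxes as delimited text
#'
#' @param report A `flux_report`.
#' @param path Output path (CSV).
#' @export
write_facet_fluxes <- function(report, path) {
  utils::write.csv(report$per_facet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
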