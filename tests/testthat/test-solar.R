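test_that("declination follows the seasonal cycle", {
  # near-zero at the March equinox, extremes near the solstices
  expect_lt(abs(declination(80)), 1)
  # frozen values of the truncated Fourier series, evaluated independently
  expect_equal(declination(166), 23.28593, tolerance = 1e-5)
  expect_equal(declination(355), -23.41989, tolerance = 1e-5)
  expect_true(all(abs(declination(1:365)) < 23.5))
  # continuity: no day-to-day jump above half a degree
  expect_lt(max(abs(diff(declination(1:365)))), 0.5)
  expect_error(declination(0), "day_of_year")
  expect_error(declination(400), "day_of_year")
})

test_that("solar altitude follows the spherical formula", {
  # overhead sun when latitude equals declination at solar noon
  d166 <- declination(166)
  expect_equal(solar_position(site_time(d166, 166, 12))$altitude, 90,
               tolerance = 1e-8)
  # study-site June-15 noon peak altitude
  expect_lt(abs(solar_position(site_time(32.076, 166, 12))$altitude - 81.21),
            0.3)
  # direct formula evaluation at an off-noon hour (independent arithmetic)
  st <- site_time(45, 123, 13)
  d <- declination(123) * pi / 180
  expected <- asin(sin(pi / 4) * sin(d) + cos(pi / 4) * cos(d) * cos(15 * pi / 180))
  expect_equal(solar_position(st)$altitude, expected * 180 / pi,
               tolerance = 1e-10)
  expect_equal(solar_position(st)$hour_angle, 15)
})

test_that("altitude is symmetric about solar noon", {
  for (lat in c(0, 32.076, 55, -35)) for (day in c(15, 166, 300)) {
    for (h in c(1, 2.5, 4, 5.5)) {
      am <- solar_position(site_time(lat, day, 12 - h))$altitude
      pm <- solar_position(site_time(lat, day, 12 + h))$altitude
      expect_equal(am, pm, tolerance = 1e-10)
    }
  }
})

test_that("azimuth convention is clockwise from north with noon at 180", {
  # northern mid-latitude, declination below latitude: noon azimuth exact
  expect_identical(solar_position(site_time(32.076, 166, 12))$azimuth, 180)
  expect_identical(solar_position(site_time(45, 300, 12))$azimuth, 180)
  # morning sun east of the meridian, afternoon west
  expect_lt(solar_position(site_time(32.076, 166, 9))$azimuth, 180)
  expect_gt(solar_position(site_time(32.076, 166, 15))$azimuth, 180)
  morning <- solar_position(site_time(32.076, 196, 10))$azimuth
  afternoon <- solar_position(site_time(32.076, 196, 14))$azimuth
  expect_equal(morning + afternoon, 360, tolerance = 1e-8)
})

test_that("beam direction is a unit vector pointing downward from the Sun", {
  for (h in c(8, 10, 12, 15.5)) {
    s <- solar_position(site_time(32.076, 166, h))
    b <- s$beam_direction
    expect_equal(sqrt(sum(b^2)), 1, tolerance = 1e-12)
    expect_lt(b[3], 0)
    a <- s$altitude * pi / 180; z <- s$azimuth * pi / 180
    expect_equal(b, -c(cos(a) * sin(z), cos(a) * cos(z), sin(a)),
                 tolerance = 1e-10)
  }
  # below the horizon the vertical component flips upward
  night <- solar_position(site_time(32.076, 166, 0.5))
  expect_lt(night$altitude, 0)
})

test_that("air mass is at least 1 above the horizon and NA below", {
  expect_equal(air_mass(90), 1, tolerance = 1e-3)
  expect_true(all(air_mass(c(5, 20, 45, 80)) >= 1))
  expect_true(is.na(air_mass(-3)))
  expect_gt(air_mass(5), air_mass(45))
})

test_that("direct irradiance is the printed product formula", {
  st <- site_time(32.076, 166, 12)
  state <- solar_position(st)
  atm <- atmosphere()
  # identity transmittances leave the extraterrestrial shortwave budget
  taus1 <- list(tau_r = 1, tau_o = 1, tau_g = 1, tau_w = 1, tau_a = 1, m_a = 1)
  expect_equal(direct_irradiance(state, atm, taus = taus1),
               0.9751 * 1367 * eccentricity_factor(166) *
                 sin(state$altitude * pi / 180), tolerance = 1e-12)
  # arbitrary transmittances: arithmetic oracle written out in full
  taus <- list(tau_r = 0.9, tau_o = 0.98, tau_g = 0.99, tau_w = 0.95,
               tau_a = 0.88, m_a = 1.2)
  expect_equal(direct_irradiance(state, atm, taus = taus),
               0.9751 * 1367 * eccentricity_factor(166) * 0.9 * 0.98 * 0.99 *
                 0.95 * 0.88 * sin(state$altitude * pi / 180),
               tolerance = 1e-12)
  # night
  night <- solar_position(site_time(32.076, 166, 0.5))
  expect_identical(direct_irradiance(night, atm), 0)
  taus_bad <- list(tau_r = -0.1, tau_o = 1, tau_g = 1, tau_w = 1, tau_a = 1,
                   m_a = 1)
  expect_error(direct_irradiance(state, atm, taus = taus_bad), "negative")
})

test_that("diffuse components follow the aerosol closure formulas", {
  st <- site_time(32.076, 166, 12)
  state <- solar_position(st)
  atm <- atmosphere()
  base_taus <- band_transmittances(state$altitude, atm)
  # frozen arithmetic oracle for tau_aa at omega_o 0.9, m 1.5, tau_a 0.85
  taus <- base_taus; taus$tau_a <- 0.85; taus$m_a <- 1.5
  dif <- diffuse_irradiance(state, atm, direct = 500, taus = taus)
  expect_equal(dif$tau_aa, 1 - 0.1 * (1 - 1.5 + 1.5^1.02) * 0.15,
               tolerance = 1e-12)
  expect_equal(dif$tau_aa, 0.9848165, tolerance = 1e-6)
  expect_equal(dif$tau_as, 0.85 / dif$tau_aa, tolerance = 1e-12)
  # tau_a = 1 limit: no aerosol scattering, sky albedo floor
  taus$tau_a <- 1
  dif1 <- diffuse_irradiance(state, atm, direct = 500, taus = taus)
  expect_equal(dif1$tau_aa, 1, tolerance = 1e-12)
  expect_equal(dif1$tau_as, 1, tolerance = 1e-12)
  expect_equal(dif1$rho_a, 0.0685, tolerance = 1e-12)
  expect_equal(dif1$diffuse_aerosol, 0, tolerance = 1e-9)
  # zero ground albedo kills the multiple-reflection term
  atm0 <- atmosphere(ground_albedo = 0)
  dif0 <- diffuse_irradiance(state, atm0, direct = 500)
  expect_identical(dif0$diffuse_multireflect, 0)
  # multiple-reflection term grows monotonically with ground albedo
  dm <- vapply(c(0, 0.2, 0.5, 0.8), function(rg)
    diffuse_irradiance(state, atmosphere(ground_albedo = rg),
                       direct = 500)$diffuse_multireflect, numeric(1))
  expect_true(all(diff(dm) > 0))
})

test_that("total irradiance conserves its component sum", {
  set.seed(7)
  for (i in 1:12) {
    st <- site_time(runif(1, 5, 60), sample(1:365, 1), runif(1, 6, 18))
    atm <- atmosphere(ozone_cm = runif(1, 0.2, 0.5),
                      water_cm = runif(1, 0.5, 6),
                      visibility_km = runif(1, 5, 60),
                      ground_albedo = runif(1, 0, 0.6))
    irr <- total_irradiance(st, atm)
    expect_equal(irr$total, irr$direct + irr$diffuse_total, tolerance = 1e-12)
    expect_equal(irr$diffuse_total,
                 irr$diffuse_rayleigh + irr$diffuse_aerosol +
                   irr$diffuse_multireflect, tolerance = 1e-12)
    expect_true(all(unlist(irr[c("direct", "diffuse_rayleigh",
                                 "diffuse_aerosol",
                                 "diffuse_multireflect")]) >= 0))
  }
  # night zeroes every component
  night <- total_irradiance(site_time(32.076, 166, 2))
  expect_identical(night$total, 0)
  expect_identical(night$direct, 0)
})

test_that("irradiance schedule is unimodal per date and summer-dominant", {
  tab <- irradiance_table(32.076, days = c(74, 166, 288), hours = 8:17)
  one <- irradiance_table(32.076, days = 166, hours = 12)
  expect_equal(nrow(one), 1)
  expect_equal(one$total, total_irradiance(site_time(32.076, 166, 12))$total)
  for (d in unique(tab$day_of_year)) {
    tot <- tab$total[tab$day_of_year == d]
    peak <- which.max(tot)
    expect_true(all(diff(tot[seq_len(peak)]) >= 0))
    expect_true(all(diff(tot[seq(peak, length(tot))]) <= 0))
  }
  june <- tab$total[tab$day_of_year == 166]
  oct <- tab$total[tab$day_of_year == 288]
  expect_true(all(june >= oct))
})

test_that("site_time rejects out-of-range inputs", {
  expect_error(site_time(100, 166, 12), "latitude")
  expect_error(site_time(32, 0, 12), "day_of_year")
  expect_error(site_time(32, 166.5, 12), "day_of_year")
  expect_error(site_time(32, 166, 24), "solar_time")
})
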