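#' Synthetic canopy scenario
#'
#' Bundles every knob of the synthetic data generators: canopy geometry,
#' diurnal microclimate parameters, species-level stomatal and
#' boundary-layer truths, measurement-noise levels and the PAR-corruption
#' process. The defaults describe a humid montane-forest canopy: a mean
#' daytime canopy-top air temperature of 15 degrees C against a 12.4 degree
#' night, canopy-top PAR peaking near 2000 umol m^-2 s^-1 with
#' Beer-law attenuation into the understorey and multiplicative cloud
#' flicker, relative humidity tightly and negatively coupled to air
#' temperature, and low lognormal within-canopy wind (about 0.26 m/s inside
#' the canopy, 1.0 m/s above it).
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   scenario, and per-stage substreams are derived from this seed.
#' @param n_days Number of simulated days.
#' @param cadence_s Record cadence in seconds (the field cadence of such
#'   loggers is 10 s; the default 60 s keeps a 10-day scenario small).
#' @param heights Sensor heights (m above ground).
#' @param species List of species specifications, see
#'   [default_species_specs()].
#' @param par_max Clear-sky canopy-top PAR maximum (umol m^-2 s^-1).
#' @param k_par Beer-law extinction coefficient for PAR (per m of canopy
#'   depth below `z_canopy`).
#' @param z_canopy Height (m) of the top of the leafy canopy; PAR is
#'   unattenuated at and above it, so exposed top leaves see full sun.
#' @param ta_day_mean,ta_night_mean Target daytime/night mean canopy-top
#'   air temperature (degrees C); the diurnal amplitude is derived so the
#'   configured daytime mean is attained in expectation.
#' @param ta_noise_sd Air-temperature measurement noise SD (degrees C).
#' @param ta_damp_floor Fraction of the diurnal amplitude retained at the
#'   ground; amplitude scales linearly up to 1 at the top sensor.
#' @param h_intercept,h_slope Linear coupling of relative humidity
#'   (proportion) to air temperature (per degree C).
#' @param h_noise_sd Relative-humidity noise SD (proportion).
#' @param u_canopy_mean,u_top_mean Mean wind speed (m/s) within the canopy
#'   (heights up to 11.5 m) and at the top sensor.
#' @param u_sdlog Lognormal sdlog of wind speed.
#' @param cloud_flicker List with `prob` (probability a flicker block is
#'   cloudy), `depth` (maximum fractional PAR reduction under cloud) and
#'   `block_s` (block duration, s).
#' @param dT_noise_sd Measurement noise SD of observed leaf-to-air
#'   temperature difference (degrees C). Individually calibrated two-junction
#'   differential thermocouples resolve a few hundredths of a degree; the
#'   default is also small relative to the within-window signal, so the
#'   window filter responds to radiation mismatch rather than to
#'   measurement noise.
#' @param gs_spot_sd Residual SD of spot stomatal-conductance measurements
#'   (mmol m^-2 s^-1).
#' @param leaf_offset_sd SD of leaf-level random intercepts of the g_s-D
#'   relationship (mmol m^-2 s^-1).
#' @param spots_per_leaf Spot measurements generated per leaf.
#' @param par_corruption_rate Fraction of daytime 20-minute windows in which
#'   the PAR actually driving the leaf differs from the recorded PAR
#'   (sensor/leaf-surface mismatch).
#' @param corruption_factors Multiplicative factors a corrupted window's
#'   leaf-surface PAR is drawn from (straddling over- and under-estimation).
#' @param g_min Floor on true stomatal conductance (mmol m^-2 s^-1).
#' @param sunrise,sunset Hours of day bounding the solar cycle.
#' @param start Start timestamp of the simulation (POSIXct or string).
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, n_days = 10, cadence_s = 60,
                               heights = c(2, 8, 12.5, 18, 25),
                               species = default_species_specs(),
                               par_max = 2000, k_par = 0.25, z_canopy = 18,
                               ta_day_mean = 15.0, ta_night_mean = 12.4,
                               ta_noise_sd = 0.15, ta_damp_floor = 0.6,
                               h_intercept = 2.0, h_slope = -0.082,
                               h_noise_sd = 0.012,
                               u_canopy_mean = 0.26, u_top_mean = 1.0,
                               u_sdlog = 0.5,
                               cloud_flicker = list(prob = 0.3, depth = 0.6,
                                                    block_s = 120),
                               dT_noise_sd = 0.02,
                               gs_spot_sd = 40, leaf_offset_sd = 30,
                               spots_per_leaf = 20,
                               par_corruption_rate = 0,
                               corruption_factors = c(0.3, 2),
                               g_min = 5,
                               sunrise = 6, sunset = 18,
                               start = "2016-10-01") {
  stopifnot(par_corruption_rate >= 0, par_corruption_rate <= 1,
            cloud_flicker$prob >= 0, cloud_flicker$prob <= 1,
            dT_noise_sd >= 0, gs_spot_sd >= 0, leaf_offset_sd >= 0,
            n_days >= 1, cadence_s > 0, length(heights) >= 2)
  scn <- list(seed = as.integer(seed), n_days = n_days,
              cadence_s = cadence_s, heights = sort(heights),
              species = species, par_max = par_max, k_par = k_par,
              z_canopy = z_canopy,
              ta_day_mean = ta_day_mean, ta_night_mean = ta_night_mean,
              ta_noise_sd = ta_noise_sd, ta_damp_floor = ta_damp_floor,
              h_intercept = h_intercept, h_slope = h_slope,
              h_noise_sd = h_noise_sd,
              u_canopy_mean = u_canopy_mean, u_top_mean = u_top_mean,
              u_sdlog = u_sdlog, cloud_flicker = cloud_flicker,
              dT_noise_sd = dT_noise_sd, gs_spot_sd = gs_spot_sd,
              leaf_offset_sd = leaf_offset_sd,
              spots_per_leaf = spots_per_leaf,
              par_corruption_rate = par_corruption_rate,
              corruption_factors = corruption_factors, g_min = g_min,
              sunrise = sunrise, sunset = sunset,
              start = as.POSIXct(start, tz = "UTC"))
  class(scn) <- "synthetic_scenario"
  scn
}

#' Default synthetic species specifications
#'
#' Three species spanning the canopy: `sp_A`, a mesophyll-leaved overstorey
#' species (g_s = 325.1 - 68.8 D, boundary coefficient 0.0171); `sp_B`, a
#' large-leaved (platyphyll) overstorey species with a high intercept and
#' steep negative slope (g_s = 401.6 - 189.8 D, boundary coefficient
#' 0.0215); and `sp_C`, a small-leaved, low-conductance understorey species
#' (g_s = 185.4 - 212.7 D, textbook boundary coefficient 0.0105).
#'
#' @return Named list of per-species specs, each with `name`,
#'   `gs_intercept` (mmol m^-2 s^-1), `gs_slope` (mmol m^-2 s^-1 kPa^-1),
#'   `bl_a` (boundary-layer coefficient, m s^-1/2), `width_m`,
#'   `lma_g_m2`, `ldmc`, `n_leaves`, `leaf_heights` (range, m).
#' @export
default_species_specs <- function() {
  list(
    sp_A = list(name = "sp_A", gs_intercept = 325.1, gs_slope = -68.8,
                bl_a = 0.0171, width_m = 0.08, lma_g_m2 = 90, ldmc = 0.45,
                n_leaves = 10, leaf_heights = c(12, 18)),
    sp_B = list(name = "sp_B", gs_intercept = 401.6, gs_slope = -189.8,
                bl_a = 0.0215, width_m = 0.15, lma_g_m2 = 120, ldmc = 0.35,
                n_leaves = 10, leaf_heights = c(8, 14)),
    sp_C = list(name = "sp_C", gs_intercept = 185.4, gs_slope = -212.7,
                bl_a = 0.0105, width_m = 0.05, lma_g_m2 = 85, ldmc = 0.25,
                n_leaves = 10, leaf_heights = c(2, 6))
  )
}

# Per-stage RNG substreams, all derived from the scenario's single seed.
stage_seed <- function(scn, stage) {
  offs <- c(microclimate = 11L, traits = 23L, spots = 37L, leaf = 53L)
  (scn$seed + offs[[stage]]) %% .Machine$integer.max
}

# Solar elevation proxy in [0, 1]; zero at night.
solar_shape <- function(hour, sunrise, sunset) {
  s <- sin(pi * (hour - sunrise) / (sunset - sunrise))
  ifelse(hour >= sunrise & hour <= sunset, pmax(0, s), 0)
}

# Canopy-top PAR for a time grid, including cloud flicker (random), given
# an already-seeded RNG state.
par_top_series <- function(scn, tsec) {
  hour <- (tsec %% 86400) / 3600
  elev <- solar_shape(hour, scn$sunrise, scn$sunset)
  block <- floor(tsec / scn$cloud_flicker$block_s)
  ublock <- unique(block)
  cloudy <- stats::runif(length(ublock)) < scn$cloud_flicker$prob
  mult <- ifelse(cloudy,
                 stats::runif(length(ublock), 1 - scn$cloud_flicker$depth,
                              1 - scn$cloud_flicker$depth / 2),
                 1)
  scn$par_max * elev^1.2 * mult[match(block, ublock)]
}

#' Generate a synthetic canopy microclimate stream
#'
#' Produces a long microclimate table at the scenario's heights and cadence:
#' diurnal sinusoidal PAR with multiplicative cloud flicker and Beer-law
#' vertical attenuation, a diurnal air-temperature cycle whose amplitude is
#' damped with depth (derived so the configured daytime canopy-top mean is
#' attained in expectation), relative humidity linearly and negatively
#' coupled to air temperature plus noise, and lognormal wind speed per
#' height. Identical scenarios yield identical output.
#'
#' @param scn A [synthetic_scenario()].
#' @return Data frame with columns `time`, `height`, `PAR`, `T_A`, `h`, `U`,
#'   `D`, `h_source`.
#' @export
gen_microclimate <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  withr::with_seed(stage_seed(scn, "microclimate"), {
    tsec <- seq(0, scn$n_days * 86400 - scn$cadence_s, by = scn$cadence_s)
    nt <- length(tsec)
    hour <- (tsec %% 86400) / 3600
    elev <- solar_shape(hour, scn$sunrise, scn$sunset)
    par_top <- par_top_series(scn, tsec)
    # daytime mean of the half-sine shape is 2/pi, giving the amplitude
    # that attains the configured daytime mean at the top of the canopy
    amp_top <- (scn$ta_day_mean - scn$ta_night_mean) * pi / 2
    z_top <- max(scn$heights)
    out <- lapply(scn$heights, function(z) {
      damp <- scn$ta_damp_floor + (1 - scn$ta_damp_floor) * z / z_top
      T_A <- scn$ta_night_mean + amp_top * damp * elev +
        stats::rnorm(nt, 0, scn$ta_noise_sd)
      h <- pmin(1, pmax(0.05, scn$h_intercept + scn$h_slope * T_A +
                          stats::rnorm(nt, 0, scn$h_noise_sd)))
      u_mean <- stats::approx(c(11.5, z_top),
                              c(scn$u_canopy_mean, scn$u_top_mean),
                              xout = z, rule = 2)$y
      U <- stats::rlnorm(nt, meanlog = log(u_mean) - scn$u_sdlog^2 / 2,
                         sdlog = scn$u_sdlog)
      data.frame(time = scn$start + tsec, height = z,
                 PAR = par_top * exp(-scn$k_par * pmax(0, scn$z_canopy - z)),
                 T_A = T_A, h = h, U = U)
    })
    mc <- do.call(rbind, out)
    mc <- derive_microclimate(mc)
    mc[order(mc$time, mc$height), ]
  })
}

#' Generate a synthetic leaf-trait table
#'
#' One row per leaf with structural traits drawn around the species
#' specification (widths jittered by +/-10%), a height uniform in the
#' species' canopy range, and the leaf's true stomatal-intercept offset
#' (`gs_offset`, drawn from a normal with the scenario's leaf-offset SD).
#'
#' @param scn A [synthetic_scenario()].
#' @return Data frame with columns `leaf_id`, `species`, `width_m`,
#'   `length_m`, `area_m2`, `thickness_mm`, `lma_g_m2`, `ldmc_g_g`,
#'   `height_m`, `angle_deg`, `gs_offset`.
#' @export
gen_leaf_traits <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  withr::with_seed(stage_seed(scn, "traits"), {
    rows <- lapply(scn$species, function(sp) {
      n <- sp$n_leaves
      W <- sp$width_m * stats::runif(n, 0.9, 1.1)
      L <- 2 * W
      data.frame(leaf_id = sprintf("%s_L%02d", sp$name, seq_len(n)),
                 species = sp$name, width_m = W, length_m = L,
                 area_m2 = 0.7 * W * L,
                 thickness_mm = stats::runif(n, 0.2, 0.4),
                 lma_g_m2 = sp$lma_g_m2 * stats::runif(n, 0.9, 1.1),
                 ldmc_g_g = pmin(0.95, pmax(0.05,
                   sp$ldmc * stats::runif(n, 0.95, 1.05))),
                 height_m = stats::runif(n, sp$leaf_heights[1],
                                         sp$leaf_heights[2]),
                 angle_deg = stats::runif(n, 0, 60),
                 gs_offset = stats::rnorm(n, 0, scn$leaf_offset_sd))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Microclimate at a leaf: T_A/h/D from the nearest sensor height, wind
# linearly interpolated to the leaf height, PAR attenuated to the leaf
# height by the same Beer law the generator used.
leaf_microclimate <- function(scn, mc, z_leaf) {
  z_top <- max(scn$heights)
  hts <- sort(unique(mc$height))
  nearest <- hts[which.min(abs(hts - z_leaf))]
  base <- mc[mc$height == nearest, ]
  base <- base[order(base$time), ]
  top <- mc[mc$height == z_top, ]
  top <- top[order(top$time), ]
  # interpolate wind between bracketing sensor heights
  if (z_leaf <= hts[1]) {
    U <- mc$U[mc$height == hts[1]][order(mc$time[mc$height == hts[1]])]
  } else if (z_leaf >= z_top) {
    U <- top$U
  } else {
    i <- findInterval(z_leaf, hts)
    w <- (z_leaf - hts[i]) / (hts[i + 1] - hts[i])
    U_lo <- mc[mc$height == hts[i], ]
    U_lo <- U_lo[order(U_lo$time), "U"]
    U_hi <- mc[mc$height == hts[i + 1], ]
    U_hi <- U_hi[order(U_hi$time), "U"]
    U <- (1 - w) * U_lo + w * U_hi
  }
  data.frame(time = base$time,
             PAR = top$PAR * exp(-scn$k_par * pmax(0, scn$z_canopy - z_leaf)),
             PAR_top = top$PAR,
             T_A = base$T_A, h = base$h, D = base$D, U = U)
}

#' Generate synthetic stomatal spot measurements
#'
#' Spot g_s measurements on each leaf at random daytime instants:
#' `g_s = species intercept + leaf offset + species slope * D + residual`,
#' with D taken from the generated microclimate at the leaf. No spots are
#' generated at night (canopy-top PAR below 5 umol m^-2 s^-1).
#'
#' @param scn A [synthetic_scenario()].
#' @param microclimate Optional pre-generated [gen_microclimate()] table.
#' @param traits Optional pre-generated [gen_leaf_traits()] table.
#' @return Data frame with columns `leaf_id`, `species`, `time`, `D`, `g_s`.
#' @export
gen_stomatal_observations <- function(scn, microclimate = NULL,
                                      traits = NULL) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  if (is.null(microclimate)) microclimate <- gen_microclimate(scn)
  if (is.null(traits)) traits <- gen_leaf_traits(scn)
  withr::with_seed(stage_seed(scn, "spots"), {
    rows <- lapply(seq_len(nrow(traits)), function(i) {
      lf <- traits[i, ]
      sp <- scn$species[[lf$species]]
      lmc <- leaf_microclimate(scn, microclimate, lf$height_m)
      day <- which(lmc$PAR_top > 5)
      pick <- sort(sample(day, min(scn$spots_per_leaf, length(day))))
      D <- lmc$D[pick]
      g_s <- sp$gs_intercept + lf$gs_offset + sp$gs_slope * D +
        stats::rnorm(length(pick), 0, scn$gs_spot_sd)
      data.frame(leaf_id = lf$leaf_id, species = lf$species,
                 time = lmc$time[pick], D = D, g_s = g_s)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic observed leaf temperature series
#'
#' For each leaf, drives the forward leaf energy balance with the leaf's
#' true traits (species boundary coefficient and leaf width) and its true
#' stomatal response to D (floored at `g_min`), under the microclimate at
#' the leaf's height. The observed temperature difference is the forward
#' truth plus measurement noise. In a fraction `par_corruption_rate` of
#' daytime 20-minute windows (per leaf) the PAR actually driving the leaf is
#' rescaled by a factor drawn from `corruption_factors`, emulating
#' sensor/leaf-surface radiation mismatch, while the recorded `PAR` column
#' is left unchanged.
#'
#' @param scn A [synthetic_scenario()].
#' @param microclimate Optional pre-generated [gen_microclimate()] table.
#' @param traits Optional pre-generated [gen_leaf_traits()] table.
#' @param k,rcfg,kt Physical, radiation and Tetens constants.
#' @return Data frame with columns `time`, `leaf_id`, `species`, `height`,
#'   `PAR` (recorded, at the leaf), `PAR_top`, `T_A`, `h`, `U`, `D`,
#'   `g_s_true` (mmol m^-2 s^-1), `dT_true`, `dT_obs`, `corrupted`,
#'   `daytime`.
#' @export
gen_leaf_temperature_series <- function(scn, microclimate = NULL,
                                        traits = NULL,
                                        k = physical_constants(),
                                        rcfg = radiation_config(),
                                        kt = tetens_constants()) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  if (is.null(microclimate)) microclimate <- gen_microclimate(scn)
  if (is.null(traits)) traits <- gen_leaf_traits(scn)
  withr::with_seed(stage_seed(scn, "leaf"), {
    rows <- lapply(seq_len(nrow(traits)), function(i) {
      lf <- traits[i, ]
      sp <- scn$species[[lf$species]]
      lmc <- leaf_microclimate(scn, microclimate, lf$height_m)
      nt <- nrow(lmc)
      daytime <- lmc$PAR_top > 5
      # corruption drawn per 20-min clock window
      win <- floor(as.numeric(lmc$time) / 1200)
      uw <- unique(win[daytime])
      corrupt_w <- uw[stats::runif(length(uw)) < scn$par_corruption_rate]
      fac_w <- sample(scn$corruption_factors, length(corrupt_w),
                      replace = TRUE)
      fac <- rep(1, nt)
      m <- match(win, corrupt_w)
      hit <- !is.na(m) & daytime
      fac[hit] <- fac_w[m[hit]]
      g_s_mmol <- pmax(scn$g_min,
                       sp$gs_intercept + lf$gs_offset + sp$gs_slope * lmc$D)
      g_s_vel <- gs_to_velocity(g_s_mmol, lmc$T_A, k$P_atm)
      p_sp <- boundary_layer_params(a = sp$bl_a)
      eb <- leaf_air_temperature_difference(
        PAR = lmc$PAR * fac, T_A = lmc$T_A, h = lmc$h, U = lmc$U,
        W = lf$width_m, g_s = g_s_vel, k = k, p = p_sp, rcfg = rcfg,
        kt = kt)
      data.frame(time = lmc$time, leaf_id = lf$leaf_id,
                 species = lf$species, height = lf$height_m,
                 PAR = lmc$PAR, PAR_top = lmc$PAR_top,
                 T_A = lmc$T_A, h = lmc$h, U = lmc$U, D = lmc$D,
                 g_s_true = g_s_mmol, dT_true = eb$delta_T_e,
                 dT_obs = eb$delta_T_e +
                   stats::rnorm(nt, 0, scn$dT_noise_sd),
                 corrupted = fac != 1, daytime = daytime)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
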