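sim_spots <- function(n_leaves = 10, spots = 20, intercept = 325.1,
                      slope = -68.8, offset_sd = 30, resid_sd = 40,
                      species = "spA", d_max = 1.2, seed = 1) {
  withr::with_seed(seed, {
    off <- rnorm(n_leaves, 0, offset_sd)
    do.call(rbind, lapply(seq_len(n_leaves), function(i) {
      D <- runif(spots, 0, d_max)
      data.frame(leaf_id = sprintf("%s_%02d", species, i), species = species,
                 D = D,
                 g_s = intercept + off[i] + slope * D +
                   rnorm(spots, 0, resid_sd))
    }))
  })
}

test_that("mixed model recovers species-level stomatal parameters", {
  spots <- rbind(sim_spots(seed = 101),
                 sim_spots(intercept = 401.6, slope = -189.8,
                           species = "spB", seed = 102))
  fit <- fit_gs_D_model(spots)
  expect_equal(fit$method, "lme")
  truth <- data.frame(species = c("spA", "spB"),
                      intercept = c(325.1, 401.6),
                      slope = c(-68.8, -189.8))
  # 3 SE keeps the fixed-seed false-alarm rate negligible; the 2-sigma
  # calibration itself is verified by the coverage test below
  for (i in 1:2) {
    r <- fit$species[fit$species$species == truth$species[i], ]
    expect_lt(abs(r$intercept - truth$intercept[i]), 3 * r$intercept_se)
    expect_lt(abs(r$slope - truth$slope[i]), 3 * r$slope_se)
  }
  # leaf offsets are centred and one per leaf
  expect_equal(nrow(fit$leaf_offsets), 20L)
  expect_lt(abs(mean(fit$leaf_offsets$offset)), 15)
})

test_that("noise-free spots are recovered exactly (with fallback if singular)", {
  spots <- sim_spots(offset_sd = 0, resid_sd = 0, seed = 5)
  fit <- suppressWarnings(fit_gs_D_model(spots))
  r <- fit$species[1, ]
  expect_equal(r$intercept, 325.1, tolerance = 1e-6)
  expect_equal(r$slope, -68.8, tolerance = 1e-6)
})

test_that("degenerate designs fall back to least squares with a warning", {
  one_leaf <- sim_spots(n_leaves = 1, spots = 6, resid_sd = 0, offset_sd = 0,
                        seed = 3)
  expect_warning(fit <- fit_gs_D_model(one_leaf), "falling back")
  expect_equal(fit$method, "ols")
  expect_equal(fit$leaf_offsets$offset, 0)
})

test_that("stomatal predictions use leaf offsets and respect the floor", {
  spots <- sim_spots(seed = 7)
  fit <- fit_gs_D_model(spots)
  lf <- fit$leaf_offsets$leaf_id[1]
  off <- fit$leaf_offsets$offset[1]
  expect_equal(predict_gs(fit, lf, 0),
               fit$species$intercept[1] + off)
  # very large D hits the configured floor, never nonpositive
  expect_equal(predict_gs(fit, lf, 50), fit$g_min)
  expect_true(all(predict_gs(fit, lf, seq(0, 60, by = 0.5)) > 0))
  # unknown leaf requires a species and takes offset zero
  expect_error(predict_gs(fit, "nobody", 0.5), "species")
  expect_equal(predict_gs(fit, "nobody", 0, species = "spA"),
               fit$species$intercept[1])
})

test_that("species lines cross: high-intercept steep-slope falls below at high D", {
  spots <- rbind(sim_spots(offset_sd = 0, resid_sd = 0, seed = 1),
                 sim_spots(intercept = 401.6, slope = -189.8, species = "spB",
                           offset_sd = 0, resid_sd = 0, seed = 2))
  fit <- suppressWarnings(fit_gs_D_model(spots))
  gA <- function(D) predict_gs(fit, "x", D, species = "spA")
  gB <- function(D) predict_gs(fit, "x", D, species = "spB")
  expect_gt(gB(0), gA(0))
  expect_lt(gB(1.2), gA(1.2))
})

test_that("molar-to-velocity conversion follows the ideal-gas law", {
  expect_equal(gs_to_velocity(400, 20, 101.325), 0.009622043716753024,
               tolerance = 1e-12)
  expect_equal(1 / gs_to_velocity(400, 20), 0.5 / gs_to_velocity(200, 20))
  expect_error(gs_to_velocity(0, 20), "must be > 0")
})

test_that("heat transfer coefficient assembles its three pathways", {
  k <- physical_constants()
  g_b_H <- 0.03320391543176799
  g_b_R <- 0.0051209400193916385
  g_s <- gs_to_velocity(300, 20, 90)
  s <- svp_slope(20); gam <- psychrometric_constant(k)
  H <- heat_transfer_coefficient(g_b_H, g_b_R, g_s, s, gam, T_A = 20, k = k)
  expect_equal(H, 62.76831454035954, tolerance = 1e-9)
  H0 <- heat_transfer_coefficient(g_b_H, g_b_R, 0, s, gam, T_A = 20, k = k)
  expect_equal(H0, air_density(20, k) * k$c_pa * (g_b_H + g_b_R))
  # H scales linearly with air density
  k2 <- physical_constants(rho_a = 2 * air_density(20, k))
  expect_equal(heat_transfer_coefficient(g_b_H, g_b_R, 0, s, gam, 20, k2),
               2 * H0)
})

test_that("thermal time constant scales with structure and cooling capacity", {
  H <- 60
  expect_equal(thermal_time_constant(0.2, 0.4, H)$tau,
               2 * thermal_time_constant(0.1, 0.4, H)$tau)
  # faster heat exchange (higher g_s, wind) shortens tau
  taus <- thermal_time_constant(0.1, 0.4, c(30, 60, 120))$tau
  expect_true(all(diff(taus) < 0))
  # drier tissue (higher LDMC) stores less heat per dry gram
  expect_gt(thermal_time_constant(0.1, 0.25, H)$tau,
            thermal_time_constant(0.1, 0.45, H)$tau)
  # fixed-LDMC trait grid: tau ratio equals LMA ratio
  lma <- seq(0.05, 0.2, by = 0.05)
  tg <- thermal_time_constant(lma, 0.35, H)$tau
  expect_equal(tg / tg[1], lma / lma[1], tolerance = 1e-12)
  expect_error(thermal_time_constant(0.1, 1.2, H), "LDMC")
  expect_error(thermal_time_constant(0.1, 0.4, -1), "H must be")
  # dimensional audit: order tens-to-hundreds of seconds for real leaves
  expect_gt(thermal_time_constant(0.09, 0.45, 60)$tau, 5)
  expect_lt(thermal_time_constant(0.09, 0.45, 60)$tau, 2000)
})

test_that("the g_s-D slope confidence interval has near-nominal coverage", {
  hits <- vapply(1:100, function(r) {
    spots <- sim_spots(seed = 4000 + r)
    fit <- suppressWarnings(fit_gs_D_model(spots))
    s <- fit$species[1, ]
    abs(s$slope - (-68.8)) <= qt(0.975, 150) * s$slope_se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})
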