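test_that("boundary-layer conductance follows the power law", {
  expect_equal(boundary_layer_conductance_heat(1, 1), 0.0105)
  expect_equal(boundary_layer_conductance_heat(4, 1),
               2 * boundary_layer_conductance_heat(1, 1))
  expect_equal(boundary_layer_conductance_heat(1, 0.1),
               0.03320391543176799, tolerance = 1e-12)
  expect_error(boundary_layer_conductance_heat(1, 0), "W must be")
  # wind floor keeps the conductance bounded away from zero
  expect_equal(boundary_layer_conductance_heat(0, 0.1),
               boundary_layer_conductance_heat(0.05, 0.1))
})

test_that("radiative conductance is the linearised 4-eps-sigma-T^3 form", {
  expect_equal(radiative_conductance(20), 0.0051209400193916385,
               tolerance = 1e-12)
  expect_gt(radiative_conductance(30), radiative_conductance(10))
  expect_equal(radiative_conductance(20, physical_constants(eps_leaf = 0)), 0)
})

test_that("psychrometric constant scales with pressure and latent heat", {
  expect_equal(psychrometric_constant(physical_constants(P_atm = 101.325)),
               67.28847037207166, tolerance = 1e-10)
  expect_equal(psychrometric_constant(), 59.767701292735744,
               tolerance = 1e-10)
  expect_equal(psychrometric_constant(physical_constants(P_atm = 45)),
               psychrometric_constant() / 2)
  expect_equal(psychrometric_constant(physical_constants(lambda_v = 2.45e6 / 2)),
               2 * psychrometric_constant())
})

test_that("net isotropic radiation converts PAR and cancels longwave by default", {
  expect_equal(net_isotropic_radiation(0, 20), 0)
  expect_equal(net_isotropic_radiation(1000, 20), 218.8183807439825,
               tolerance = 1e-10)
  expect_gt(net_isotropic_radiation(1500, 20),
            net_isotropic_radiation(1000, 20))
  # unequal emissivities re-activate the longwave term
  k2 <- physical_constants(eps_leaf = 0.95)
  expect_gt(net_isotropic_radiation(0, 20, k2), 0)
})

test_that("leaf-to-air temperature difference matches the independent oracle", {
  g_s <- gs_to_velocity(300, 20, 90)
  eb <- leaf_air_temperature_difference(PAR = 1500, T_A = 20, h = 0.7,
                                        U = 1, W = 0.1, g_s = g_s)
  # frozen from an independent evaluation of the two-term quotient form
  expect_equal(eb$delta_T_e, 4.149617324996771, tolerance = 1e-9)
  expect_equal(eb$delta_T_e, oracle_delta_T(1500, 20, 0.7, 1, 0.1, g_s),
               tolerance = 1e-12)
  expect_equal(eb$delta_T_e, eb$radiative_term - eb$evaporative_term)
  expect_equal(eb$T_Le, 20 + eb$delta_T_e)
  expect_equal(eb$r_b_HR, 1 / (eb$g_b_H + eb$g_b_R))

  # oracle agreement across random states
  st <- random_states(50, seed = 3)
  g <- gs_to_velocity(st$g_s_mmol, st$T_A, 90)
  got <- leaf_air_temperature_difference(st$PAR, st$T_A, st$h, st$U, st$W, g)
  expect_equal(got$delta_T_e,
               oracle_delta_T(st$PAR, st$T_A, st$h, st$U, st$W, g),
               tolerance = 1e-10)
})

test_that("sign structure: radiation warms, dry air cools", {
  g_s <- gs_to_velocity(300, 20, 90)
  # both forcings zero -> exactly zero
  eb0 <- leaf_air_temperature_difference(0, 20, 1, 1, 0.1, g_s)
  expect_equal(eb0$delta_T_e, 0)
  expect_gt(leaf_air_temperature_difference(800, 20, 1, 1, 0.1,
                                            g_s)$delta_T_e, 0)
  expect_lt(leaf_air_temperature_difference(0, 20, 0.5, 1, 0.1,
                                            g_s)$delta_T_e, 0)
})

test_that("delta-T is monotone in radiation and stomatal conductance", {
  g_s <- gs_to_velocity(c(100, 200, 400), 20, 90)
  par_grid <- c(100, 500, 1000, 1800)
  dts <- leaf_air_temperature_difference(par_grid, 20, 0.7, 1, 0.1, g_s[2])
  expect_true(all(diff(dts$delta_T_e) > 0))
  dts2 <- vapply(g_s, function(g)
    leaf_air_temperature_difference(1200, 20, 0.7, 1, 0.1, g)$delta_T_e,
    numeric(1))
  expect_true(all(diff(dts2) < 0))
  # well-coupled limit: ever-stronger convective coupling locks the leaf
  # onto air temperature from either side
  g_s <- gs_to_velocity(300, 20, 90)
  warm <- vapply(c(1e2, 1e4, 1e6), function(U)
    leaf_air_temperature_difference(1200, 20, 0.7, U, 0.1, g_s)$delta_T_e,
    numeric(1))
  cool <- vapply(c(1e2, 1e4, 1e6), function(U)
    leaf_air_temperature_difference(0, 20, 0.6, U, 0.1, g_s)$delta_T_e,
    numeric(1))
  expect_true(all(diff(abs(warm)) < 0) && all(warm > 0))
  expect_true(all(diff(abs(cool)) < 0) && all(cool < 0))
  expect_lt(abs(warm[3]), 0.01)
  expect_lt(abs(cool[3]), 0.01)
})

test_that("energy closes: sensible plus latent flux equals net radiation", {
  st <- random_states(100, seed = 8)
  g <- gs_to_velocity(st$g_s_mmol, st$T_A, 90)
  eb <- leaf_air_temperature_difference(st$PAR, st$T_A, st$h, st$U, st$W, g)
  rho <- air_density(st$T_A)
  k <- physical_constants()
  D_Pa <- 1000 * vapour_pressure_deficit(st$T_A, st$h)
  sensible <- rho * k$c_pa * eb$delta_T_e / eb$r_b_HR
  latent <- rho * k$c_pa / eb$gamma *
    (D_Pa + eb$s * eb$delta_T_e) / (eb$r_b_W + eb$r_l_W)
  expect_equal(sensible + latent, eb$R_ni, tolerance = 1e-8)
})

test_that("inversion recovers the boundary resistance it came from", {
  st <- random_states(400, seed = 5)
  g <- gs_to_velocity(st$g_s_mmol, st$T_A, 90)
  eb <- leaf_air_temperature_difference(st$PAR, st$T_A, st$h, st$U, st$W, g)
  inv <- invert_boundary_resistance(eb$delta_T_e, st$PAR, st$T_A, st$h, g)
  # radiation-dominated observations are uniquely invertible and exact
  warm <- eb$delta_T_e > 0
  expect_gt(sum(warm), 100)
  expect_true(all(inv$flag[warm] == "ok"))
  expect_lt(max(abs(inv$r_b_W[warm] - eb$r_b_W[warm]) / eb$r_b_W[warm]),
            1e-6)
  # every returned root reproduces the observation when substituted back,
  # holding the conductance-ratio coupling
  k <- physical_constants(); p <- boundary_layer_params()
  rcfg <- radiation_config(); kt <- tetens_constants()
  got <- vapply(which(!is.na(inv$r_b_W)), function(i)
    leaftherm:::delta_T_given_rbw(inv$r_b_W[i], st$PAR[i], st$T_A[i],
                                  st$h[i], g[i], k, p, rcfg, kt),
    numeric(1))
  expect_equal(got, eb$delta_T_e[!is.na(inv$r_b_W)], tolerance = 1e-6)
})

test_that("evaporation-dominated ambiguity returns the smallest root, flagged", {
  st <- random_states(400, seed = 5)
  g <- gs_to_velocity(st$g_s_mmol, st$T_A, 90)
  eb <- leaf_air_temperature_difference(st$PAR, st$T_A, st$h, st$U, st$W, g)
  inv <- invert_boundary_resistance(eb$delta_T_e, st$PAR, st$T_A, st$h, g)
  amb <- inv$flag == "multiple_roots"
  expect_gt(sum(amb), 0)
  expect_true(all(eb$delta_T_e[amb] < 0))
  # the returned root is never larger than the generating resistance
  expect_true(all(inv$r_b_W[amb] <= eb$r_b_W[amb] * (1 + 1e-9)))
})

test_that("inversion flags degenerate and rootless observations", {
  g_s <- gs_to_velocity(300, 20, 90)
  deg <- invert_boundary_resistance(0, PAR = 0, T_A = 20, h = 1, g_s = g_s)
  expect_equal(deg$flag, "degenerate")
  expect_true(is.na(deg$r_b_W))
  # a +10 C excess cannot arise with zero radiation: no positive root
  bad <- invert_boundary_resistance(10, PAR = 0, T_A = 20, h = 0.6,
                                    g_s = g_s)
  expect_equal(bad$flag, "no_root")
})
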