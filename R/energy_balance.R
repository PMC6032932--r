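#' Boundary-layer conductance to heat
#'
#' Forced-convection power law \eqn{g_{b,H} = a (U/W)^b} (m/s), with leaf
#' width `W` (m) and wind speed `U` (m/s). Wind speeds below `p$U_min` are
#' floored to bound the associated resistance in near-still air.
#'
#' @param U Wind speed (m/s), non-negative.
#' @param W Leaf width (m), strictly positive.
#' @param p [boundary_layer_params()].
#' @return Conductance (m/s), vectorised.
#' @export
boundary_layer_conductance_heat <- function(U, W, p = boundary_layer_params()) {
  if (any(W <= 0)) stop("leaf width W must be > 0")
  if (any(U < 0)) stop("wind speed U must be >= 0")
  U_eff <- pmax(U, p$U_min)
  p$a * (U_eff / W)^p$b
}

#' Radiative conductance
#'
#' Linearised longwave-exchange conductance
#' \eqn{g_{b,R} = 4 \epsilon_{leaf} \sigma (T_A + 273.15)^3 / (\rho_a c_{pa})},
#' placing radiative exchange in parallel with the convective heat path.
#'
#' @param T_A Air temperature (degrees C).
#' @param k [physical_constants()].
#' @return Conductance (m/s), vectorised over `T_A`.
#' @export
radiative_conductance <- function(T_A, k = physical_constants()) {
  if (any(T_A <= -273.15)) stop("T_A below absolute zero")
  rho <- air_density(T_A, k)
  4 * k$eps_leaf * k$sigma * (T_A + 273.15)^3 / (rho * k$c_pa)
}

#' Psychrometric constant
#'
#' \eqn{\gamma = c_{pa} P / (0.622 \lambda_v)} in Pa/K, with `P` the
#' atmospheric pressure in Pa. About 60 Pa/K at 90 kPa.
#'
#' @param k [physical_constants()].
#' @return Psychrometric constant (Pa/K).
#' @export
psychrometric_constant <- function(k = physical_constants()) {
  k$c_pa * k$P_atm * 1000 / (0.622 * k$lambda_v)
}

#' Net isotropic radiation
#'
#' Absorbed shortwave plus net isothermal longwave exchange per unit leaf
#' area, taking the sky temperature equal to air temperature:
#' \deqn{R_{ni} = \alpha_{SW} (PAR / q_{conv}) / f_{PAR} +
#'       (\epsilon_{sky} - \epsilon_{leaf}) \sigma (T_A + 273.15)^4.}
#' With the default emissivities equal, the longwave term is exactly zero.
#'
#' @param PAR Photosynthetically active radiation (umol m^-2 s^-1).
#' @param T_A Air temperature (degrees C).
#' @param k [physical_constants()].
#' @param rcfg [radiation_config()].
#' @return Net isotropic radiation (W/m^2), vectorised.
#' @export
net_isotropic_radiation <- function(PAR, T_A, k = physical_constants(),
                                    rcfg = radiation_config()) {
  if (any(PAR < 0)) stop("PAR must be >= 0")
  sw <- rcfg$alpha_sw * (PAR / rcfg$q_conv) / rcfg$f_par
  lw <- (k$eps_sky - k$eps_leaf) * k$sigma * (T_A + 273.15)^4
  sw + lw
}

# Resistance network for a leaf: convective + radiative heat path in
# parallel (r_b_HR), water-vapour boundary layer scaled from the heat
# conductance, leaf (stomatal) resistance from g_s in velocity units.
resistance_network <- function(T_A, U, W, g_s, k, p) {
  if (any(g_s <= 0)) stop("g_s must be > 0 (velocity units, m/s)")
  g_b_H <- boundary_layer_conductance_heat(U, W, p)
  g_b_R <- radiative_conductance(T_A, k)
  g_b_W <- p$gbw_ratio * g_b_H
  data.frame(g_b_H = g_b_H, g_b_R = g_b_R, g_b_W = g_b_W,
             r_b_HR = 1 / (g_b_H + g_b_R),
             r_b_W = 1 / g_b_W, r_l_W = 1 / g_s,
             gamma = psychrometric_constant(k),
             s = svp_slope(T_A))
}

# Core two-term quotient for the leaf-to-air temperature difference, given
# an already-built resistance set. D_Pa in Pa. Returns the two summands.
delta_T_terms <- function(R_ni, D_Pa, rho, c_pa, r_b_HR, r_W, gamma, s) {
  if (any(r_b_HR <= 0) || any(r_W <= 0)) stop("nonpositive resistance")
  denom <- gamma * r_W + s * r_b_HR
  radiative <- r_b_HR * gamma * r_W * R_ni / (rho * c_pa * denom)
  evaporative <- r_b_HR * D_Pa / denom
  list(radiative = radiative, evaporative = evaporative)
}

#' Steady-state leaf-to-air temperature difference
#'
#' Solves the linearised steady-state leaf energy balance for the
#' leaf-to-air temperature difference:
#' \deqn{\Delta T_e = \frac{r_{b,HR}\,\gamma\,(r_{b,W}+r_{l,W})\,R_{ni}}
#'   {\rho_a c_{pa} [\gamma (r_{b,W}+r_{l,W}) + s\, r_{b,HR}]}
#'   - \frac{r_{b,HR}\, D}{\gamma (r_{b,W}+r_{l,W}) + s\, r_{b,HR}},}
#' the difference of a radiative warming term and an evaporative cooling
#' term (D in Pa inside the equation; the user-facing `h` and derived `D`
#' are in proportion and kPa). Assumes no leaf heat storage (steady state)
#' and a sky temperature equal to air temperature.
#'
#' @param PAR Photosynthetically active radiation at the leaf
#'   (umol m^-2 s^-1).
#' @param T_A Air temperature (degrees C).
#' @param h Relative humidity (proportion).
#' @param U Wind speed (m/s).
#' @param W Leaf width (m).
#' @param g_s Stomatal conductance in velocity units (m/s); see
#'   [gs_to_velocity()].
#' @param k [physical_constants()].
#' @param p [boundary_layer_params()].
#' @param rcfg [radiation_config()].
#' @param kt [tetens_constants()].
#' @return Data frame with columns `delta_T_e`, `T_Le`, `R_ni`,
#'   `radiative_term`, `evaporative_term` and the resistance set
#'   (`g_b_H`, `g_b_R`, `g_b_W`, `r_b_HR`, `r_b_W`, `r_l_W`, `gamma`, `s`).
#' @export
#' @examples
#' leaf_air_temperature_difference(
#'   PAR = 1500, T_A = 20, h = 0.7, U = 1, W = 0.1,
#'   g_s = gs_to_velocity(300, T_A = 20, P_atm = 90))
leaf_air_temperature_difference <- function(PAR, T_A, h, U, W, g_s,
                                            k = physical_constants(),
                                            p = boundary_layer_params(),
                                            rcfg = radiation_config(),
                                            kt = tetens_constants()) {
  n <- max(length(PAR), length(T_A), length(h), length(U),
           length(W), length(g_s))
  PAR <- rep_len(PAR, n); T_A <- rep_len(T_A, n); h <- rep_len(h, n)
  U <- rep_len(U, n); W <- rep_len(W, n); g_s <- rep_len(g_s, n)
  res <- resistance_network(T_A, U, W, g_s, k, p)
  rho <- air_density(T_A, k)
  R_ni <- net_isotropic_radiation(PAR, T_A, k, rcfg)
  D_Pa <- 1000 * vapour_pressure_deficit(T_A, h, kt)
  tm <- delta_T_terms(R_ni, D_Pa, rho, k$c_pa, res$r_b_HR,
                      res$r_b_W + res$r_l_W, res$gamma, res$s)
  dT <- tm$radiative - tm$evaporative
  cbind(data.frame(delta_T_e = dT, T_Le = T_A + dT, R_ni = R_ni,
                   radiative_term = tm$radiative,
                   evaporative_term = tm$evaporative),
        res)
}

# Delta-T as a function of the water-vapour boundary-layer resistance alone,
# holding the g_b_W = gbw_ratio * g_b_H coupling, so r_b_HR moves with
# r_b_W. Scalar in r_b_W; used by the inversion.
delta_T_given_rbw <- function(r_b_W, PAR, T_A, h, g_s, k, p, rcfg, kt) {
  g_b_W <- 1 / r_b_W
  g_b_H <- g_b_W / p$gbw_ratio
  g_b_R <- radiative_conductance(T_A, k)
  r_b_HR <- 1 / (g_b_H + g_b_R)
  rho <- air_density(T_A, k)
  R_ni <- net_isotropic_radiation(PAR, T_A, k, rcfg)
  D_Pa <- 1000 * vapour_pressure_deficit(T_A, h, kt)
  tm <- delta_T_terms(R_ni, D_Pa, rho, k$c_pa, r_b_HR,
                      r_b_W + 1 / g_s, psychrometric_constant(k),
                      svp_slope(T_A, kt))
  tm$radiative - tm$evaporative
}

#' Invert the energy balance for boundary-layer resistance
#'
#' Given an observed leaf-to-air temperature difference and simultaneous
#' microclimate and stomatal conductance, solves the leaf energy balance for
#' the boundary-layer resistance to water `r_b_W`. The radiative/heat
#' resistance is held coupled to `r_b_W` through
#' `g_b_W = gbw_ratio * g_b_H`; after substituting the coupling the balance
#' is a quadratic in `r_b_W`, solved in closed form (numerically stable
#' formulation). Radiation-dominated observations (leaf warmer than air)
#' have a unique positive root; evaporation-dominated observations can
#' admit two positive roots, in which case the smallest is returned and
#' flagged, since the observation alone cannot distinguish them.
#'
#' @param delta_T_obs Observed leaf-to-air temperature difference (degrees C).
#' @param PAR,T_A,h Microclimate at the leaf (umol m^-2 s^-1, degrees C,
#'   proportion).
#' @param g_s Stomatal conductance in velocity units (m/s).
#' @param k,p,rcfg,kt Constants as in [leaf_air_temperature_difference()].
#' @return Data frame with columns `r_b_W` (NA when no root) and `flag`
#'   in `{"ok", "multiple_roots", "no_root", "degenerate"}`. Records flagged
#'   other than `"ok"` should be excluded from calibration downstream.
#' @export
invert_boundary_resistance <- function(delta_T_obs, PAR, T_A, h, g_s,
                                       k = physical_constants(),
                                       p = boundary_layer_params(),
                                       rcfg = radiation_config(),
                                       kt = tetens_constants()) {
  n <- max(length(delta_T_obs), length(PAR), length(T_A), length(h),
           length(g_s))
  obs <- rep_len(delta_T_obs, n); PAR <- rep_len(PAR, n)
  T_A <- rep_len(T_A, n); h <- rep_len(h, n); g_s <- rep_len(g_s, n)
  if (any(g_s <= 0)) stop("g_s must be > 0 (velocity units, m/s)")
  gam <- psychrometric_constant(k)
  rho <- air_density(T_A, k)
  s <- svp_slope(T_A, kt)
  g_b_R <- radiative_conductance(T_A, k)
  R_ni <- net_isotropic_radiation(PAR, T_A, k, rcfg)
  D_Pa <- 1000 * vapour_pressure_deficit(T_A, h, kt)
  r_l <- 1 / g_s
  q <- p$gbw_ratio
  # obs * [gam (x + r_l)(1 + q g_bR x) + q s x] =
  #   q x [gam (x + r_l) R_ni / (rho c_pa) - D]  -- quadratic in x = r_b_W
  A <- q * gam * (obs * g_b_R - R_ni / (rho * k$c_pa))
  B <- obs * (gam * (1 + q * g_b_R * r_l) + q * s) -
    q * (gam * r_l * R_ni / (rho * k$c_pa) - D_Pa)
  C <- obs * gam * r_l
  r_out <- rep(NA_real_, n)
  flag <- character(n)
  disc <- B^2 - 4 * A * C
  for (i in seq_len(n)) {
    if (R_ni[i] == 0 && D_Pa[i] == 0) {
      # no forcing: Delta-T is identically zero whatever the resistance, so
      # the observation carries no information about r_b_W
      flag[i] <- "degenerate"
      next
    }
    if (abs(A[i]) < .Machine$double.eps * max(1, abs(B[i]))) {
      x <- -C[i] / B[i]
      if (is.finite(x) && x > 0) {
        r_out[i] <- x
        flag[i] <- "ok"
      } else {
        flag[i] <- "no_root"
      }
      next
    }
    if (disc[i] < 0) {
      flag[i] <- "no_root"
      next
    }
    # stable quadratic roots
    qq <- -(B[i] + sign(B[i]) * sqrt(disc[i])) / 2
    roots <- c(qq / A[i], if (qq != 0) C[i] / qq else -B[i] / A[i])
    pos <- sort(unique(roots[is.finite(roots) & roots > 0]))
    if (length(pos) == 0L) {
      flag[i] <- "no_root"
    } else {
      r_out[i] <- pos[1]
      flag[i] <- if (length(pos) > 1L) "multiple_roots" else "ok"
    }
  }
  data.frame(r_b_W = r_out, flag = flag)
}
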