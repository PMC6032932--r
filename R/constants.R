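#' Tetens saturation vapour pressure constants
#'
#' Coefficients of the Tetens form \eqn{e_{sat} = a \exp(b T_A / (T_A + c))}
#' with \eqn{T_A} in degrees Celsius and \eqn{e_{sat}} in kPa.
#'
#' @param a Leading coefficient (kPa). At 0 degrees C the exponent vanishes, so
#'   `a` is the saturation vapour pressure of water at 0 degrees C.
#' @param b Dimensionless exponent coefficient.
#' @param c Temperature offset (degrees C); the form is defined for
#'   `T_A > -c`.
#' @return A list of class `tetens_constants`.
#' @export
#' @examples
#' k <- tetens_constants()
#' saturation_vapour_pressure(20, k)
tetens_constants <- function(a = 0.611, b = 17.502, c = 240.97) {
  stopifnot(a > 0, b > 0, c > 0)
  structure(list(a = a, b = b, c = c), class = "tetens_constants")
}

#' Physical constants for the leaf energy balance
#'
#' Bundles the thermodynamic constants used throughout the energy-balance and
#' thermal-time-constant calculations. `rho_a = NULL` (the default) computes
#' the density of dry air from air temperature and `P_atm` by the ideal-gas
#' law; supply a number to override with a constant density.
#'
#' @param rho_a Density of dry air (kg/m^3), or `NULL` for ideal-gas.
#' @param c_pa Specific heat capacity of dry air (J kg^-1 K^-1).
#' @param sigma Stefan-Boltzmann constant (W m^-2 K^-4).
#' @param eps_sky Sky emissivity (dimensionless, in (0, 1]).
#' @param eps_leaf Leaf emissivity (dimensionless, in [0, 1]).
#' @param P_atm Atmospheric pressure (kPa); the default 90 kPa corresponds to
#'   roughly 1000 m elevation.
#' @param lambda_v Latent heat of vaporisation of water (J/kg).
#' @param c_pw Specific heat capacity of liquid water (J kg^-1 K^-1).
#' @param c_pd Specific heat capacity of dry leaf matter (J kg^-1 K^-1);
#'   the default is a mean over tropical tree species.
#' @param phi Ratio of projected to total leaf area; 0.5 for flat leaves.
#' @return A list of class `physical_constants`.
#' @export
physical_constants <- function(rho_a = NULL, c_pa = 1012,
                               sigma = 5.670374419e-8,
                               eps_sky = 0.97, eps_leaf = 0.97,
                               P_atm = 90, lambda_v = 2.45e6,
                               c_pw = 4181, c_pd = 2814, phi = 0.5) {
  stopifnot(is.null(rho_a) || rho_a > 0, c_pa > 0, sigma > 0,
            eps_sky > 0, eps_sky <= 1, eps_leaf >= 0, eps_leaf <= 1,
            P_atm > 0, lambda_v > 0, c_pw > 0, c_pd > 0, phi > 0)
  structure(list(rho_a = rho_a, c_pa = c_pa, sigma = sigma,
                 eps_sky = eps_sky, eps_leaf = eps_leaf, P_atm = P_atm,
                 lambda_v = lambda_v, c_pw = c_pw, c_pd = c_pd, phi = phi),
            class = "physical_constants")
}

#' Boundary-layer conductance parameters
#'
#' Parameters of the forced-convection boundary-layer conductance model
#' \eqn{g_{b,H} = a (U/W)^b} (m/s) with wind speed `U` (m/s) and leaf width
#' `W` (m). The default `a = 0.0105`, `b = 0.5` is the textbook
#' flat-plate value; `a` can be recalibrated per species from inverted
#' boundary-layer resistances (see [fit_boundary_constants()]).
#'
#' @param a Coefficient (m s^-1/2 when `b = 0.5`).
#' @param b Dimensionless exponent in (0, 1].
#' @param gbw_ratio Ratio of the boundary-layer conductance to water vapour to
#'   that to heat (diffusivity-ratio correction), `g_b_W = gbw_ratio * g_b_H`.
#' @param U_min Wind-speed floor (m/s) applied before evaluating the power
#'   law, bounding resistances in still air.
#' @return A list of class `boundary_layer_params`.
#' @export
boundary_layer_params <- function(a = 0.0105, b = 0.5, gbw_ratio = 1.08,
                                  U_min = 0.05) {
  stopifnot(a > 0, b > 0, b <= 1, gbw_ratio > 0, U_min >= 0)
  structure(list(a = a, b = b, gbw_ratio = gbw_ratio, U_min = U_min),
            class = "boundary_layer_params")
}

#' Radiation configuration
#'
#' Constants converting photosynthetically active radiation (PAR) into
#' absorbed shortwave energy for the net isotropic radiation term.
#'
#' @param alpha_sw Leaf shortwave absorptance (dimensionless).
#' @param q_conv Quanta-to-energy conversion for PAR (umol/J).
#' @param f_par Fraction of shortwave irradiance that is PAR; dividing the
#'   PAR energy flux by `f_par` recovers total shortwave.
#' @return A list of class `radiation_config`.
#' @export
radiation_config <- function(alpha_sw = 0.5, q_conv = 4.57, f_par = 0.5) {
  stopifnot(alpha_sw > 0, alpha_sw <= 1, q_conv > 0, f_par > 0, f_par <= 1)
  structure(list(alpha_sw = alpha_sw, q_conv = q_conv, f_par = f_par),
            class = "radiation_config")
}

#' Density of dry air
#'
#' Ideal-gas density of dry air at air temperature `T_A` and the pressure in
#' `k`, unless `k$rho_a` overrides it with a constant.
#'
#' @param T_A Air temperature (degrees C).
#' @param k [physical_constants()].
#' @return Density (kg/m^3), vectorised over `T_A`.
#' @export
air_density <- function(T_A, k = physical_constants()) {
  if (!is.null(k$rho_a)) {
    return(rep_len(k$rho_a, length(T_A)))
  }
  R_dry <- 287.058  # specific gas constant of dry air, J kg^-1 K^-1
  k$P_atm * 1000 / (R_dry * (T_A + 273.15))
}
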