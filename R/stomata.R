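#' Fit the species-level stomatal response to vapour pressure deficit
#'
#' Linear mixed-effects model of stomatal conductance on vapour pressure
#' deficit, with species-specific fixed intercepts and slopes (a species by
#' D interaction) and a random intercept per leaf, estimated by REML. The
#' intercept of the g_s-D relationship is therefore leaf specific while the
#' slope is species specific. When the mixed fit fails or is singular the
#' function falls back to ordinary least squares (all leaf offsets zero)
#' and flags the fallback with a warning.
#'
#' @param spots Data frame of spot measurements with columns `leaf_id`,
#'   `species`, `D` (kPa), `g_s` (mmol m^-2 s^-1).
#' @param g_min Floor (mmol m^-2 s^-1) applied by [predict_gs()]; stored with
#'   the fit.
#' @return An object of class `stomatal_params`: `species` (data frame with
#'   `species`, `intercept`, `intercept_se`, `slope`, `slope_se`),
#'   `leaf_offsets` (data frame with `leaf_id`, `species`, `offset`),
#'   `method` (`"lme"` or `"ols"`), `g_min`, and the underlying `fit`.
#' @export
fit_gs_D_model <- function(spots, g_min = 5) {
  stopifnot(all(c("leaf_id", "species", "D", "g_s") %in% names(spots)))
  spots <- spots[stats::complete.cases(spots[c("leaf_id", "species",
                                               "D", "g_s")]), ]
  if (nrow(spots) < 4L) stop("too few spot measurements")
  spots$species <- factor(spots$species)
  spots$leaf_id <- factor(spots$leaf_id)
  one_species <- nlevels(spots$species) == 1L
  # a single-level factor cannot enter a contrast; drop to a plain slope fit
  form <- if (one_species) g_s ~ D else g_s ~ 0 + species + species:D
  method <- "lme"
  fit <- if (nlevels(spots$leaf_id) < 2L) {
    # a single leaf cannot separate its random intercept from the fixed one
    NULL
  } else {
    tryCatch(
      nlme::lme(form, random = ~ 1 | leaf_id, data = spots, method = "REML"),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    # a random-intercept SD collapsing to ~0 relative to the residual is a
    # singular fit; treat like a failure and fall back
    vc <- try(as.numeric(nlme::VarCorr(fit)[1, 1]), silent = TRUE)
    if (inherits(vc, "try-error") || !is.finite(vc)) fit <- NULL
  }
  if (is.null(fit)) {
    warning("mixed-effects fit failed or was singular; ",
            "falling back to ordinary least squares")
    method <- "ols"
    fit <- stats::lm(form, data = spots)
  }
  cf <- if (method == "lme") nlme::fixef(fit) else stats::coef(fit)
  se <- sqrt(diag(as.matrix(suppressWarnings(stats::vcov(fit)))))
  sp <- levels(spots$species)
  if (one_species) {
    int_names <- "(Intercept)"
    slp_names <- "D"
  } else {
    int_names <- paste0("species", sp)
    slp_names <- paste0("species", sp, ":D")
  }
  species_tab <- data.frame(species = sp,
                            intercept = unname(cf[int_names]),
                            intercept_se = unname(se[int_names]),
                            slope = unname(cf[slp_names]),
                            slope_se = unname(se[slp_names]))
  leaf_species <- unique(spots[c("leaf_id", "species")])
  if (method == "lme") {
    re <- nlme::ranef(fit)
    offsets <- data.frame(leaf_id = rownames(re),
                          offset = re[[1]])
  } else {
    offsets <- data.frame(leaf_id = levels(spots$leaf_id), offset = 0)
  }
  offsets <- merge(offsets,
                   data.frame(leaf_id = as.character(leaf_species$leaf_id),
                              species = as.character(leaf_species$species)),
                   by = "leaf_id", all.x = TRUE)
  out <- list(species = species_tab,
              leaf_offsets = offsets[c("leaf_id", "species", "offset")],
              method = method, g_min = g_min, fit = fit)
  class(out) <- "stomatal_params"
  out
}

#' @export
print.stomatal_params <- function(x, ...) {
  cat("Stomatal g_s-D response (", x$method, " fit), per species:\n", sep = "")
  for (i in seq_len(nrow(x$species))) {
    r <- x$species[i, ]
    cat(sprintf("  %s: g_s = %.1f (+/-%.1f) %+.1f (+/-%.1f) D\n",
                r$species, r$intercept, r$intercept_se, r$slope, r$slope_se))
  }
  cat(sprintf("  %d leaves; floor g_min = %g mmol m-2 s-1\n",
              nrow(x$leaf_offsets), x$g_min))
  invisible(x)
}

#' Predict stomatal conductance from vapour pressure deficit
#'
#' Leaf-level prediction `g_s = max(g_min, intercept + leaf_offset +
#' slope * D)`, using the leaf's random-intercept offset when the leaf is
#' known to the fit (offset zero otherwise). The floor keeps the predicted
#' conductance physical at large D, where the fitted lines cross zero.
#'
#' @param params A `stomatal_params` fit from [fit_gs_D_model()].
#' @param leaf_id Leaf identifier(s); recycled against `D`.
#' @param D Vapour pressure deficit (kPa).
#' @param species Optional species label(s) for leaves not in the fit.
#' @return Predicted g_s (mmol m^-2 s^-1), never below `params$g_min`.
#' @export
predict_gs <- function(params, leaf_id, D, species = NULL) {
  stopifnot(inherits(params, "stomatal_params"))
  n <- max(length(leaf_id), length(D))
  leaf_id <- rep_len(as.character(leaf_id), n)
  D <- rep_len(D, n)
  idx <- match(leaf_id, params$leaf_offsets$leaf_id)
  offset <- ifelse(is.na(idx), 0, params$leaf_offsets$offset[idx])
  sp <- params$leaf_offsets$species[idx]
  if (!is.null(species)) {
    species <- rep_len(as.character(species), n)
    sp[is.na(sp)] <- species[is.na(sp)]
  }
  if (anyNA(sp)) stop("species unknown for leaves not in the fit; ",
                      "supply `species`")
  si <- match(sp, params$species$species)
  if (anyNA(si)) stop("species not present in the fit: ",
                      paste(unique(sp[is.na(si)]), collapse = ", "))
  pmax(params$g_min,
       params$species$intercept[si] + offset + params$species$slope[si] * D)
}

#' Convert stomatal conductance from molar to velocity units
#'
#' The energy balance needs the leaf resistance to water in s/m, while
#' porometers report conductance in mmol m^-2 s^-1. By the ideal-gas law,
#' `g (m/s) = g (mol m^-2 s^-1) * R * (T_A + 273.15) / P` with pressure in
#' Pa.
#'
#' @param g_s Stomatal conductance (mmol m^-2 s^-1), strictly positive.
#' @param T_A Air temperature (degrees C).
#' @param P_atm Atmospheric pressure (kPa).
#' @return Conductance in velocity units (m/s).
#' @export
gs_to_velocity <- function(g_s, T_A, P_atm = 101.325) {
  if (any(g_s <= 0)) stop("g_s must be > 0 to yield a finite resistance")
  R_gas <- 8.31446
  (g_s / 1000) * R_gas * (T_A + 273.15) / (P_atm * 1000)
}

#' Total heat transfer coefficient
#'
#' \eqn{H = \rho_a c_{pa} (g_{b,H} + g_{b,R} + g_s s / \gamma)}
#' (W m^-2 K^-1), accounting for convection, radiation and transpiration.
#' All conductances in velocity units (m/s).
#'
#' @param g_b_H Boundary-layer conductance to heat (m/s).
#' @param g_b_R Radiative conductance (m/s).
#' @param g_s Stomatal conductance (m/s).
#' @param s Saturation vapour pressure slope (Pa/K); see [svp_slope()].
#' @param gamma Psychrometric constant (Pa/K); see
#'   [psychrometric_constant()].
#' @param T_A Air temperature (degrees C) used for the air density when
#'   `k$rho_a` is `NULL`.
#' @param k [physical_constants()].
#' @return Heat transfer coefficient (W m^-2 K^-1).
#' @export
heat_transfer_coefficient <- function(g_b_H, g_b_R, g_s, s, gamma,
                                      T_A = 20, k = physical_constants()) {
  if (any(c(g_b_H, g_b_R) < 0) || any(g_s < 0)) {
    stop("conductances must be >= 0")
  }
  air_density(T_A, k) * k$c_pa * (g_b_H + g_b_R + g_s * s / gamma)
}

#' Leaf thermal time constant
#'
#' E-folding time for leaf temperature to respond to a step change in its
#' environment:
#' \deqn{\tau = \phi\, LMA\, [c_{pw} / LDMC + (c_{pd} - c_{pw})] / H,}
#' with LMA in kg/m^2, LDMC the leaf dry matter content (g/g, i.e. dry over
#' water-saturated fresh mass) and `H` the total heat transfer coefficient
#' of [heat_transfer_coefficient()]. The bracketed heat capacity per unit
#' dry mass falls as LDMC rises (drier tissue stores less heat per dry
#' gram), so tau is proportional to LMA, decreasing in LDMC, and
#' decreasing in H (hence in g_s and wind).
#'
#' @param LMA Leaf mass per area (kg/m^2).
#' @param LDMC Leaf dry matter content (g/g), in (0, 1).
#' @param H Heat transfer coefficient (W m^-2 K^-1), > 0.
#' @param k [physical_constants()].
#' @return Data frame with columns `tau` (s) and `H`.
#' @export
thermal_time_constant <- function(LMA, LDMC, H, k = physical_constants()) {
  if (any(LMA <= 0)) stop("LMA must be > 0 (kg/m^2)")
  if (any(LDMC <= 0 | LDMC >= 1)) stop("LDMC must lie in (0, 1)")
  if (any(H <= 0)) stop("H must be > 0")
  tau <- k$phi * LMA * (k$c_pw / LDMC + (k$c_pd - k$c_pw)) / H
  data.frame(tau = tau, H = H)
}
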