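#' Specify a trait-substitution counterfactual
#'
#' @param base_leaf Leaf identifier of the base leaf.
#' @param donor_species Species whose traits are substituted in; must differ
#'   from the base leaf's species.
#' @param components Character vector, non-empty subset of
#'   `c("width", "gs_intercept", "gs_slope")`.
#' @param label Optional variant label; defaults to the components joined
#'   with `+`.
#' @return A list of class `swap_spec`.
#' @export
swap_spec <- function(base_leaf, donor_species, components, label = NULL) {
  allowed <- c("width", "gs_intercept", "gs_slope")
  if (length(components) == 0L || !all(components %in% allowed)) {
    stop("components must be a non-empty subset of: ",
         paste(allowed, collapse = ", "))
  }
  structure(list(base_leaf = base_leaf, donor_species = donor_species,
                 components = unique(components),
                 label = label %||% paste(unique(components), collapse = "+")),
            class = "swap_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-predict leaf temperature excess under substituted traits
#'
#' Counterfactual re-prediction of the leaf-to-air temperature difference
#' for a base leaf with donor-species traits substituted: leaf width, the
#' g_s-D intercept, the g_s-D slope, or any combination. The base leaf's
#' own microclimate stream (its height and exposure) is retained. The base
#' variant is always included.
#'
#' @param specs A `swap_spec` or a list of them (all sharing the base leaf).
#' @param microclimate Data frame of the base leaf's microclimate with
#'   columns `time`, `PAR`, `T_A`, `h`, `U`, `D`.
#' @param params A `stomatal_params` fit from [fit_gs_D_model()].
#' @param traits Leaf-trait table with `leaf_id`, `species`, `width_m`.
#' @param k,p,rcfg,kt Constants as in [leaf_air_temperature_difference()];
#'   `p` should carry the base species' (possibly recalibrated)
#'   boundary-layer coefficient.
#' @param par_breaks PAR bin edges (umol m^-2 s^-1) for the summary.
#' @return A list with `series` (data frame: `time`, `variant`,
#'   `delta_T_e`) and `summary` (mean `delta_T_e` per PAR bin per variant).
#' @export
run_trait_swap <- function(specs, microclimate, params, traits,
                           k = physical_constants(),
                           p = boundary_layer_params(),
                           rcfg = radiation_config(),
                           kt = tetens_constants(),
                           par_breaks = seq(0, 2000, by = 200)) {
  if (inherits(specs, "swap_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "swap_spec")))
  base_leaf <- specs[[1]]$base_leaf
  stopifnot(all(vapply(specs, function(s) s$base_leaf, "") == base_leaf))
  bt <- traits[traits$leaf_id == base_leaf, , drop = FALSE]
  if (nrow(bt) != 1L) stop("base leaf not found in traits: ", base_leaf)
  base_species <- as.character(bt$species)
  off_i <- match(base_leaf, params$leaf_offsets$leaf_id)
  offset <- if (is.na(off_i)) 0 else params$leaf_offsets$offset[off_i]
  sp_row <- function(sp) {
    r <- params$species[params$species$species == sp, , drop = FALSE]
    if (nrow(r) != 1L) stop("species missing from stomatal fit: ", sp)
    r
  }
  base_par <- sp_row(base_species)
  donor_width <- function(sp) {
    w <- traits$width_m[traits$species == sp]
    if (length(w) == 0L) stop("no donor traits for species: ", sp)
    mean(w)
  }
  variant_eval <- function(W, intercept, slope) {
    g_s_mmol <- pmax(params$g_min, intercept + offset + slope * microclimate$D)
    g_s_vel <- gs_to_velocity(g_s_mmol, microclimate$T_A, k$P_atm)
    leaf_air_temperature_difference(
      PAR = microclimate$PAR, T_A = microclimate$T_A, h = microclimate$h,
      U = microclimate$U, W = W, g_s = g_s_vel,
      k = k, p = p, rcfg = rcfg, kt = kt)$delta_T_e
  }
  variants <- list(base = variant_eval(bt$width_m, base_par$intercept,
                                       base_par$slope))
  for (s in specs) {
    if (s$donor_species == base_species) {
      stop("donor species must differ from the base leaf's species")
    }
    dp <- sp_row(s$donor_species)
    W <- if ("width" %in% s$components) donor_width(s$donor_species)
         else bt$width_m
    intercept <- if ("gs_intercept" %in% s$components) dp$intercept
                 else base_par$intercept
    slope <- if ("gs_slope" %in% s$components) dp$slope else base_par$slope
    variants[[s$label]] <- variant_eval(W, intercept, slope)
  }
  series <- do.call(rbind, lapply(names(variants), function(v) {
    data.frame(time = microclimate$time, variant = v,
               delta_T_e = variants[[v]])
  }))
  bin <- cut(microclimate$PAR, breaks = par_breaks, right = FALSE)
  summ <- do.call(rbind, lapply(names(variants), function(v) {
    agg <- tapply(variants[[v]], bin, mean)
    ok <- !is.na(agg)
    data.frame(variant = v, par_bin = names(agg)[ok],
               mean_delta_T_e = as.numeric(agg[ok]),
               n = as.integer(table(bin)[ok]))
  }))
  rownames(series) <- rownames(summ) <- NULL
  list(series = series, summary = summ)
}
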