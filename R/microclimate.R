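#' Saturation vapour pressure (Tetens form)
#'
#' \eqn{e_{sat} = a \exp(b T_A / (T_A + c))} in kPa.
#'
#' @param T_A Air temperature (degrees C); must exceed `-k$c`.
#' @param k [tetens_constants()].
#' @return Saturation vapour pressure (kPa), vectorised over `T_A`.
#' @export
#' @examples
#' saturation_vapour_pressure(0)   # equals the leading coefficient, 0.611 kPa
#' saturation_vapour_pressure(20)
saturation_vapour_pressure <- function(T_A, k = tetens_constants()) {
  if (any(!is.finite(T_A)) || any(T_A <= -k$c)) {
    stop("T_A must be finite and greater than -c (", -k$c, " degrees C)")
  }
  k$a * exp(k$b * T_A / (T_A + k$c))
}

#' Vapour pressure deficit
#'
#' \eqn{D = e_{sat}(T_A) (1 - h)} in kPa, with relative humidity `h` as a
#' proportion.
#'
#' @param T_A Air temperature (degrees C).
#' @param h Relative humidity as a proportion in \[0, 1\].
#' @param k [tetens_constants()].
#' @return Vapour pressure deficit (kPa).
#' @export
vapour_pressure_deficit <- function(T_A, h, k = tetens_constants()) {
  if (any(h < 0 | h > 1, na.rm = TRUE)) {
    stop("relative humidity h must lie in [0, 1]")
  }
  saturation_vapour_pressure(T_A, k) * (1 - h)
}

#' Slope of the saturation vapour pressure curve
#'
#' Analytic derivative of the Tetens curve with respect to temperature,
#' evaluated at `T_A`, in Pa/K:
#' \eqn{s = 1000\, e_{sat}\, b c / (T_A + c)^2}.
#'
#' @inheritParams saturation_vapour_pressure
#' @return Slope (Pa/K).
#' @export
svp_slope <- function(T_A, k = tetens_constants()) {
  1000 * saturation_vapour_pressure(T_A, k) * k$b * k$c / (T_A + k$c)^2
}

#' Fit per-height humidity gap-fill models
#'
#' Ordinary least squares of relative humidity on air temperature, fitted
#' separately at every humidity-sensor height. Used to reconstruct humidity
#' (and hence vapour pressure deficit) for periods when the humidity sensors
#' were not recording, exploiting the tight negative coupling between air
#' temperature and relative humidity within the canopy.
#'
#' Heights with fewer than `min_n` paired observations, or with no variance
#' in `T_A`, are refused with a warning and omitted from the model.
#'
#' @param records Data frame with columns `height`, `T_A`, `h` (rows with
#'   missing `h` are ignored).
#' @param min_n Minimum number of paired observations per height.
#' @return A data frame of class `humidity_model` with one row per fitted
#'   height: `height`, `intercept`, `slope`, `r_squared`, `n`.
#' @export
fit_humidity_model <- function(records, min_n = 10) {
  stopifnot(all(c("height", "T_A", "h") %in% names(records)))
  ok <- !is.na(records$h) & !is.na(records$T_A)
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0L) stop("no paired (T_A, h) observations")
  fits <- lapply(split(records, records$height), function(d) {
    z <- d$height[1]
    if (nrow(d) < min_n) {
      warning("height ", z, ": only ", nrow(d), " paired observations; ",
              "refusing fit")
      return(NULL)
    }
    if (stats::sd(d$T_A) == 0) {
      warning("height ", z, ": zero variance in T_A; refusing fit")
      return(NULL)
    }
    fit <- stats::lm(h ~ T_A, data = d)
    # noise-free input triggers lm's perfect-fit warning; R^2 = 1 is valid
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(height = z,
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               r_squared = r2,
               n = nrow(d))
  })
  out <- do.call(rbind, fits)
  if (is.null(out) || nrow(out) == 0L) stop("no height could be fitted")
  rownames(out) <- NULL
  class(out) <- c("humidity_model", class(out))
  out
}

#' Gap-fill missing relative humidity from air temperature
#'
#' Fills missing `h` using the per-height linear model from
#' [fit_humidity_model()]. Records take the model of the nearest fitted
#' humidity-sensor height. Predictions are clipped to `[0.01, 1]` so the
#' derived vapour pressure deficit stays defined; `D` is recomputed for all
#' rows and `h_source` is set to `"measured"` or `"gap_filled"`.
#'
#' @param records Data frame with columns `height`, `T_A`, `h` (possibly NA).
#' @param model A `humidity_model` from [fit_humidity_model()].
#' @param k [tetens_constants()] for the recomputation of `D`.
#' @return `records` with `h` complete and columns `h_source` and `D` set.
#' @export
gap_fill_humidity <- function(records, model, k = tetens_constants()) {
  stopifnot(inherits(model, "humidity_model"), nrow(model) > 0)
  miss <- is.na(records$h)
  src <- if ("h_source" %in% names(records)) records$h_source else
    rep("measured", nrow(records))
  src[!miss] <- "measured"
  if (any(miss)) {
    idx <- vapply(records$height[miss],
                  function(z) which.min(abs(model$height - z)), integer(1))
    pred <- model$intercept[idx] + model$slope[idx] * records$T_A[miss]
    records$h[miss] <- pmin(1, pmax(0.01, pred))
    src[miss] <- "gap_filled"
  }
  records$h_source <- src
  records$D <- vapour_pressure_deficit(records$T_A, records$h, k)
  records
}

#' Wind speed at an arbitrary height
#'
#' Linear interpolation of wind speed between anemometer heights. Heights
#' below the lowest sensor take the lowest sensor's value, heights above the
#' highest take the highest sensor's value (clamped, not extrapolated).
#'
#' @param profile Data frame with columns `height` and `U`, one row per
#'   anemometer (a single time slice), or a named numeric vector with heights
#'   as names.
#' @param z Height(s) (m) at which wind speed is wanted.
#' @return Wind speed(s) (m/s) at `z`.
#' @export
wind_at_height <- function(profile, z) {
  if (is.numeric(profile) && !is.null(names(profile))) {
    profile <- data.frame(height = as.numeric(names(profile)), U = unname(profile))
  }
  stopifnot(all(c("height", "U") %in% names(profile)))
  profile <- profile[order(profile$height), , drop = FALSE]
  if (nrow(profile) == 0L) stop("empty wind profile")
  if (nrow(profile) == 1L) return(rep_len(profile$U, length(z)))
  stats::approx(profile$height, profile$U, xout = z, rule = 2, ties = mean)$y
}

#' Derive vapour pressure deficit on a microclimate table
#'
#' Adds the derived column `D` (kPa) and, when absent, an `h_source` flag,
#' leaving measured values untouched.
#'
#' @param records Data frame with at least `T_A` and `h` columns.
#' @param k [tetens_constants()].
#' @return `records` with `D` and `h_source` columns.
#' @export
derive_microclimate <- function(records, k = tetens_constants()) {
  stopifnot(all(c("T_A", "h") %in% names(records)))
  records$D <- vapour_pressure_deficit(records$T_A, records$h, k)
  if (!"h_source" %in% names(records)) {
    records$h_source <- ifelse(is.na(records$h), NA_character_, "measured")
  }
  records
}
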