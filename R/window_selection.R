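#' Window-regression data-selection filter
#'
#' Splits each leaf's daytime series into fixed-width windows aligned to
#' clock boundaries and, within each window, regresses the energy-balance
#' prediction on the observation by ordinary least squares. A window is
#' selected when its slope lies in `slope_band`, its intercept in
#' `intercept_band` (degrees C), and it holds at least `n_min` points.
#' Windows where predicted and observed temperature differences agree
#' certify that the radiation measured at the tower represented the leaf
#' surface; mismatched windows (typically sunfleck/shade mismatch) are
#' rejected.
#'
#' @param data Data frame with columns `time` (POSIXct), `dT_obs`, `dT_est`,
#'   optionally `leaf_id` (windows are per leaf) and `daytime` (logical;
#'   non-daytime rows are never selected and not windowed).
#' @param width_min Window width in minutes.
#' @param n_min Minimum number of points per window; at the 10 s native
#'   cadence 60 is half a full 20-minute window, and should be scaled with
#'   the data cadence.
#' @param slope_band Acceptance interval for the window slope.
#' @param intercept_band Acceptance interval for the window intercept
#'   (degrees C).
#' @return A list with `diagnostics` (data frame: `window_start`, `leaf_id`,
#'   `slope`, `intercept`, `n_points`, `selected`, `reason`) and `mask`, a
#'   logical vector over the rows of `data` marking records of selected
#'   windows.
#' @export
select_windows <- function(data, width_min = 20, n_min = 60,
                           slope_band = c(0.7, 1.3),
                           intercept_band = c(-2, 2)) {
  stopifnot(all(c("time", "dT_obs", "dT_est") %in% names(data)))
  n <- nrow(data)
  leaf <- if ("leaf_id" %in% names(data)) as.character(data$leaf_id)
          else rep("leaf", n)
  day <- if ("daytime" %in% names(data)) data$daytime else rep(TRUE, n)
  width_s <- width_min * 60
  wstart <- as.POSIXct(floor(as.numeric(data$time) / width_s) * width_s,
                       origin = "1970-01-01", tz = "UTC")
  mask <- rep(FALSE, n)
  key <- paste(leaf, as.numeric(wstart))
  idx_day <- which(day)
  groups <- split(idx_day, key[idx_day])
  diag_rows <- lapply(groups, function(ix) {
    d <- data[ix, , drop = FALSE]
    row <- data.frame(window_start = wstart[ix[1]], leaf_id = leaf[ix[1]],
                      slope = NA_real_, intercept = NA_real_,
                      n_points = length(ix), selected = FALSE,
                      reason = "")
    if (length(ix) < n_min) {
      row$reason <- "too_few_points"
      return(row)
    }
    if (stats::sd(d$dT_obs) == 0) {
      row$reason <- "zero_variance"
      return(row)
    }
    fit <- stats::lm(dT_est ~ dT_obs, data = d)
    cf <- stats::coef(fit)
    row$intercept <- unname(cf[1])
    row$slope <- unname(cf[2])
    row$selected <- row$slope >= slope_band[1] & row$slope <= slope_band[2] &
      row$intercept >= intercept_band[1] & row$intercept <= intercept_band[2]
    row$reason <- if (row$selected) "selected" else "gate_failed"
    row
  })
  diagnostics <- do.call(rbind, diag_rows)
  if (is.null(diagnostics)) {
    diagnostics <- data.frame(window_start = as.POSIXct(character(0)),
                              leaf_id = character(0), slope = numeric(0),
                              intercept = numeric(0), n_points = integer(0),
                              selected = logical(0), reason = character(0))
  } else {
    rownames(diagnostics) <- NULL
    sel_keys <- paste(diagnostics$leaf_id,
                      as.numeric(diagnostics$window_start))[diagnostics$selected]
    mask <- key %in% sel_keys & day
  }
  diagnostics <- diagnostics[order(diagnostics$leaf_id,
                                   diagnostics$window_start), ]
  rownames(diagnostics) <- NULL
  list(diagnostics = diagnostics, mask = mask)
}

#' Subset leaf records by microclimate bin
#'
#' Keeps records whose PAR, air temperature and wind speed all fall in the
#' half-open ranges `[lo, hi)` of the bin. If the data carry a `selected`
#' column (from [select_windows()]), unselected rows are dropped first.
#'
#' @param data Data frame with columns `PAR`, `T_A`, `U` (and optionally
#'   `selected`).
#' @param bin A list with elements `par`, `ta`, `u`, each `c(lo, hi)`, and
#'   optionally `label`.
#' @return The subset (possibly zero rows).
#' @export
subset_by_microclimate <- function(data, bin) {
  stopifnot(all(c("PAR", "T_A", "U") %in% names(data)),
            all(c("par", "ta", "u") %in% names(bin)))
  if ("selected" %in% names(data)) data <- data[data$selected, , drop = FALSE]
  keep <- data$PAR >= bin$par[1] & data$PAR < bin$par[2] &
    data$T_A >= bin$ta[1] & data$T_A < bin$ta[2] &
    data$U >= bin$u[1] & data$U < bin$u[2]
  data[keep & !is.na(keep), , drop = FALSE]
}

#' Species contrast in leaf temperature excess
#'
#' Mixed-effects model of the leaf-to-air temperature difference on species
#' with a random intercept per leaf, returning the fixed-effect species
#' contrasts (relative to the first species level) with standard errors and
#' p-values. When the mixed fit cannot be estimated (e.g. one observation
#' per leaf) the function falls back to ordinary least squares with a
#' warning.
#'
#' @param data Data frame with columns `leaf_id`, `species`, `dT`.
#' @return A list with `contrasts` (data frame: `term`, `estimate`, `se`,
#'   `df`, `p`), `method` (`"lme"` or `"ols"`), and the underlying `fit`.
#' @export
compare_species <- function(data) {
  stopifnot(all(c("leaf_id", "species", "dT") %in% names(data)))
  data <- data[stats::complete.cases(data[c("leaf_id", "species", "dT")]), ]
  data$species <- factor(data$species)
  data$leaf_id <- factor(data$leaf_id)
  if (nlevels(data$species) < 2L) stop("need at least 2 species")
  leaves_per_sp <- tapply(data$leaf_id, data$species,
                          function(x) length(unique(x)))
  if (any(leaves_per_sp < 2L)) stop("need at least 2 leaves per species")
  method <- "lme"
  fit <- tryCatch(
    nlme::lme(dT ~ species, random = ~ 1 | leaf_id, data = data,
              method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed-effects fit failed; falling back to ordinary least squares")
    method <- "ols"
    fit <- stats::lm(dT ~ species, data = data)
  }
  if (method == "lme") {
    tt <- summary(fit)$tTable
    keep <- grep("^species", rownames(tt))
    contrasts <- data.frame(term = rownames(tt)[keep],
                            estimate = tt[keep, "Value"],
                            se = tt[keep, "Std.Error"],
                            df = tt[keep, "DF"],
                            p = tt[keep, "p-value"])
  } else {
    tt <- summary(fit)$coefficients
    keep <- grep("^species", rownames(tt))
    contrasts <- data.frame(term = rownames(tt)[keep],
                            estimate = tt[keep, "Estimate"],
                            se = tt[keep, "Std. Error"],
                            df = stats::df.residual(fit),
                            p = tt[keep, "Pr(>|t|)"])
  }
  rownames(contrasts) <- NULL
  list(contrasts = contrasts, method = method, fit = fit)
}

#' Marginal and conditional pseudo R-squared for a mixed model
#'
#' Variance-decomposition pseudo R-squared for linear mixed models:
#' marginal uses the fixed-effect variance only,
#' `var_f / (var_f + var_r + var_e)`; conditional adds the random-effect
#' variance to the numerator. For an ordinary `lm`, both reduce to the
#' classical R-squared.
#'
#' @param fit An `lme` fit (or an `lm`, for which `var_r = 0`).
#' @return Named numeric vector with elements `marginal` and `conditional`.
#' @export
pseudo_r_squared <- function(fit) {
  if (inherits(fit, "lme")) {
    var_f <- stats::var(as.numeric(stats::predict(fit, level = 0)))
    vc <- nlme::VarCorr(fit)
    var_r <- sum(as.numeric(vc[-nrow(vc), "Variance"]))
    var_e <- fit$sigma^2
  } else if (inherits(fit, "lm")) {
    var_f <- stats::var(stats::fitted(fit))
    var_r <- 0
    var_e <- summary(fit)$sigma^2
  } else {
    stop("unsupported model class")
  }
  denom <- var_f + var_r + var_e
  c(marginal = var_f / denom, conditional = (var_f + var_r) / denom)
}

#' Per-leaf day/night temperature summaries
#'
#' Minimum, mean, maximum and adjusted Fisher-Pearson sample skewness of
#' leaf temperature and leaf-to-air temperature difference, per leaf and
#' day/night period. Skewness of a constant (zero-variance) series is
#' reported as missing.
#'
#' @param data Data frame with columns `leaf_id`, `T_L`, `dT`, and `daytime`
#'   (logical).
#' @return Data frame with one row per leaf x period and columns
#'   `leaf_id`, `period`, and `<var>_min/_mean/_max/_skew` for `T_L` and
#'   `dT`.
#' @export
daily_summaries <- function(data) {
  stopifnot(all(c("leaf_id", "T_L", "dT", "daytime") %in% names(data)))
  skew <- function(x) {
    if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
    e1071::skewness(x, type = 2)
  }
  period <- ifelse(data$daytime, "day", "night")
  groups <- split(data, list(data$leaf_id, period), drop = TRUE)
  rows <- lapply(groups, function(d) {
    data.frame(leaf_id = as.character(d$leaf_id[1]),
               period = ifelse(d$daytime[1], "day", "night"),
               n = nrow(d),
               T_L_min = min(d$T_L), T_L_mean = mean(d$T_L),
               T_L_max = max(d$T_L), T_L_skew = skew(d$T_L),
               dT_min = min(d$dT), dT_mean = mean(d$dT),
               dT_max = max(d$dT), dT_skew = skew(d$dT))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$leaf_id, out$period), ]
}

#' Linear regression forced through the origin
#'
#' Slope `sum(x*y) / sum(x^2)` with its standard error and 95% confidence
#' interval from the no-intercept model.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `slope`, `se`, `ci` (length-2), `n`.
#' @export
regression_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (all(x == 0)) stop("all x are zero; slope undefined")
  fit <- stats::lm(y ~ 0 + x)
  # a zero-residual fit warns about reliability; the closed form is exact
  ci <- suppressWarnings(suppressMessages(stats::confint(fit, level = 0.95)))
  se <- suppressWarnings(summary(fit)$coefficients[1, 2])
  list(slope = unname(stats::coef(fit)[1]),
       se = se, ci = as.numeric(ci[1, ]), n = length(x))
}
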