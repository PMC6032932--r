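#' Bin inverted boundary-layer resistances by wind speed
#'
#' Summarises inverted `r_b_W` values in half-open wind-speed bins
#' `[lo, lo + bin_width)`, excluding records with `PAR < par_min` and,
#' within each bin, values outside the Tukey fences
#' (`fence_k` times the interquartile range beyond the quartiles).
#'
#' @param data Data frame with columns `U`, `r_b_W`, `PAR` and optionally
#'   `flag` (rows whose flag is not `"ok"` are dropped first).
#' @param bin_width Wind-speed bin width (m/s).
#' @param par_min Minimum PAR (umol m^-2 s^-1) for inclusion; low-light
#'   records carry little energy-balance signal.
#' @param fence_k Tukey fence multiplier.
#' @return Data frame with `bin_lo`, `bin_hi`, `mean`, `sd`, `n` per
#'   non-empty bin (possibly zero rows if every record is excluded).
#' @export
bin_resistances <- function(data, bin_width = 0.1, par_min = 200,
                            fence_k = 1.5) {
  stopifnot(all(c("U", "r_b_W", "PAR") %in% names(data)))
  if (nrow(data) == 0L) stop("empty resistance stream")
  if ("flag" %in% names(data)) data <- data[data$flag == "ok", , drop = FALSE]
  data <- data[!is.na(data$r_b_W) & data$PAR >= par_min, , drop = FALSE]
  if (nrow(data) == 0L) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0)))
  }
  lo <- floor(data$U / bin_width) * bin_width
  rows <- lapply(split(data$r_b_W, lo), function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    keep <- v >= q[1] - fence_k * iqr & v <= q[2] + fence_k * iqr
    v <- v[keep]
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  out <- do.call(rbind, rows)
  out$bin_lo <- as.numeric(names(rows))
  out$bin_hi <- out$bin_lo + bin_width
  rownames(out) <- NULL
  out[order(out$bin_lo), c("bin_lo", "bin_hi", "mean", "sd", "n")]
}

# Drop per-wind-bin Tukey-fence outliers from an inverted-resistance table
# (same exclusion rule bin_resistances applies before summarising).
exclude_resistance_outliers <- function(data, bin_width = 0.1,
                                        fence_k = 1.5) {
  lo <- floor(data$U / bin_width) * bin_width
  keep <- unsplit(lapply(split(data$r_b_W, lo), function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    v >= q[1] - fence_k * iqr & v <= q[2] + fence_k * iqr
  }), lo)
  data[keep, , drop = FALSE]
}

#' Recalibrate boundary-layer conductance constants
#'
#' Nonlinear least squares of inverted boundary-layer resistances on wind
#' speed and leaf width, re-estimating the constants of the power-law
#' conductance model. On the resistance scale (the default) the fitted
#' model is
#' \deqn{r_{b,W} = 1 / (gbw\_ratio \cdot a (U/W)^b),}
#' with `b` fixed at 0.5 in the one-parameter model and free in the
#' two-parameter model. Fitting on the conductance scale
#' (`scale = "conductance"`) regresses `1/r_b_W` on the same power law.
#'
#' @param data Data frame with columns `U`, `W`, `r_b_W` (rows with missing
#'   `r_b_W` are dropped).
#' @param model `"one_param"` (b fixed at 0.5) or `"two_param"`.
#' @param scale Fit on the `"resistance"` (default) or `"conductance"` scale.
#' @param gbw_ratio Water/heat conductance ratio held inside the model.
#' @param start Starting values, a list with `a` and `b`.
#' @param maxiter Maximum Gauss-Newton iterations.
#' @return A list of class `calibration_fit`: `model`, `a`, `a_se`, `b`,
#'   `b_se` (NA for one-parameter), `n_points`, `residual_sd`, `fit` (the
#'   underlying `nls` object).
#' @export
fit_boundary_constants <- function(data, model = c("one_param", "two_param"),
                                   scale = c("resistance", "conductance"),
                                   gbw_ratio = 1.08,
                                   start = list(a = 0.0105, b = 0.5),
                                   maxiter = 200) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  stopifnot(all(c("U", "W", "r_b_W") %in% names(data)))
  data <- data[!is.na(data$r_b_W), , drop = FALSE]
  if (nrow(data) < 5L) stop("need at least 5 points to calibrate")
  if (any(data$U <= 0) || any(data$W <= 0)) stop("U and W must be > 0")
  d <- data.frame(x = data$U / data$W,
                  y = if (scale == "resistance") data$r_b_W else 1 / data$r_b_W)
  rhs_r <- function() if (model == "one_param")
    y ~ 1 / (gbw_ratio * a * x^0.5) else y ~ 1 / (gbw_ratio * a * x^b)
  rhs_g <- function() if (model == "one_param")
    y ~ gbw_ratio * a * x^0.5 else y ~ gbw_ratio * a * x^b
  form <- if (scale == "resistance") rhs_r() else rhs_g()
  st <- if (model == "one_param") start["a"] else start[c("a", "b")]
  fit <- tryCatch(
    stats::nls(form, data = d, start = st,
               control = stats::nls.control(maxiter = maxiter,
                                            scaleOffset = 1,
                                            warnOnly = FALSE)),
    error = function(e) stop("boundary-constant fit did not converge: ",
                             conditionMessage(e)))
  sm <- summary(fit)
  co <- sm$coefficients
  out <- list(model = model, scale = scale,
              a = co["a", "Estimate"], a_se = co["a", "Std. Error"],
              b = if (model == "two_param") co["b", "Estimate"] else 0.5,
              b_se = if (model == "two_param") co["b", "Std. Error"] else NA_real_,
              n_points = nrow(d), residual_sd = sm$sigma, fit = fit)
  class(out) <- "calibration_fit"
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Boundary-layer calibration (", x$model, ", ", x$scale, " scale)\n",
      sep = "")
  cat(sprintf("  a = %.5g (SE %.3g)\n", x$a, x$a_se))
  if (x$model == "two_param") {
    cat(sprintf("  b = %.4g (SE %.3g)\n", x$b, x$b_se))
  } else {
    cat("  b = 0.5 (fixed)\n")
  }
  cat(sprintf("  n = %d, residual SD = %.4g\n", x$n_points, x$residual_sd))
  invisible(x)
}
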