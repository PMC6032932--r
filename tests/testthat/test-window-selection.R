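mk_series <- function(n = 120, slope = 1, intercept = 0, noise = 0,
                      seed = 1, start = "2016-10-01 10:00:00") {
  withr::with_seed(seed, {
    time <- as.POSIXct(start, tz = "UTC") + seq(0, by = 10,
                                                length.out = n)
    obs <- runif(n, 0, 5)
    data.frame(time = time, dT_obs = obs,
               dT_est = intercept + slope * obs + rnorm(n, 0, noise))
  })
}

test_that("window gates pass agreement and reject offsets and bad slopes", {
  sel <- select_windows(mk_series(), n_min = 60)
  expect_equal(nrow(sel$diagnostics), 1L)
  expect_equal(sel$diagnostics$slope, 1)
  expect_equal(sel$diagnostics$intercept, 0)
  expect_true(sel$diagnostics$selected)
  expect_true(all(sel$mask))

  off <- select_windows(mk_series(intercept = 5), n_min = 60)
  expect_false(off$diagnostics$selected)
  expect_equal(off$diagnostics$intercept, 5)

  steep <- select_windows(mk_series(slope = 1.4, noise = 0.1, seed = 2),
                          n_min = 60)
  expect_false(steep$diagnostics$selected)
  ok <- select_windows(mk_series(slope = 1.2, noise = 0.1, seed = 2),
                       n_min = 60)
  expect_true(ok$diagnostics$selected)
})

test_that("windows are clock-aligned, per leaf, and small ones are rejected", {
  # 40 min of data starting at 10:05 spans three clock windows; the last
  # holds only 5 min of points and is rejected for size
  a <- mk_series(n = 240, start = "2016-10-01 10:05:00")
  a$leaf_id <- "L1"
  sel <- select_windows(a, n_min = 60)
  expect_equal(nrow(sel$diagnostics), 3L)
  expect_equal(sum(sel$diagnostics$reason == "too_few_points"), 1L)
  expect_equal(sel$diagnostics$n_points, c(90L, 120L, 30L))
  expect_equal(as.numeric(sel$diagnostics$window_start) %% 1200,
               rep(0, 3))
  # rejected-window records are not masked
  expect_equal(sum(sel$mask),
               sum(sel$diagnostics$n_points[sel$diagnostics$selected]))
})

test_that("selection is idempotent on an already-selected stream", {
  d <- rbind(transform(mk_series(seed = 4), leaf_id = "L1"),
             transform(mk_series(intercept = 5, seed = 5,
                                 start = "2016-10-01 11:00:00"),
                       leaf_id = "L1"))
  s1 <- select_windows(d, n_min = 60)
  d2 <- d[s1$mask, ]
  s2 <- select_windows(d2, n_min = 60)
  expect_true(all(s2$mask))
  expect_equal(s2$diagnostics$window_start,
               s1$diagnostics$window_start[s1$diagnostics$selected])
})

test_that("microclimate subsetting uses half-open ranges", {
  d <- data.frame(PAR = c(999, 1000, 1299, 1300), T_A = 19, U = 1,
                  dT = 1:4)
  bin <- list(par = c(1000, 1300), ta = c(18, 20), u = c(0.5, 1.5))
  out <- subset_by_microclimate(d, bin)
  expect_equal(out$dT, 2:3)     # hi boundary excluded, lo included
  empty <- subset_by_microclimate(d, list(par = c(5000, 6000),
                                          ta = c(18, 20), u = c(0.5, 1.5)))
  expect_equal(nrow(empty), 0L)
  # brute-force recount on a random table
  set.seed(6)
  big <- data.frame(PAR = runif(500, 0, 2000), T_A = runif(500, 10, 25),
                    U = runif(500, 0, 3))
  got <- nrow(subset_by_microclimate(big, bin))
  want <- sum(big$PAR >= 1000 & big$PAR < 1300 & big$T_A >= 18 &
                big$T_A < 20 & big$U >= 0.5 & big$U < 1.5)
  expect_equal(got, want)
  # a `selected` column is honoured first
  d$selected <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(subset_by_microclimate(d, bin)$dT, 3)
})

test_that("species contrast recovers a known temperature offset", {
  set.seed(12)
  sim <- do.call(rbind, lapply(1:10, function(i) {
    sp <- if (i <= 5) "A" else "B"
    mu <- if (sp == "A") 0 else 1.5
    data.frame(leaf_id = paste0("L", i), species = sp,
               dT = mu + rnorm(1, 0, 0.3) + rnorm(30, 0, 0.5))
  }))
  res <- compare_species(sim)
  expect_equal(res$method, "lme")
  expect_lt(abs(res$contrasts$estimate - 1.5), 2 * res$contrasts$se)
  expect_lt(res$contrasts$p, 0.01)

  expect_error(compare_species(sim[sim$species == "A", ]), "2 species")
  expect_error(compare_species(sim[sim$leaf_id %in% c("L1", "L6", "L7"), ]),
               "2 leaves")
  # one observation per leaf still yields a contrast (possibly by fallback)
  single <- sim[!duplicated(sim$leaf_id), ]
  res1 <- suppressWarnings(compare_species(single))
  expect_true(is.finite(res1$contrasts$estimate))
})

test_that("pseudo R-squared decomposes variance as Nakagawa-Schielzeth", {
  set.seed(13)
  # zero random-effect variance: lm path, marginal equals conditional
  x <- rnorm(200); y <- 2 * x + rnorm(200)
  fit_lm <- lm(y ~ x)
  r2 <- pseudo_r_squared(fit_lm)
  expect_equal(unname(r2["marginal"]), unname(r2["conditional"]))
  expect_equal(unname(r2["marginal"]), summary(fit_lm)$r.squared,
               tolerance = 0.01)

  # known variance components: fixed 1.5^2/4 between two balanced species,
  # leaf variance 0.09, residual 1
  sim <- do.call(rbind, lapply(1:200, function(i) {
    sp <- if (i <= 100) "A" else "B"
    mu <- if (sp == "A") 0 else 1.5
    data.frame(leaf_id = paste0("L", i), species = sp,
               dT = mu + rnorm(1, 0, 0.3) + rnorm(20, 0, 1))
  }))
  fit <- nlme::lme(dT ~ species, random = ~ 1 | leaf_id, data = sim)
  r2m <- pseudo_r_squared(fit)
  var_f <- var(c(rep(0, 1000), rep(1.5, 1000)))
  want_m <- var_f / (var_f + 0.09 + 1)
  want_c <- (var_f + 0.09) / (var_f + 0.09 + 1)
  expect_equal(unname(r2m["marginal"]), want_m, tolerance = 0.15)
  expect_equal(unname(r2m["conditional"]), want_c, tolerance = 0.15)
  expect_lte(r2m["marginal"], r2m["conditional"])
  expect_lte(r2m["conditional"], 1)
})

test_that("daily summaries report extremes and adjusted skewness", {
  withr::with_seed(21, {
    sym <- rnorm(10000)
    d <- data.frame(leaf_id = "L1", T_L = sym + 15, dT = sym,
                    daytime = TRUE)
    s <- daily_summaries(d)
    expect_lt(abs(s$dT_skew), 0.05)
    expect_equal(s$dT_min, min(sym))

    ex <- rexp(5000) - 1
    d2 <- data.frame(leaf_id = "L2", T_L = ex + 15, dT = ex,
                     daytime = FALSE)
    s2 <- daily_summaries(d2)
    expect_equal(s2$period, "night")
    expect_gt(s2$dT_skew, 0.5)
    expect_equal(s2$dT_skew, oracle_skewness(ex), tolerance = 1e-10)

    cst <- data.frame(leaf_id = "L3", T_L = 15, dT = rep(0.5, 10),
                      daytime = TRUE)
    s3 <- daily_summaries(cst)
    expect_equal(s3$dT_min, s3$dT_max)
    expect_true(is.na(s3$dT_skew))
  })
})

test_that("regression through the origin matches its closed form", {
  x <- c(1, 2, 3, 4); y <- x
  r <- regression_through_origin(x, y)
  expect_equal(r$slope, 1)
  expect_equal(r$se, 0)
  withr::with_seed(31, {
    x <- runif(2000, 0, 10)
    y <- 0.91 * x + rnorm(2000, 0, 0.3)
    r2 <- regression_through_origin(x, y)
    expect_equal(r2$slope, sum(x * y) / sum(x^2))
    expect_lt(r2$ci[2], 1)     # CI excludes the 1:1 line at large n
  })
  expect_error(regression_through_origin(c(0, 0), c(1, 2)), "slope undefined")
})
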