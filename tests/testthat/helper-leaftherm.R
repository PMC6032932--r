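# Independent evaluation of the steady-state leaf energy balance, written
# directly from the two-term quotient form with its own constants, kept
# separate from the package internals so it can serve as an oracle.
oracle_delta_T <- function(PAR, T_A, h, U, W, g_s_vel, a_bl = 0.0105,
                           P_atm = 90) {
  esat <- 0.611 * exp(17.502 * T_A / (T_A + 240.97))
  D <- 1000 * esat * (1 - h)
  s <- 1000 * esat * 17.502 * 240.97 / (T_A + 240.97)^2
  gam <- 1012 * P_atm * 1000 / (0.622 * 2.45e6)
  rho <- P_atm * 1000 / (287.058 * (T_A + 273.15))
  g_bH <- a_bl * sqrt(pmax(U, 0.05) / W)
  g_bR <- 4 * 0.97 * 5.670374419e-8 * (T_A + 273.15)^3 / (rho * 1012)
  r_bHR <- 1 / (g_bH + g_bR)
  r_W <- 1 / (1.08 * g_bH) + 1 / g_s_vel
  Rni <- 0.5 * (PAR / 4.57) / 0.5
  den <- gam * r_W + s * r_bHR
  r_bHR * gam * r_W * Rni / (rho * 1012 * den) - r_bHR * D / den
}

# Adjusted Fisher-Pearson sample skewness, brute force from moments.
oracle_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

# Small scenario for fast tests.
tiny_scenario <- function(seed = 42, n_days = 1, ...) {
  synthetic_scenario(seed = seed, n_days = n_days, ...)
}

# Random physical leaf/microclimate states for property tests.
random_states <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    PAR = stats::runif(n, 0, 2000),
    T_A = stats::runif(n, 5, 35),
    h = stats::runif(n, 0.2, 0.95),
    U = stats::runif(n, 0.05, 5),
    W = stats::runif(n, 0.02, 0.3),
    g_s_mmol = stats::runif(n, 20, 600)))
}
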