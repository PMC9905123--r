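# Occupancy statistics, boundary locators, specific heat, surface tension.

test_that("occupancy histogram handles degenerate and exact cases", {
  box <- 8
  # empty box: P0 = 1
  empty <- ljphase:::new_configuration(matrix(numeric(0), 0, 3),
                                       matrix(numeric(0), 0, 3), box, 1e-9)
  h <- occupancy_histogram(empty, 2)
  expect_equal(h$p0, 1)
  # lattice matched to the grid: exactly one particle per 2-sigma bin
  g <- seq(1, 7, by = 2)
  lat <- as.matrix(expand.grid(g, g, g))
  cfg <- ljphase:::new_configuration(lat, matrix(0, 64, 3), box, 1)
  h1 <- occupancy_histogram(cfg, 2)
  expect_equal(h1$p0, 0)
  expect_equal(h1$p_k[["1"]], 1)
  expect_equal(sum(h1$p_k), 1, tolerance = 1e-12)
})

test_that("the distribution always sums to one and the grid size is guarded", {
  cfg <- make_fixture("ideal_gas", n = 500, rho_star = 0.3, seed = 1)
  h <- occupancy_histogram(cfg, 2)
  expect_equal(sum(h$p_k), 1, tolerance = 1e-12)
  expect_error(occupancy_histogram(cfg, cfg$box_side / 1.5), "8 bins")
})

test_that("ideal-gas P0 is non-increasing in density (Poisson regime)", {
  rhos <- c(0.05, 0.1, 0.2, 0.4)
  p0 <- vapply(rhos, function(r) {
    mean(vapply(1:20, function(s)
      occupancy_histogram(make_fixture("ideal_gas", n = 1000, rho_star = r,
                                       seed = 1000 + s), 2)$p0, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(p0) < 0))
})

test_that("the liquid-branch locator interpolates the P0 crossing", {
  rho <- seq(0.05, 0.6, by = 0.05)
  p0 <- pmax(0, 0.5 - rho)
  est <- locate_binodal_liquid(rho, p0, threshold = 0.005)
  expect_true(est$defined)
  expect_equal(est$value, 0.495, tolerance = 1e-12)
  # a curve that never crosses: flagged, not fabricated
  flat <- locate_binodal_liquid(rho, rep(0.3, length(rho)), 0.005)
  expect_false(flat$defined)
  expect_true(is.na(flat$value))
})

test_that("the vapor-branch locator finds the growth interval midpoint", {
  rho <- seq(0.01, 0.10, by = 0.01)
  nlar <- c(10, 10, 10, 10, 3500, 3500, 3500, 3500, 3500, 3500) / 4000
  est <- locate_binodal_vapor(rho, nlar)
  expect_true(est$defined)
  expect_equal(est$value, 0.045, tolerance = 1e-12)
  # gently linear curve: no growth spurt above the noise floor
  lin <- locate_binodal_vapor(rho, seq(0.3, 1, length.out = 10))
  expect_false(lin$defined)
})

test_that("the vapor-branch locator picks the steepest log-slope interval", {
  # sigmoid with baseline 10 over n_m = 4000; discrete log-slopes peak on the
  # 0.03-0.04 interval (hand-computed), midpoint 0.035
  rho <- seq(0.01, 0.10, by = 0.01)
  f <- 10 + 3990 / (1 + exp(-(rho - 0.05) / 0.005))
  est <- locate_binodal_vapor(rho, f / 4000)
  expect_true(est$defined)
  expect_equal(est$value, 0.035, tolerance = 1e-12)
})

test_that("specific heat is zero for constant energy and needs 100 frames", {
  frames <- replicate(120, matrix(runif(30, 0, 10), 10, 3), simplify = FALSE)
  traj <- fake_trajectory(frames, 10, pe = rep(-5, 120), ke = rep(3, 120),
                          T_star = 1.0)
  expect_equal(specific_heat(traj)$C_v, 0)
  short <- fake_trajectory(frames[1:50], 10, pe = rep(-5, 50), ke = rep(3, 50))
  expect_error(specific_heat(short), "100")
})

test_that("the low-density spinodal locator follows the tallest-spike rule", {
  rho <- seq(0.02, 0.30, by = 0.02)
  base <- rep(1, length(rho))
  one <- base; one[5] <- 5                      # spike at rho = 0.10
  est <- locate_spinodal_low(rho, one, rho_high = 0.30)
  expect_equal(est$value, rho[5])
  two <- base; two[4] <- 4; two[6] <- 6         # spikes at 0.08 and 0.12
  expect_equal(locate_spinodal_low(rho, two, rho_high = 0.30)$value, rho[6])
  mono <- seq(1, 3, length.out = length(rho))
  expect_false(locate_spinodal_low(rho, mono, rho_high = 0.30)$defined)
})

test_that("the high-density spinodal locator reports growth and C_v drop", {
  rho <- seq(0.30, 0.50, by = 0.01)
  mean_n <- 2 + 3998 / (1 + exp(-(rho - 0.40) / 0.004))
  cv <- 100 - 80 / (1 + exp(-(rho - 0.41) / 0.004))
  est <- suppressWarnings(locate_spinodal_high(rho, mean_n, cv))
  expect_true(est$defined)
  expect_lt(abs(est$value - 0.40), 0.016)        # within ~1.5 grid spacings
  expect_lt(abs(est$cross_check - 0.41), 0.016)
  # inconsistent curves raise the consistency warning
  cv_far <- 100 - 80 / (1 + exp(-(rho - 0.48) / 0.004))
  expect_warning(locate_spinodal_high(rho, mean_n, cv_far), "disagree")
})

test_that("discrete slopes in the locator match a hand computation", {
  rho <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  y <- c(2, 2, 2, 2, 20, 200, 200)
  # log-slopes: 0 x3, log(10)/0.1 on two intervals, 0; first maximal interval
  # is 0.4-0.5, midpoint 0.45
  est <- locate_spinodal_high(rho, y)
  expect_equal(est$value, 0.45, tolerance = 1e-12)
})

test_that("surface tension follows sigma = k_B T / u^2 exactly", {
  s <- sqrt(0.5)
  series <- rep(c(5 + s, 5 - s), 60)   # population variance exactly 0.5
  a <- surface_tension(series, T_star = 1.0)
  expect_true(a$defined)
  expect_equal(a$u_sq, 0.5, tolerance = 1e-12)
  expect_equal(a$sigma_ten, 2.0, tolerance = 1e-12)
  b <- surface_tension(series, T_star = 2.0)
  expect_equal(b$sigma_ten, 4.0, tolerance = 1e-12)  # linear in T
})

test_that("the surface-tension estimator refuses degenerate droplets", {
  expect_false(surface_tension(rep(3, 120), 1.0)$defined)      # constant series
  expect_false(surface_tension(rnorm(50), 1.0)$defined)        # too short
  series <- rnorm(120, 5, 0.1)
  expect_false(surface_tension(series, 1.0, min_size = 50,
                               sizes = rep(20, 120))$defined)  # too small
  expect_false(surface_tension(series, 1.0,
                               spanning = c(rep(FALSE, 119), TRUE))$defined)
})

test_that("estimate_boundaries degrades to flagged-undefined on short grids", {
  tbl <- data.frame(rho_star = c(0.1, 0.2), P0 = c(0.4, 0.2),
                    mean_nlar_norm = c(0.1, 0.5), mean_n = c(2, 5),
                    Cv = c(100, 120))
  est <- estimate_boundaries(tbl, 1.0)
  expect_false(any(est$rho_V_defined, est$rho_sV_defined,
                   est$rho_sL_defined, est$rho_L_defined))
  expect_true(is.na(est$ordering_ok))
})

test_that("estimate_boundaries assembles and validates the four densities", {
  rho <- seq(0.02, 0.80, by = 0.02)
  n_m <- 4000
  nlar <- (20 + (n_m - 20) / (1 + exp(-(rho - 0.06) / 0.005))) / n_m
  mean_n <- 2 + 3000 / (1 + exp(-(rho - 0.40) / 0.005))
  cv <- 100 - 60 / (1 + exp(-(rho - 0.40) / 0.01))
  cv[rho > 0.11 & rho < 0.13] <- 250   # grid-narrow spinodal-entry spike
  p0 <- pmax(0, 0.64 - rho) / 0.64 * 0.5
  tbl <- data.frame(rho_star = rho, P0 = p0, mean_nlar_norm = nlar,
                    mean_n = mean_n, Cv = cv)
  est <- estimate_boundaries(tbl, 1.1)
  expect_true(est$rho_V_defined && est$rho_sV_defined &&
                est$rho_sL_defined && est$rho_L_defined)
  expect_true(est$ordering_ok)
  expect_lt(abs(est$rho_V - 0.06), 0.03)
  expect_lt(abs(est$rho_sV - 0.12), 0.03)
  expect_lt(abs(est$rho_sL - 0.40), 0.03)
  expect_lt(abs(est$rho_L - 0.634), 0.02)
})
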