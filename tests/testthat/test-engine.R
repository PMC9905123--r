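# Force field and integrators.

dimer_config <- function(r, box = 12) {
  ljphase:::new_configuration(
    rbind(c(1, 1, 1), c(1 + r, 1, 1)), matrix(0, 2, 3), box, 2 / box^3)
}

test_that("LJ dimer reproduces the analytic minimum and sigma point", {
  at_min <- pair_energy_forces(dimer_config(2^(1 / 6)), 5)
  expect_equal(at_min$energy, -1, tolerance = 1e-12)
  expect_lt(max(abs(at_min$forces)), 1e-10)
  at_sigma <- pair_energy_forces(dimer_config(1), 5)
  expect_equal(at_sigma$energy, 0, tolerance = 1e-12)
  # repulsive: force magnitude 24 along the bond axis
  expect_equal(at_sigma$forces[1, 1], -24, tolerance = 1e-10)
  expect_equal(at_sigma$forces[2, 1], 24, tolerance = 1e-10)
})

test_that("neighbor-list forces equal the all-pairs oracle (both list paths)", {
  for (case in list(list(n = 60, rho = 0.02, rcut = 2.5),   # cell-grid path
                    list(n = 40, rho = 0.30, rcut = 2.0))) { # all-pairs path
    cfg <- build_configuration(case$n, case$rho, seed = 8)
    got <- pair_energy_forces(cfg, case$rcut)
    want <- oracle_lj(cfg$positions, cfg$box_side, case$rcut)
    expect_equal(got$energy, want$energy, tolerance = 1e-10)
    expect_equal(got$forces, want$forces, tolerance = 1e-8)
    expect_lt(max(abs(colSums(got$forces))), 1e-9)  # Newton's third law
  }
})

test_that("r_cut at or above half the box side is rejected", {
  cfg <- build_configuration(50, 0.5, seed = 1)
  expect_error(pair_energy_forces(cfg, cfg$box_side / 2), "box_side/2")
})

test_that("close approaches trigger the near-singular-force warning", {
  cfg <- ljphase:::new_configuration(
    rbind(c(1, 1, 1), c(1.4, 1, 1)), matrix(0, 2, 3), 10, 2e-3)
  expect_warning(pair_energy_forces(cfg, 4), "0.5 sigma")
})

test_that("bond energy follows k_b (r - sigma)^2", {
  two <- function(r) ljphase:::new_configuration(
    rbind(c(1, 1, 1), c(1 + r, 1, 1)), matrix(0, 2, 3), 12, 2 / 12^3,
    chain_id = c(1L, 1L), chain_length = 2L)
  expect_equal(bond_energy_forces(two(1))$energy, 0, tolerance = 1e-15)
  # k_b = 75000, stretch 0.01 sigma -> 7.5 epsilon
  expect_equal(bond_energy_forces(two(1.01))$energy, 7.5, tolerance = 1e-9)
  expect_error(bond_energy_forces(build_configuration(5, 0.1, seed = 1)),
               "topology")
})

test_that("chain bond energy matches a per-bond summation oracle", {
  set.seed(31)
  box <- 20
  pos <- matrix(runif(30, 0, box), 10, 3)
  cfg <- ljphase:::new_configuration(pos, matrix(0, 10, 3), box, 10 / box^3,
                                     chain_id = rep(1L, 10), chain_length = 10L)
  got <- bond_energy_forces(cfg, k_bond = 75000)
  want <- 0
  for (k in 1:9) {
    d <- min_image_r(pos[k, ] - pos[k + 1, ], box)
    want <- want + 75000 * (sqrt(sum(d * d)) - 1)^2
  }
  expect_equal(got$energy, want, tolerance = 1e-10 * max(1, abs(want)))
})

test_that("a free particle moves in a straight line under NVE", {
  cfg <- ljphase:::new_configuration(matrix(c(2, 3, 4), 1), matrix(c(0.3, -0.2, 0.1), 1),
                                     10, 1e-3)
  tr <- integrate_nve(cfg, sim_params(n_steps = 1000, dt = 0.005, r_cut = 3,
                                      sampling_stride = 100))
  expected <- (c(2, 3, 4) + c(0.3, -0.2, 0.1) * tr$times[10]) %% 10
  expect_equal(as.numeric(tr$positions[[10]]), expected, tolerance = 1e-10)
})

test_that("a dimer at the potential minimum is a fixed point of the dynamics", {
  cfg <- dimer_config(2^(1 / 6))
  tr <- integrate_nve(cfg, sim_params(n_steps = 2000, r_cut = 5,
                                      sampling_stride = 200))
  sep <- vapply(seq_len(n_frames(tr)), function(i) {
    d <- min_image_r(tr$positions[[i]][1, ] - tr$positions[[i]][2, ], 12)
    sqrt(sum(d * d))
  }, numeric(1))
  expect_equal(sep, rep(2^(1 / 6), length(sep)), tolerance = 1e-9)
})

test_that("NVT conserves zero total momentum at every sampled frame", {
  cfg <- build_configuration(80, 0.3, T_star = 1.2, seed = 6)
  tr <- integrate_nvt(cfg, sim_params(n_steps = 2000, r_cut = 2.5,
                                      sampling_stride = 100, seed = 6), 1.2)
  for (i in seq_len(n_frames(tr)))
    expect_lt(max(abs(colSums(tr$velocities[[i]]))), 1e-8)
})

test_that("NVT kinetic temperature settles near the target", {
  cfg <- build_configuration(200, 0.5, T_star = 1.2, seed = 12)
  tr <- integrate_nvt(cfg, sim_params(n_steps = 3e4, r_cut = 2.5,
                                      sampling_stride = 50, seed = 12), 1.2)
  w <- analysis_window(tr)
  t_kin <- mean(w$ke) / (1.5 * (tr$n - 1))
  expect_equal(t_kin, 1.2, tolerance = 0.03)
})

test_that("harmonic bonds equilibrate to the equipartition stretch variance", {
  cfg <- build_chain_configuration(5, 10, 0.05, T_star = 1.0, seed = 3)
  p <- sim_params("chain", n_steps = 3e4, r_cut = 2.5, sampling_stride = 100,
                  thermostat_damping = 1.0, seed = 3)
  tr <- integrate_nvt(cfg, p, 1.0)
  w <- analysis_window(tr)
  bonds <- bond_list(cfg)
  stretch2 <- numeric(0)
  for (i in seq_len(n_frames(w))) {
    d <- min_image_r(w$positions[[i]][bonds[, 1], ] -
                       w$positions[[i]][bonds[, 2], ], tr$box_side)
    stretch2 <- c(stretch2, (sqrt(rowSums(d * d)) - 1)^2)
  }
  # <k_b (r-sigma)^2> = kT/2  =>  <(r-sigma)^2> = kT / (2 k_b)
  expect_equal(mean(stretch2), 1 / (2 * 75000), tolerance = 0.3)
})

test_that("fixed seeds reproduce trajectories bit-for-bit", {
  run <- function() {
    cfg <- build_configuration(50, 0.3, seed = 99)
    integrate_nvt(cfg, sim_params(n_steps = 500, r_cut = 2.5,
                                  sampling_stride = 50, seed = 99), 1.0)
  }
  a <- run(); b <- run()
  expect_identical(a$positions, b$positions)
  expect_identical(a$pe, b$pe)
})

test_that("run_state_point returns the equilibration-trimmed window", {
  p <- sim_params(n_steps = 3000, r_cut = 2.5, sampling_stride = 10, seed = 2)
  tr <- run_state_point(0.2, 1.1, "monomer", p, n = 60)
  expect_equal(n_frames(tr), 100)  # final third of 300 frames
  expect_true(all(tr$times > 2 / 3 * 3000 * 0.005))
  dt_frames <- diff(tr$times)
  expect_equal(dt_frames, rep(10 * 0.005, length(dt_frames)), tolerance = 1e-12)
})

test_that("oversized r_cut is clamped with a warning during integration", {
  cfg <- build_configuration(30, 0.2, seed = 1)
  expect_warning(
    integrate_nve(cfg, sim_params(n_steps = 10, r_cut = 6.85,
                                  sampling_stride = 5)),
    "clamped")
})
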