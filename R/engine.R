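# Molecular-dynamics engine: force-field evaluation and time integration.
#
# Velocity-Verlet with plain-truncated LJ (no shift, no tail correction) plus
# harmonic bonds for chains; canonical sampling via a Nose-Hoover chain
# (length 3) coupled to the total kinetic energy, as in standard MD engines.
# The numerics live in src/engine.cpp; these wrappers own validation,
# trajectory assembly, and the equilibration-window bookkeeping.

check_rcut <- function(r_cut, box_side, clamp = FALSE) {
  lim <- box_side / 2
  if (r_cut >= lim) {
    if (!clamp)
      stop(sprintf("r_cut = %.4g must be < box_side/2 = %.4g under the minimum-image convention",
                   r_cut, lim))
    r_new <- lim - 1e-6
    warning(sprintf("r_cut = %.4g does not fit the box (side %.4g); clamped to %.6g",
                    r_cut, box_side, r_new), call. = FALSE)
    return(r_new)
  }
  r_cut
}

#' Lennard-Jones energy and forces of a configuration
#'
#' Plain-truncated 6-12 Lennard-Jones,
#' \eqn{\Phi(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} for
#' \eqn{r < r_{cut}}, under the minimum-image convention.  No energy shift
#' and no tail correction are applied.  For chain systems, directly bonded
#' pairs are excluded; all other intra-chain pairs interact.
#'
#' @param config An `lj_config`.
#' @param r_cut Cutoff radius in \eqn{\sigma}; must be below half the box
#'   side.
#' @return List with `energy` (\eqn{\epsilon}), `forces` (n x 3 matrix,
#'   exact negative gradients), and `min_distance` (closest pair seen).
#' @export
pair_energy_forces <- function(config, r_cut = 6.85) {
  r_cut <- check_rcut(r_cut, config$box_side)
  res <- cpp_lj_energy_forces(config$positions, config$box_side, r_cut,
                              bond_list(config))
  if (is.finite(res$min_distance) && res$min_distance < 0.5)
    warning(sprintf("pair distance %.3g sigma below 0.5 sigma: near-singular forces",
                    res$min_distance), call. = FALSE)
  res
}

#' Harmonic bond energy and forces of a chain configuration
#'
#' \eqn{U_{bond}(r) = k_b (r - \sigma)^2} summed over consecutive-bead bonds.
#'
#' @param config An `lj_config` with chain topology.
#' @param k_bond Bond constant in \eqn{\epsilon/\sigma^2} (default 75000).
#' @return List with `energy` and `forces`.
#' @export
bond_energy_forces <- function(config, k_bond = 75000) {
  bonds <- bond_list(config)
  if (nrow(bonds) == 0)
    stop("configuration has no chain topology; bond energy undefined")
  cpp_bond_energy_forces(config$positions, config$box_side, bonds, k_bond)
}

new_trajectory <- function(raw, config, params, T_star = NULL, ensemble) {
  structure(list(times = raw$times,
                 positions = raw$positions,
                 velocities = raw$velocities,
                 pe = raw$pe, ke = raw$ke,
                 pe_shifted = raw$pe_shifted,
                 thermostat = raw$thermostat,
                 box_side = config$box_side,
                 rho_star = config$rho_star,
                 T_star = T_star,
                 n = config$n,
                 chain_id = config$chain_id,
                 chain_length = config$chain_length,
                 params = params,
                 ensemble = ensemble,
                 E0 = raw$E0,
                 E0_shifted = raw$E0_shifted,
                 min_distance = raw$min_distance),
            class = "lj_trajectory")
}

#' @export
print.lj_trajectory <- function(x, ...) {
  cat(sprintf("LJ trajectory (%s): %d frames x %d particles, t = [%.3g, %.3g] tau, rho* = %.4g%s\n",
              x$ensemble, n_frames(x), x$n,
              if (n_frames(x)) x$times[1] else NA, if (n_frames(x)) x$times[n_frames(x)] else NA,
              x$rho_star,
              if (!is.null(x$T_star)) sprintf(", T* = %.4g", x$T_star) else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `lj_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract a single frame
#'
#' @param traj An `lj_trajectory`.
#' @param i Frame index (1-based).
#' @return List with `time`, `positions`, `velocities`, `potential_energy`,
#'   `kinetic_energy`, `thermostat_state`, `box_side`, `chain_id`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  list(time = traj$times[i],
       positions = traj$positions[[i]],
       velocities = traj$velocities[[i]],
       potential_energy = traj$pe[i],
       kinetic_energy = traj$ke[i],
       thermostat_state = traj$thermostat[i, ],
       box_side = traj$box_side,
       chain_id = traj$chain_id)
}

#' Turn a trajectory frame back into a configuration
#'
#' Useful for restarting: e.g. equilibrate under NVT, then continue the last
#' frame under NVE for energy-conservation checks.
#'
#' @param traj An `lj_trajectory`.
#' @param i Frame index (default: last frame).
#' @return An `lj_config`.
#' @export
as_configuration <- function(traj, i = n_frames(traj)) {
  fr <- get_frame(traj, i)
  new_configuration(fr$positions, fr$velocities, traj$box_side,
                    traj$rho_star, traj$T_star,
                    chain_id = traj$chain_id, chain_length = traj$chain_length)
}

run_md <- function(config, params, nvt, T_star) {
  r_cut <- check_rcut(params$r_cut, config$box_side, clamp = TRUE)
  stopifnot(params$dt > 0, params$n_steps >= 1)
  vxi0 <- rep(0, 3)
  if (nvt) {
    # draw the thermostat-chain velocities from their canonical Gaussians
    # (variance kT/Q_k); starting the chain exactly at its fixed point
    # freezes the kinetic-energy fluctuations of weakly coupled systems
    g <- if (config$n > 1) 3 * (config$n - 1) else 3
    Q <- c(g, 1, 1) * T_star * params$thermostat_damping^2
    vxi0 <- rnorm(3) * sqrt(T_star / Q)
  }
  raw <- cpp_md_run(config$positions, config$velocities, config$box_side,
                    bond_list(config), params$k_bond, r_cut,
                    params$dt, as.integer(params$n_steps),
                    as.integer(params$sampling_stride),
                    nvt, if (nvt) T_star else 0.0, params$thermostat_damping,
                    vxi0,
                    isTRUE(params$interactions), params$skin,
                    if (nvt) 0.0 else 1e-2)
  new_trajectory(raw, config, params, T_star = if (nvt) T_star else NULL,
                 ensemble = if (nvt) "NVT" else "NVE")
}

#' Microcanonical (NVE) integration
#'
#' Velocity-Verlet without a thermostat.  The run aborts with a diagnostic if
#' the conserved energy drifts by more than 1\% relative to its initial
#' value, which indicates an unstable time step.  Note that with plain
#' truncation the reported potential energy jumps by \eqn{\Phi(r_{cut})}
#' whenever a pair crosses the cutoff; the quantity the truncated-force
#' dynamics conserves is [conserved_energy()], which includes the cutoff
#' shift, and that is what the drift diagnostic monitors.
#'
#' @param config An `lj_config`.
#' @param params A [sim_params()] list.
#' @return An `lj_trajectory` with frames every `sampling_stride` steps.
#' @export
integrate_nve <- function(config, params = sim_params()) {
  run_md(config, params, nvt = FALSE, T_star = NULL)
}

#' Relative secular energy drift of an NVE trajectory
#'
#' Compares the mean conserved energy over the final `fraction` of frames
#' with the mean over the initial `fraction`, relative to the overall mean
#' magnitude.  Robust against the bounded \eqn{O(dt^2)} oscillation of
#' velocity-Verlet energies, which is not drift.
#'
#' @param traj An `lj_trajectory` from [integrate_nve()].
#' @param fraction Window fraction at each end (default 0.1).
#' @return Non-negative scalar.
#' @export
energy_drift <- function(traj, fraction = 0.1) {
  e <- conserved_energy(traj)
  nf <- length(e)
  k <- max(1, round(nf * fraction))
  abs(mean(e[(nf - k + 1):nf]) - mean(e[1:k])) / max(abs(mean(e)), 1)
}

#' Conserved-energy series of a trajectory
#'
#' Kinetic energy plus the cutoff-shifted potential
#' \eqn{\sum_{r<r_{cut}} [\Phi(r) - \Phi(r_{cut})]} (plus bond terms).  This
#' is the exact invariant of velocity-Verlet dynamics under truncated
#' forces, and the right quantity for energy-conservation checks; the
#' plain-truncated `pe` is what the coexistence protocol reports.
#'
#' @param traj An `lj_trajectory`.
#' @return Numeric vector, one value per frame.
#' @export
conserved_energy <- function(traj) traj$ke + traj$pe_shifted

#' Canonical (NVT) integration with a Nose-Hoover chain thermostat
#'
#' A chain of three thermostat variables is coupled to the total kinetic
#' energy (the standard Martyna-Tuckerman-Klein scheme used by mainstream MD
#' engines); a single thermostat variable is not ergodic for weakly coupled
#' systems, so the chain form is used throughout.  Velocity scaling is
#' uniform, so a zero total momentum is preserved exactly.
#'
#' @param config An `lj_config`.
#' @param params A [sim_params()] list; `thermostat_damping` sets the
#'   coupling time.
#' @param T_star Target temperature.
#' @return An `lj_trajectory`.  A warning is emitted if the kinetic
#'   temperature fails to settle within 10\% of `T_star` over the
#'   post-equilibration window.
#' @export
integrate_nvt <- function(config, params = sim_params(), T_star = 1.0) {
  stopifnot(T_star > 0)
  traj <- run_md(config, params, nvt = TRUE, T_star = T_star)
  win <- analysis_window(traj)
  if (n_frames(win) >= 5) {
    g <- 3 * (traj$n - 1)
    t_kin <- mean(win$ke) / (g / 2)
    if (abs(t_kin - T_star) / T_star > 0.10)
      warning(sprintf("kinetic temperature %.4g did not settle within 10%% of T* = %.4g",
                      t_kin, T_star), call. = FALSE)
  }
  traj
}

#' Restrict a trajectory to its analysis window
#'
#' Drops the equilibration prefix: frames with time less than
#' `equilibration_fraction` times the total simulated time are discarded
#' (default 2/3, e.g. the final 1666.7 of 5000 \eqn{\tau_{LJ}}).
#'
#' @param traj An `lj_trajectory`.
#' @param equilibration_fraction Override; defaults to the value stored in
#'   the trajectory's parameters.
#' @return An `lj_trajectory` containing only the analysis frames.
#' @export
analysis_window <- function(traj, equilibration_fraction = NULL) {
  f <- equilibration_fraction %||% traj$params$equilibration_fraction
  t_total <- traj$params$n_steps * traj$params$dt
  keep <- traj$times > f * t_total + 1e-12
  out <- traj
  out$times <- traj$times[keep]
  out$positions <- traj$positions[keep]
  out$velocities <- traj$velocities[keep]
  out$pe <- traj$pe[keep]
  out$ke <- traj$ke[keep]
  out$pe_shifted <- traj$pe_shifted[keep]
  out$thermostat <- traj$thermostat[keep, , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one state point and return its analysis window
#'
#' Builds a configuration (random placement, falling back to a lattice at
#' densities too high for overlap-free random insertion), runs NVT at the
#' requested state point, discards the equilibration prefix, and returns the
#' analysis-window trajectory.
#'
#' @param rho_star Density \eqn{\rho^*}.
#' @param T_star Temperature \eqn{T^*}.
#' @param system_kind `"monomer"` or `"chain"`.
#' @param params A [sim_params()] list (its `seed` drives configuration
#'   building).
#' @param n Particle count for monomer systems.
#' @param n_chains,chain_length Chain-system dimensions (200 x 20 is the
#'   canonical full-size system).
#' @return An `lj_trajectory` restricted to the analysis window.
#' @export
run_state_point <- function(rho_star, T_star,
                            system_kind = c("monomer", "chain"),
                            params = sim_params(system_kind),
                            n = 4000L, n_chains = 200L, chain_length = 20L) {
  system_kind <- match.arg(system_kind)
  config <- if (system_kind == "monomer") {
    tryCatch(
      build_configuration(n, rho_star, T_star, "random", seed = params$seed),
      error = function(e)
        build_configuration(n, rho_star, T_star, "lattice", seed = params$seed))
  } else {
    build_chain_configuration(n_chains, chain_length, rho_star, T_star,
                              seed = params$seed)
  }
  traj <- integrate_nvt(config, params, T_star)
  analysis_window(traj)
}
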