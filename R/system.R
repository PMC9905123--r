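# System construction: reduced units, state points, and configuration builders.
#
# Everything is expressed in reduced Lennard-Jones units:
#   epsilon = sigma = m = k_B = 1,  tau_LJ = sqrt(m sigma^2 / epsilon) = 1.
# Densities are monomers per sigma^3 (rho*), temperatures in epsilon/k_B (T*).

#' Reduced Lennard-Jones units
#'
#' Returns the unit system used throughout the package.  All four base
#' constants are fixed at exactly 1, so the intrinsic time unit
#' \eqn{\tau_{LJ} = \sqrt{m\sigma^2/\epsilon}} is also 1.  Starred quantities
#' (\eqn{\rho^*}, \eqn{T^*}) are understood in these units everywhere.
#'
#' @return A list with components `epsilon`, `sigma`, `mass`, `k_B`, `tau_LJ`.
#' @export
reduced_units <- function() {
  list(epsilon = 1, sigma = 1, mass = 1, k_B = 1, tau_LJ = 1)
}

#' Define a thermodynamic state point
#'
#' @param rho_star Number density in monomers per \eqn{\sigma^3}; must be > 0.
#' @param T_star Temperature in \eqn{\epsilon/k_B}; must be > 0.
#' @return A list of class `state_point`.
#' @export
state_point <- function(rho_star, T_star) {
  stopifnot(is.numeric(rho_star), length(rho_star) == 1, rho_star > 0,
            is.numeric(T_star), length(T_star) == 1, T_star > 0)
  structure(list(rho_star = rho_star, T_star = T_star), class = "state_point")
}

#' Simulation parameters
#'
#' Collects the force-field and integrator settings.  Defaults follow the
#' monomeric protocol; `system = "chain"` switches to the stiffer-bond
#' settings (smaller time step, softer thermostat coupling).
#'
#' @param system `"monomer"` or `"chain"`; selects the per-system defaults.
#' @param r_cut Lennard-Jones cutoff in \eqn{\sigma} (plain truncation, no
#'   shift or tail correction).  Default 6.85.
#' @param dt Integration step in \eqn{\tau_{LJ}}: 0.005 for monomers, 0.001
#'   for chains.
#' @param n_steps Number of integration steps (default \eqn{10^6} monomers,
#'   \eqn{5\times 10^6} chains, i.e. 5000 \eqn{\tau_{LJ}} either way).
#' @param thermostat_damping Nose-Hoover damping time in \eqn{\tau_{LJ}}:
#'   1.0 for monomers, 10.0 for chains.
#' @param k_bond Harmonic bond constant in \eqn{\epsilon/\sigma^2}
#'   (default 75000).
#' @param seed Integer seed for configuration building.
#' @param equilibration_fraction Fraction of the run discarded before
#'   analysis (default 2/3, leaving the final third as the analysis window).
#' @param sampling_stride Steps between stored frames (default 100 monomers /
#'   500 chains, i.e. 0.5 \eqn{\tau_{LJ}} resolution).
#' @param interactions Logical; set `FALSE` to disable the nonbonded LJ
#'   interaction (ideal-gas reference runs).
#' @param skin Neighbor-list skin width in \eqn{\sigma}.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(system = c("monomer", "chain"),
                       r_cut = 6.85,
                       dt = NULL,
                       n_steps = NULL,
                       thermostat_damping = NULL,
                       k_bond = 75000,
                       seed = 1L,
                       equilibration_fraction = 2 / 3,
                       sampling_stride = NULL,
                       interactions = TRUE,
                       skin = 0.4) {
  system <- match.arg(system)
  if (is.null(dt)) dt <- if (system == "monomer") 0.005 else 0.001
  if (is.null(n_steps)) n_steps <- if (system == "monomer") 1e6 else 5e6
  if (is.null(thermostat_damping))
    thermostat_damping <- if (system == "monomer") 1.0 else 10.0
  if (is.null(sampling_stride))
    sampling_stride <- if (system == "monomer") 100L else 500L
  stopifnot(r_cut > 0, dt > 0, n_steps >= 1, thermostat_damping > 0,
            k_bond >= 0, equilibration_fraction >= 0,
            equilibration_fraction < 1, sampling_stride >= 1)
  structure(list(system = system, r_cut = r_cut, dt = dt,
                 n_steps = as.integer(round(n_steps)),
                 thermostat_damping = thermostat_damping, k_bond = k_bond,
                 seed = as.integer(seed),
                 equilibration_fraction = equilibration_fraction,
                 sampling_stride = as.integer(sampling_stride),
                 interactions = interactions, skin = skin),
            class = "sim_params")
}

#' Scaled-down and full-protocol parameter presets
#'
#' `"paper"` is the full protocol (4000 particles, \eqn{r_c = 6.85\sigma},
#' \eqn{10^6} steps for monomers).  `"desk"` is a scaled-down preset suitable
#' for a single workstation: 1000 particles, \eqn{r_c = 4\sigma},
#' \eqn{5\times 10^4} steps.
#'
#' @param name `"desk"` or `"paper"`.
#' @param system `"monomer"` or `"chain"`.
#' @param ... Overrides passed to [sim_params()].
#' @return A list with `params` (a `sim_params`) and `n` (particle count;
#'   for chains, `n_chains` and `chain_length`).
#' @export
preset <- function(name = c("desk", "paper"), system = c("monomer", "chain"), ...) {
  name <- match.arg(name)
  system <- match.arg(system)
  dots <- list(...)
  base <- if (name == "desk") {
    list(r_cut = 4.0, n_steps = if (system == "monomer") 5e4 else 2.5e5)
  } else {
    list(r_cut = 6.85, n_steps = if (system == "monomer") 1e6 else 5e6)
  }
  base$system <- system
  base[names(dots)] <- dots
  p <- do.call(sim_params, base)
  if (system == "monomer") {
    list(params = p, n = if (name == "desk") 1000L else 4000L)
  } else {
    list(params = p,
         n_chains = if (name == "desk") 50L else 200L,
         chain_length = 20L)
  }
}

box_side_for <- function(n, rho_star) (n / rho_star)^(1 / 3)

#' Maxwell-Boltzmann velocities with exact momentum and temperature targets
#'
#' Draws from the Maxwell-Boltzmann distribution at `T_star`, removes the
#' center-of-mass momentum exactly, then rescales so the kinetic energy is
#' exactly \eqn{(3/2)(n-1) k_B T^*} (the correct equipartition target after
#' momentum removal).  A single particle gets zero velocity.
#' @noRd
mb_velocities <- function(n, T_star) {
  if (n == 1) return(matrix(0, 1, 3))
  v <- matrix(rnorm(n * 3, sd = sqrt(T_star)), n, 3)
  v <- sweep(v, 2, colMeans(v))
  ke <- 0.5 * sum(v^2)
  target <- 1.5 * (n - 1) * T_star
  v * sqrt(target / ke)
}

new_configuration <- function(positions, velocities, box_side, rho_star,
                              T_star = NULL, chain_id = NULL, chain_length = NULL) {
  structure(list(n = nrow(positions), positions = positions,
                 velocities = velocities, box_side = box_side,
                 rho_star = rho_star, T_star = T_star,
                 chain_id = chain_id, chain_length = chain_length),
            class = "lj_config")
}

#' @export
print.lj_config <- function(x, ...) {
  kind <- if (is.null(x$chain_id)) "monomer" else
    sprintf("chain (%d chains x %d beads)",
            length(unique(x$chain_id)), x$chain_length)
  cat(sprintf("LJ configuration: %d particles (%s), box %.4f sigma, rho* = %.4f\n",
              x$n, kind, x$box_side, x$rho_star))
  invisible(x)
}

#' Bond list of a chain configuration
#'
#' Consecutive beads within each chain are bonded; monomer systems have no
#' bonds.
#'
#' @param config An `lj_config`.
#' @return Integer matrix with two columns (1-based particle indices), one
#'   row per bond.
#' @export
bond_list <- function(config) {
  if (is.null(config$chain_id)) return(matrix(integer(0), 0, 2))
  idx <- seq_len(config$n - 1)
  keep <- config$chain_id[idx] == config$chain_id[idx + 1]
  cbind(idx[keep], idx[keep] + 1L)
}

#' Build a monomeric configuration
#'
#' Places `n` particles in a cubic periodic box sized so that
#' \eqn{L = (n/\rho^*)^{1/3}}.  Random placement rejects pairs closer than
#' \eqn{0.85\sigma} (to avoid near-singular forces); lattice placement uses a
#' simple cubic lattice padded with vacancies when `n` is not a perfect cube.
#' Velocities are Maxwell-Boltzmann at `T_star` with the total momentum
#' removed exactly and kinetic energy rescaled to
#' \eqn{(3/2)(n-1)k_B T^*}.
#'
#' @param n Number of particles (>= 1).
#' @param rho_star Number density \eqn{\rho^*}.
#' @param T_star Temperature \eqn{T^*} for velocity initialization.
#' @param arrangement `"random"` (overlap-rejecting) or `"lattice"`.
#' @param seed Integer seed; same seed gives a bit-identical configuration.
#' @return An `lj_config`.
#' @export
build_configuration <- function(n, rho_star, T_star = 1.0,
                                arrangement = c("random", "lattice"),
                                seed = 1L) {
  arrangement <- match.arg(arrangement)
  stopifnot(n >= 1, rho_star > 0, T_star > 0)
  set.seed(seed)
  L <- box_side_for(n, rho_star)
  if (arrangement == "lattice") {
    ns <- ceiling(n^(1 / 3) - 1e-9)
    spacing <- L / ns
    g <- seq(0, by = spacing, length.out = ns) + spacing / 2
    sites <- as.matrix(expand.grid(x = g, y = g, z = g))
    pos <- sites[seq_len(n), , drop = FALSE]
    dimnames(pos) <- NULL
  } else {
    pos <- matrix(NA_real_, n, 3)
    min2 <- 0.85^2
    budget <- 100L * n
    placed <- 0L
    while (placed < n) {
      if (budget <= 0L)
        stop("random placement failed at rho* = ", signif(rho_star, 4),
             " after the attempt budget; use arrangement = \"lattice\"")
      cand <- runif(3, 0, L)
      ok <- TRUE
      if (placed > 0L) {
        d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
        d <- d - L * round(d / L)
        ok <- min(rowSums(d * d)) >= min2
      }
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
      budget <- budget - 1L
    }
  }
  pos <- pos %% L
  new_configuration(pos, mb_velocities(n, T_star), L, rho_star, T_star)
}

#' Build a bead-spring chain configuration
#'
#' Each chain is a line of `chain_length` beads connected by harmonic bonds;
#' chains are grown as self-avoiding random walks with consecutive-bead
#' distance exactly \eqn{\sigma}, rejecting any bead closer than
#' \eqn{0.85\sigma} to a previously placed bead (other than its bonded
#' predecessor).  Chains occupy consecutive particle indices.
#'
#' @param n_chains Number of chains (>= 1).
#' @param chain_length Beads per chain (>= 2; 20 is the canonical value).
#' @param rho_star Number density in beads per \eqn{\sigma^3}.
#' @param T_star Temperature for velocity initialization.
#' @param seed Integer seed.
#' @return An `lj_config` with `chain_id` and `chain_length` set.
#' @export
build_chain_configuration <- function(n_chains, chain_length = 20L,
                                      rho_star = 0.1, T_star = 1.0, seed = 1L) {
  stopifnot(n_chains >= 1, chain_length >= 2, rho_star > 0, T_star > 0)
  set.seed(seed)
  n <- n_chains * chain_length
  L <- box_side_for(n, rho_star)
  pos <- matrix(NA_real_, n, 3)
  min2 <- 0.85^2
  budget <- 200L * n
  too_close <- function(cand, upto, skip = 0L) {
    if (upto == 0L) return(FALSE)
    idx <- seq_len(upto)
    if (skip > 0L) idx <- setdiff(idx, skip)
    if (length(idx) == 0L) return(FALSE)
    d <- sweep(pos[idx, , drop = FALSE], 2, cand)
    d <- d - L * round(d / L)
    min(rowSums(d * d)) < min2
  }
  for (c_i in seq_len(n_chains)) {
    base <- (c_i - 1L) * chain_length
    done <- FALSE
    while (!done) {
      if (budget <= 0L)
        stop("chain placement failed at rho* = ", signif(rho_star, 4),
             "; density too high for self-avoiding growth")
      budget <- budget - 1L
      start <- runif(3, 0, L)
      if (too_close(start, base)) next
      pos[base + 1L, ] <- start
      k <- 2L
      fail <- FALSE
      while (k <= chain_length) {
        ok <- FALSE
        for (try in seq_len(60L)) {
          u <- rnorm(3)
          u <- u / sqrt(sum(u * u))
          cand <- (pos[base + k - 1L, ] + u) %% L
          if (!too_close(cand, base + k - 1L, skip = base + k - 1L)) {
            pos[base + k, ] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) { fail <- TRUE; break }
        k <- k + 1L
      }
      done <- !fail
    }
  }
  pos <- pos %% L
  new_configuration(pos, mb_velocities(n, T_star), L, rho_star, T_star,
                    chain_id = rep(seq_len(n_chains), each = chain_length),
                    chain_length = as.integer(chain_length))
}

#' Deterministic test fixtures
#'
#' Hand-constructible configurations used by the analysis estimators' tests
#' and examples:
#' \describe{
#'   \item{`ideal_gas`}{`n` uniform independent positions in a box sized from
#'     `rho_star` (overlaps allowed), so bin occupancies follow Poisson
#'     statistics.}
#'   \item{`multi_cluster`}{Compact blobs of the requested `sizes`, internal
#'     neighbor spacing about \eqn{\sigma} (< 1.3\eqn{\sigma}), blob gaps
#'     > 2\eqn{\sigma}, so contact-cluster analysis at 1.3\eqn{\sigma}
#'     recovers exactly the requested partition.}
#'   \item{`cube_corners`}{8 particles at the corners of a cube of side
#'     `side`, centered in the box; its radius of gyration is
#'     \eqn{(\sqrt{3}/2)\,}`side` in closed form.}
#' }
#'
#' @param kind One of `"ideal_gas"`, `"multi_cluster"`, `"cube_corners"`.
#' @param n Particle count (`ideal_gas`).
#' @param rho_star Density (`ideal_gas`).
#' @param sizes Integer vector of blob sizes (`multi_cluster`).
#' @param box_side Box side; required for `multi_cluster`, default `4 * side`
#'   for `cube_corners`.
#' @param side Cube side (`cube_corners`).
#' @param T_star Temperature for `ideal_gas` velocities (others get zero
#'   velocities).
#' @param seed Integer seed.
#' @return An `lj_config`.
#' @export
make_fixture <- function(kind = c("ideal_gas", "multi_cluster", "cube_corners"),
                         n = 1000L, rho_star = 0.2, sizes = c(3L, 3L, 4L),
                         box_side = NULL, side = 2.0, T_star = 1.0, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "ideal_gas") {
    L <- box_side_for(n, rho_star)
    pos <- matrix(runif(n * 3, 0, L), n, 3)
    return(new_configuration(pos, mb_velocities(n, T_star), L, rho_star, T_star))
  }
  if (kind == "cube_corners") {
    if (is.null(box_side)) box_side <- 4 * side
    corners <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
    dimnames(corners) <- NULL
    pos <- (corners + (box_side - side) / 2) %% box_side
    return(new_configuration(pos, matrix(0, 8, 3), box_side,
                             8 / box_side^3, T_star))
  }
  # multi_cluster: blob centers on a coarse grid with guaranteed gaps
  stopifnot(all(sizes >= 1))
  blob_rmax <- 1.6   # blobs are confined to a ball of this radius
  pitch <- 2 * blob_rmax + 2.5  # center spacing: gap > 2 sigma guaranteed
  k <- length(sizes)
  if (is.null(box_side)) box_side <- ceiling(k^(1 / 3)) * pitch
  per_axis <- floor(box_side / pitch)
  if (per_axis^3 < k)
    stop("requested blobs cannot fit disjointly in a box of side ", box_side)
  g <- (seq_len(per_axis) - 0.5) * pitch
  centers <- as.matrix(expand.grid(g, g, g))[seq_len(k), , drop = FALSE]
  pos_list <- vector("list", k)
  for (b in seq_len(k)) {
    m <- sizes[b]
    bp <- matrix(NA_real_, m, 3)
    bp[1, ] <- centers[b, ]
    j <- 2L
    tries <- 0L
    while (j <= m) {
      tries <- tries + 1L
      if (tries > 5000L * m)
        stop("blob of size ", m, " could not be grown; reduce sizes")
      anchor <- bp[sample.int(j - 1L, 1L), ]
      u <- rnorm(3); u <- u / sqrt(sum(u * u))
      cand <- anchor + runif(1, 0.95, 1.15) * u
      d2c <- sum((cand - centers[b, ])^2)
      ok <- d2c <= blob_rmax^2
      if (ok && j > 2L) {
        d <- sweep(bp[seq_len(j - 1L), , drop = FALSE], 2, cand)
        ok <- min(rowSums(d * d)) >= 0.8^2
      }
      if (ok) { bp[j, ] <- cand; j <- j + 1L }
    }
    pos_list[[b]] <- bp
  }
  pos <- do.call(rbind, pos_list) %% box_side
  new_configuration(pos, matrix(0, nrow(pos), 3), box_side,
                    nrow(pos) / box_side^3, T_star)
}
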