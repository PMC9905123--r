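# Independent brute-force oracles used to cross-check the fast C++ paths.
# Everything here is deliberately naive: O(N^2) loops and textbook formulas.

# minimum-image displacement matrix entries
min_image_r <- function(d, box) d - box * round(d / box)

# all-pairs truncated LJ energy and forces (no neighbor list, no cells)
oracle_lj <- function(pos, box, rcut) {
  n <- nrow(pos)
  energy <- 0
  forces <- matrix(0, n, 3)
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        d <- min_image_r(pos[a, ] - pos[b, ], box)
        r2 <- sum(d * d)
        if (r2 < rcut^2) {
          s6 <- 1 / r2^3
          energy <- energy + 4 * (s6^2 - s6)
          fs <- 24 * (2 * s6^2 - s6) / r2
          forces[a, ] <- forces[a, ] + fs * d
          forces[b, ] <- forces[b, ] - fs * d
        }
      }
    }
  }
  list(energy = energy, forces = forces)
}

# exhaustive pair scan for contacts (r <= cutoff)
oracle_contact_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- NULL
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        d <- min_image_r(pos[a, ] - pos[b, ], box)
        if (sum(d * d) <= cutoff^2) out <- rbind(out, c(a, b))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# plain union-find over an edge list, labels in first-appearance order
oracle_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- setNames(seq_along(unique(roots)), unique(roots))
  as.integer(remap[as.character(roots)])
}

# chain-level clustering through the explicit quotient graph
oracle_chain_components <- function(pos, box, cutoff, chain_id) {
  pairs <- oracle_contact_pairs(pos, box, cutoff)
  n_chains <- max(chain_id)
  if (nrow(pairs) > 0) {
    ci <- chain_id[pairs[, 1]]; cj <- chain_id[pairs[, 2]]
    keep <- ci != cj
    cp <- unique(cbind(pmin(ci, cj), pmax(ci, cj))[keep, , drop = FALSE])
  } else cp <- matrix(integer(0), 0, 2)
  oracle_components(n_chains, cp)
}

# radius of gyration without any periodic handling
oracle_rg <- function(pos) {
  cm <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, cm)^2)))
}

# canonicalize a partition so label numbering does not matter
canon_partition <- function(labels) match(labels, unique(labels))

# minimal hand-built trajectory for estimator tests
fake_trajectory <- function(frames, box_side, times = seq_along(frames),
                            pe = NULL, ke = NULL, T_star = 1.0,
                            chain_id = NULL) {
  n <- if (length(frames)) nrow(frames[[1]]) else 0L
  nf <- length(frames)
  structure(list(times = as.numeric(times), positions = frames,
                 velocities = replicate(nf, matrix(0, n, 3), simplify = FALSE),
                 pe = pe %||% rep(0, nf), ke = ke %||% rep(0, nf),
                 pe_shifted = pe %||% rep(0, nf),
                 thermostat = matrix(0, nf, 3), box_side = box_side,
                 rho_star = n / box_side^3, T_star = T_star, n = n,
                 chain_id = chain_id,
                 chain_length = if (!is.null(chain_id)) sum(chain_id == 1) else NULL,
                 params = sim_params(n_steps = max(1L, nf),
                                     equilibration_fraction = 0),
                 ensemble = "synthetic", E0 = NA_real_, E0_shifted = NA_real_,
                 min_distance = NA_real_),
            class = "lj_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
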