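# State-point scanning and phase-diagram assembly.
#
# A scan runs one NVT simulation per (rho*, T*, seed), applies every
# estimator to the analysis window, and emits one table row per state point.
# assemble_boundaries() turns the table into per-temperature boundary
# estimates and fits the critical point with the mean-field width law
# (rho_L - rho_V) ~ (T_c - T)^(1/2) plus the rectilinear-diameter rule.

# compact deterministic fingerprint of a parameter list (polynomial hash of
# its deparsed form), so every scan row records the settings that produced it
param_hash <- function(params) {
  s <- utf8ToInt(paste(deparse(params[order(names(params))]), collapse = ""))
  h <- 0
  for (ch in s) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

state_point_row <- function(rho_star, T_star, system_kind, params, seed,
                            n, n_chains, chain_length,
                            contact_cutoff, bin_side, min_droplet) {
  p <- params
  p$seed <- as.integer(seed)
  traj <- run_state_point(rho_star, T_star, system_kind, p,
                          n = n, n_chains = n_chains,
                          chain_length = chain_length)
  level <- if (system_kind == "chain") "chain" else "atom"
  cs <- trajectory_cluster_stats(traj, contact_cutoff, level)
  occ <- occupancy_histogram(traj, bin_side)
  cv <- specific_heat(traj)
  st <- surface_tension(cs, T_star, min_size = min_droplet)
  n_units <- cs$n_units
  data.frame(rho_star = rho_star, T_star = T_star, seed = seed,
             system = system_kind, n_particles = traj$n,
             n_units = n_units,
             P0 = occ$p0,
             mean_n = cs$mean_size,
             mean_nlar = cs$mean_largest_size,
             mean_nlar_norm = cs$mean_largest_size / n_units,
             mean_rg = cs$mean_rg,
             mean_rg_lar = cs$mean_rg_largest,
             Cv = cv$C_v,
             Cv_per_particle = cv$C_v_per_particle,
             sigma_ten = st$sigma_ten,
             param_hash = param_hash(unclass(p)[setdiff(names(p), "seed")]),
             status = "ok")
}

failed_row <- function(rho_star, T_star, system_kind, seed, msg) {
  data.frame(rho_star = rho_star, T_star = T_star, seed = seed,
             system = system_kind, n_particles = NA_integer_,
             n_units = NA_integer_, P0 = NA_real_, mean_n = NA_real_,
             mean_nlar = NA_real_, mean_nlar_norm = NA_real_,
             mean_rg = NA_real_, mean_rg_lar = NA_real_, Cv = NA_real_,
             Cv_per_particle = NA_real_, sigma_ten = NA_real_,
             param_hash = NA_character_,
             status = paste("error:", msg))
}

#' Scan a (density, temperature) grid
#'
#' Runs [run_state_point()] for every grid combination and seed, applies the
#' occupancy, cluster, specific-heat and surface-tension estimators, and
#' returns one row per state point.  Individual state-point failures are
#' recorded in the `status` column and the scan continues.  When `cache` is
#' a file path, completed rows are appended there as CSV and skipped on
#' restart, making long scans resumable.
#'
#' @param densities Strictly increasing vector of \eqn{\rho^*} values.
#' @param temperatures Vector of \eqn{T^*} values.
#' @param system_kind `"monomer"` or `"chain"`.
#' @param params A [sim_params()] list.
#' @param n Monomer count per state point.
#' @param n_chains,chain_length Chain-system dimensions.
#' @param seeds Integer seeds; a single value is expanded to one distinct
#'   deterministic seed per state point.
#' @param contact_cutoff,bin_side,min_droplet Analysis settings.
#' @param cache Optional CSV path for resumable operation.
#' @param verbose Print one line per state point.
#' @return A data.frame, one row per (density, temperature, seed).
#' @export
run_scan <- function(densities, temperatures,
                     system_kind = c("monomer", "chain"),
                     params = sim_params(system_kind),
                     n = 4000L, n_chains = 200L, chain_length = 20L,
                     seeds = 1L, contact_cutoff = 1.3, bin_side = 2.0,
                     min_droplet = 50L, cache = NULL, verbose = FALSE) {
  system_kind <- match.arg(system_kind)
  stopifnot(length(densities) >= 1, !is.unsorted(densities, strictly = TRUE),
            length(temperatures) >= 1)
  grid <- expand.grid(rho_star = densities, T_star = temperatures,
                      rep = seq_along(seeds))
  if (length(seeds) == 1) {
    grid$seed <- as.integer((seeds + 7919 * (seq_len(nrow(grid)) - 1)) %% .Machine$integer.max)
  } else {
    grid$seed <- as.integer(seeds[grid$rep])
  }
  done <- NULL
  if (!is.null(cache) && file.exists(cache)) done <- read.csv(cache)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (!is.null(done)) {
      hit <- done$rho_star == g$rho_star & done$T_star == g$T_star &
        done$seed == g$seed
      if (any(hit)) { rows[[i]] <- done[which(hit)[1], ]; next }
    }
    row <- tryCatch(
      state_point_row(g$rho_star, g$T_star, system_kind, params, g$seed,
                      n, n_chains, chain_length,
                      contact_cutoff, bin_side, min_droplet),
      error = function(e)
        failed_row(g$rho_star, g$T_star, system_kind, g$seed,
                   conditionMessage(e)))
    if (verbose)
      message(sprintf("rho* = %.3f, T* = %.3f, seed %d: %s",
                      g$rho_star, g$T_star, g$seed, row$status))
    if (!is.null(cache))
      write.table(row, cache, sep = ",", append = file.exists(cache),
                  col.names = !file.exists(cache), row.names = FALSE)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic parabolic coexistence boundaries
#'
#' Generates exact mean-field binodal branches
#' \eqn{\rho_{V,L}(T) = \rho_c + B(T_c - T) \mp \frac{A}{2}\sqrt{T_c - T}}
#' for testing the critical-point fit: the coexistence-region width follows
#' \eqn{(\rho_L-\rho_V) = A (T_c-T)^{1/2}} and the diameter is rectilinear
#' with slope \eqn{B}.
#'
#' @param temperatures Temperatures below `T_c`.
#' @param T_c,rho_c Critical point of the generated parabola.
#' @param width_amp Amplitude \eqn{A} of the width law.
#' @param diameter_slope Rectilinear-diameter slope \eqn{B}.
#' @return Data frame with `T_star`, `rho_V`, `rho_L`.
#' @export
synthetic_parabola_boundaries <- function(temperatures, T_c = 1.31,
                                          rho_c = 0.316, width_amp = 0.9,
                                          diameter_slope = 0.1) {
  stopifnot(all(temperatures < T_c))
  dT <- T_c - temperatures
  half <- width_amp * sqrt(dT) / 2
  dia <- rho_c + diameter_slope * dT
  data.frame(T_star = temperatures, rho_V = dia - half, rho_L = dia + half)
}

#' Fit the critical point from binodal branches
#'
#' Uses the mean-field width law with exponent fixed at 1/2:
#' \eqn{(\rho_L - \rho_V)^2 = A^2 (T_c - T)} is linear in \eqn{T}, giving
#' \eqn{T_c} from the intercept/slope ratio; \eqn{\rho_c} then comes from a
#' rectilinear-diameter regression of \eqn{(\rho_V + \rho_L)/2} on
#' \eqn{(T_c - T)}.
#'
#' @param boundaries Data frame with `T_star`, `rho_V`, `rho_L` (>= 2 usable
#'   temperatures with `rho_V < rho_L`).
#' @return List with `T_c`, `rho_c`, `width_amp`, `diameter_slope`,
#'   `n_temperatures`.
#' @export
fit_critical_point <- function(boundaries) {
  b <- boundaries[complete.cases(boundaries[, c("T_star", "rho_V", "rho_L")]), ]
  usable <- b$rho_V < b$rho_L
  if (any(!usable))
    warning("temperatures with rho_V >= rho_L excluded from the critical fit",
            call. = FALSE)
  b <- b[usable, ]
  if (nrow(b) < 2)
    return(list(T_c = NA_real_, rho_c = NA_real_, width_amp = NA_real_,
                diameter_slope = NA_real_, n_temperatures = nrow(b)))
  w2 <- (b$rho_L - b$rho_V)^2
  fit <- lm(w2 ~ b$T_star)
  slope <- coef(fit)[[2]]
  if (slope >= 0)
    return(list(T_c = NA_real_, rho_c = NA_real_, width_amp = NA_real_,
                diameter_slope = NA_real_, n_temperatures = nrow(b)))
  T_c <- -coef(fit)[[1]] / slope
  A <- sqrt(-slope)
  dia <- (b$rho_V + b$rho_L) / 2
  dT <- T_c - b$T_star
  dfit <- lm(dia ~ dT)
  list(T_c = T_c, rho_c = coef(dfit)[[1]], width_amp = A,
       diameter_slope = coef(dfit)[[2]], n_temperatures = nrow(b))
}

#' Assemble a phase diagram from a scan table
#'
#' Applies [estimate_boundaries()] at each temperature and fits the critical
#' point from the defined binodal branches.  Temperatures at or above the
#' fitted \eqn{T_c} are flagged and their boundary densities set to `NA`
#' (no two-phase region exists there).
#'
#' @param tbl A [run_scan()] table (multi-seed tables are averaged per
#'   state point first), or a per-temperature boundary table that already
#'   has `rho_V` and `rho_L` columns (e.g. from
#'   [synthetic_parabola_boundaries()]), in which case only the critical
#'   fit is performed.
#' @param p0_threshold Threshold for the liquid-branch locator.
#' @return A list of class `phase_diagram`: `boundaries` (per-temperature
#'   data.frame), `T_c`, `rho_c`, `fit`, `grid` metadata.
#' @export
assemble_boundaries <- function(tbl, p0_threshold = 0.005) {
  if (all(c("rho_V", "rho_L") %in% names(tbl))) {
    boundaries <- as.data.frame(tbl)
    fit <- fit_critical_point(boundaries)
    return(structure(list(boundaries = boundaries, T_c = fit$T_c,
                          rho_c = fit$rho_c, fit = fit,
                          grid = list(temperatures = sort(unique(tbl$T_star)))),
                     class = "phase_diagram"))
  }
  ok <- tbl$status == "ok"
  tbl <- tbl[ok, ]
  agg <- stats::aggregate(
    tbl[, c("P0", "mean_n", "mean_nlar_norm", "Cv")],
    by = list(rho_star = tbl$rho_star, T_star = tbl$T_star), FUN = mean)
  temps <- sort(unique(agg$T_star))
  rows <- lapply(temps, function(Tv)
    estimate_boundaries(agg[agg$T_star == Tv, ], Tv, p0_threshold))
  boundaries <- do.call(rbind, rows)
  fit <- fit_critical_point(boundaries)
  if (!is.na(fit$T_c)) {
    super <- boundaries$T_star >= fit$T_c
    boundaries[super, c("rho_V", "rho_sV", "rho_sL", "rho_L")] <- NA_real_
  }
  structure(list(boundaries = boundaries, T_c = fit$T_c, rho_c = fit$rho_c,
                 fit = fit,
                 grid = list(densities = sort(unique(tbl$rho_star)),
                             temperatures = temps,
                             seeds = sort(unique(tbl$seed)),
                             n_particles = unique(tbl$n_particles))),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram over %d temperature(s); T_c = %.4g, rho_c = %.4g\n",
              nrow(x$boundaries), x$T_c, x$rho_c))
  cols <- intersect(c("T_star", "rho_V", "rho_sV", "rho_sL", "rho_L"),
                    names(x$boundaries))
  print(x$boundaries[, cols], row.names = FALSE)
  invisible(x)
}
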