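# Phase-boundary estimators.
#
# Four densities are located per temperature:
#   rho_L  - liquid binodal branch, from the vanishing of the empty-bin
#            probability P0 of a cubic occupancy grid (2 sigma bins);
#   rho_V  - vapor binodal branch, from the rapid growth of the largest
#            cluster size <n_lar>;
#   rho_sL - liquid spinodal branch, from the rapid growth of the mean
#            cluster size <n>, cross-checked against the drop in C_v;
#   rho_sV - vapor spinodal branch, from the tallest specific-heat spike.
# A fluctuation-based surface tension sigma_ten = k_B T / u^2 accompanies
# them, with u^2 the time variance of a droplet's radius of gyration.

#' Bin-occupancy histogram of a trajectory
#'
#' Divides the box into \eqn{\lfloor L/b\rfloor^3} cubic bins of side `b`
#' anchored at the box origin (the residual sliver along each axis is merged
#' into the last bin), counts particles per bin in every frame, and pools
#' the bin-frame observations into the occupancy distribution
#' \eqn{P_k = } fraction of observations with exactly \eqn{k} particles.
#' \eqn{P_0} is the empty-bin probability used to locate \eqn{\rho_L}.
#'
#' @param x An `lj_trajectory` (use the analysis window) or an `lj_config`
#'   (single frame).
#' @param bin_side Bin side in \eqn{\sigma}; 2 is optimal for monatomic
#'   particles (use a chain's radius of gyration scale for polymers).
#' @return A list of class `occupancy_histogram`: `p_k` (named vector,
#'   `p_k[1]` is \eqn{P_0}), `p0`, `bin_side`, `n_bins`,
#'   `n_frames_averaged`.
#' @export
occupancy_histogram <- function(x, bin_side = 2.0) {
  frames <- if (inherits(x, "lj_trajectory")) {
    lapply(seq_len(n_frames(x)), function(i) x$positions[[i]])
  } else {
    list(as_frame(x)$positions)
  }
  box <- if (inherits(x, "lj_trajectory")) x$box_side else as_frame(x)$box_side
  if (bin_side > box) stop("bin_side must not exceed the box side")
  nb_axis <- floor(box / bin_side + 1e-9)  # guard exact multiples against fp
  n_bins <- nb_axis^3
  if (n_bins < 8) stop("occupancy grid too coarse: fewer than 8 bins")
  counts <- integer(0)
  for (pos in frames) {
    idx <- pmin(floor(pos / bin_side), nb_axis - 1)
    lin <- idx[, 1] * nb_axis^2 + idx[, 2] * nb_axis + idx[, 3] + 1
    occ <- tabulate(lin, n_bins)
    kmax <- max(occ) + 1L
    if (kmax > length(counts)) counts <- c(counts, integer(kmax - length(counts)))
    tab <- tabulate(occ + 1L, kmax)
    counts[seq_len(kmax)] <- counts[seq_len(kmax)] + tab
  }
  p_k <- counts / sum(counts)
  names(p_k) <- as.character(seq_along(p_k) - 1L)
  structure(list(p_k = p_k, p0 = p_k[[1]], bin_side = bin_side,
                 n_bins = n_bins, n_frames_averaged = length(frames)),
            class = "occupancy_histogram")
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("Occupancy histogram: %d bins of side %.2f sigma over %d frame(s); P0 = %.4g\n",
              x$n_bins, x$bin_side, x$n_frames_averaged, x$p0))
  invisible(x)
}

undefined_boundary <- function(reason) {
  structure(list(value = NA_real_, defined = FALSE, reason = reason),
            class = "boundary_estimate")
}

defined_boundary <- function(value, ...) {
  structure(c(list(value = value, defined = TRUE), list(...)),
            class = "boundary_estimate")
}

#' @export
print.boundary_estimate <- function(x, ...) {
  if (x$defined) cat(sprintf("boundary at rho* = %.4g\n", x$value))
  else cat(sprintf("boundary undefined: %s\n", x$reason))
  invisible(x)
}

#' Locate the liquid binodal branch from the P0 curve
#'
#' \eqn{\rho_L} is the smallest density at which the empty-bin probability
#' first drops below `threshold` ("approaches zero"), linearly interpolated
#' between the adjacent grid points.
#'
#' @param rho Densities of the scan grid (increasing).
#' @param p0 Empty-bin probabilities at those densities.
#' @param threshold Crossing threshold (default 0.005).
#' @return A `boundary_estimate`; undefined (flagged, not fabricated) when
#'   the curve never crosses the threshold.
#' @export
locate_binodal_liquid <- function(rho, p0, threshold = 0.005) {
  stopifnot(length(rho) == length(p0), length(rho) >= 3,
            !is.unsorted(rho, strictly = TRUE))
  below <- which(p0 < threshold)
  if (length(below) == 0)
    return(undefined_boundary("P0 never drops below the threshold in the scanned range"))
  j <- below[1]
  if (j == 1) return(defined_boundary(rho[1], threshold = threshold))
  # linear interpolation of the crossing between grid points j-1 and j
  frac <- (p0[j - 1] - threshold) / (p0[j - 1] - p0[j])
  defined_boundary(rho[j - 1] + frac * (rho[j] - rho[j - 1]),
                   threshold = threshold)
}

log_slopes <- function(rho, y, floor_val = 1e-12) {
  ly <- log(pmax(y, floor_val))
  list(slope = diff(ly) / diff(rho), mid = (head(rho, -1) + tail(rho, -1)) / 2)
}

#' Locate the vapor binodal branch from the largest-cluster growth
#'
#' \eqn{\rho_V} is where \eqn{\langle n_{lar}\rangle} undergoes its rapid
#' growth: the interval of maximum discrete slope of
#' \eqn{\log\langle n_{lar}\rangle} on the low-density side of the curve
#' (midpoints below the interpolated half-maximum of the normalized curve),
#' reported with the midpoint-of-interval convention.  The curve should be
#' normalized by the total particle (or chain) count before analysis.
#'
#' @param rho Densities (increasing, >= 5 points).
#' @param nlar_norm \eqn{\langle n_{lar}\rangle / n_m} at those densities.
#' @return A `boundary_estimate`; undefined when the maximum slope does not
#'   exceed 3x the median absolute slope (flat / noise-level curve).
#' @export
locate_binodal_vapor <- function(rho, nlar_norm) {
  stopifnot(length(rho) == length(nlar_norm), length(rho) >= 5,
            !is.unsorted(rho, strictly = TRUE))
  s <- log_slopes(rho, nlar_norm)
  half <- max(nlar_norm) / 2
  above <- which(nlar_norm >= half)
  rho_half <- if (length(above) == 0 || above[1] == 1) rho[1] else {
    j <- above[1]
    rho[j - 1] + (half - nlar_norm[j - 1]) / (nlar_norm[j] - nlar_norm[j - 1]) *
      (rho[j] - rho[j - 1])
  }
  # low-density side: intervals whose left endpoint lies below the half-max
  # crossing (this keeps the interval containing the crossing itself)
  eligible <- head(rho, -1) < rho_half
  if (!any(eligible))
    return(undefined_boundary("no slope intervals on the low-density side"))
  noise_floor <- 3 * median(abs(s$slope))
  k <- which(eligible)[which.max(s$slope[eligible])]
  if (!is.finite(s$slope[k]) || s$slope[k] < noise_floor || s$slope[k] <= 0)
    return(undefined_boundary("largest-cluster curve has no growth above the noise floor"))
  defined_boundary(s$mid[k], slope = s$slope[k])
}

#' Specific heat from energy fluctuations
#'
#' Canonical fluctuation estimator over the analysis window:
#' \eqn{C_v = (\langle E^2\rangle - \langle E\rangle^2) / (k_B T^{*2})} with
#' \eqn{E = KE + PE} per frame.  Reported per system; divide by \eqn{n} for
#' per-particle values.
#'
#' @param traj An NVT `lj_trajectory` with at least 100 analysis frames.
#' @param energy `"total"` (default) or `"potential"`; the potential-only
#'   variant adds the analytic kinetic contribution \eqn{\frac{3}{2}(n-1)k_B}.
#' @return List of class `thermo_stats` with `C_v`, `C_v_per_particle`,
#'   `T_star`, `n_frames`.
#' @export
specific_heat <- function(traj, energy = c("total", "potential")) {
  energy <- match.arg(energy)
  if (is.null(traj$T_star)) stop("specific heat requires an NVT trajectory")
  nf <- n_frames(traj)
  if (nf < 100) stop("too few frames for the fluctuation estimator (need >= 100)")
  e <- if (energy == "total") traj$pe + traj$ke else traj$pe
  cv <- mean((e - mean(e))^2) / traj$T_star^2
  if (energy == "potential") cv <- cv + 1.5 * (traj$n - 1)
  structure(list(C_v = cv, C_v_per_particle = cv / traj$n,
                 T_star = traj$T_star, n_frames = nf, energy = energy),
            class = "thermo_stats")
}

#' Locate the vapor spinodal branch from specific-heat spikes
#'
#' Entering the non-thermodynamic spinodal region shows up as sudden spikes
#' in \eqn{C_v(\rho)}.  \eqn{\rho_{sV}} is the tallest local maximum on the
#' low-density side of the curve's global drop: a point qualifying as a
#' spike must exceed both neighbors and exceed the low-density baseline
#' median by at least `spike_factor`.
#'
#' @param rho Densities (increasing, >= 5 points).
#' @param cv Specific heat at those densities.
#' @param rho_high Optional upper limit (e.g. the located \eqn{\rho_{sL}});
#'   when `NULL`, the midpoint of the steepest \eqn{C_v} decrease is used.
#' @param spike_factor Multiple of the baseline median a spike must reach
#'   (default 2).
#' @return A `boundary_estimate`; undefined when no qualifying spike exists.
#' @export
locate_spinodal_low <- function(rho, cv, rho_high = NULL, spike_factor = 2) {
  stopifnot(length(rho) == length(cv), length(rho) >= 5,
            !is.unsorted(rho, strictly = TRUE))
  if (is.null(rho_high)) {
    rho_high <- cv_drop_location(rho, cv)
  }
  side <- which(rho <= rho_high)
  if (length(side) < 3)
    return(undefined_boundary("too few points on the low-density side"))
  # gas-phase baseline: the lowest quartile of the scanned side, so that the
  # elevated specific heat inside the spinodal region does not mask spikes
  n_base <- max(3L, ceiling(length(side) / 4))
  baseline <- median(cv[side[seq_len(min(n_base, length(side)))]])
  peaks <- integer(0)
  for (i in side) {
    if (i == 1 || i == length(rho)) next
    if (cv[i] > cv[i - 1] && cv[i] > cv[i + 1] && cv[i] >= spike_factor * baseline)
      peaks <- c(peaks, i)
  }
  if (length(peaks) == 0)
    return(undefined_boundary("no specific-heat spike above the baseline"))
  best <- peaks[which.max(cv[peaks])]
  defined_boundary(rho[best], height = cv[best], baseline = baseline)
}

# location of the C_v step down to the liquid value: steepest discrete
# decrease after a width-3 median filter.  The filter removes grid-narrow
# spinodal-entry spikes, whose falling edges would otherwise masquerade as
# the liquid-side drop.
cv_drop_location <- function(rho, cv) {
  cv_s <- if (length(cv) >= 3) stats::runmed(cv, 3) else cv
  dcv <- diff(cv_s) / diff(rho)
  k <- which.min(dcv)
  (rho[k] + rho[k + 1]) / 2
}

#' Locate the liquid spinodal branch from mean-cluster growth and the C_v drop
#'
#' Primary estimate: the interval of maximum discrete slope of
#' \eqn{\log\langle n\rangle} (the mean size over all clusters) on its
#' high-density rise, midpoint convention.  Cross-check: the location of the
#' \eqn{C_v} step down to the liquid value, detected as the steepest
#' discrete decrease after a width-3 median filter (so grid-narrow
#' specific-heat spikes are not mistaken for the liquid-side drop).  Both
#' are reported; a consistency warning is raised when they disagree by more
#' than two grid spacings.
#'
#' @param rho Densities (increasing, >= 5 points, shared by both curves).
#' @param mean_n \eqn{\langle n\rangle} at those densities.
#' @param cv Specific heat at those densities (optional; `NULL` skips the
#'   cross-check).
#' @return A `boundary_estimate` with fields `cross_check`, `discrepancy`,
#'   `consistent`.
#' @export
locate_spinodal_high <- function(rho, mean_n, cv = NULL) {
  stopifnot(length(rho) == length(mean_n), length(rho) >= 5,
            !is.unsorted(rho, strictly = TRUE))
  s <- log_slopes(rho, mean_n)
  k <- which.max(s$slope)
  if (!is.finite(s$slope[k]) || s$slope[k] <= 0)
    return(undefined_boundary("mean-cluster-size curve never grows"))
  primary <- s$mid[k]
  cross <- NA_real_
  consistent <- NA
  grid <- median(diff(rho))
  if (!is.null(cv)) {
    stopifnot(length(cv) == length(rho))
    cross <- cv_drop_location(rho, cv)
    consistent <- abs(primary - cross) <= 2 * grid
    if (!consistent)
      warning(sprintf("rho_sL estimates disagree: cluster growth %.4g vs C_v drop %.4g (> 2 grid spacings)",
                      primary, cross), call. = FALSE)
  }
  defined_boundary(primary, cross_check = cross,
                   discrepancy = abs(primary - cross), consistent = consistent)
}

#' Fluctuation-based surface tension of a droplet
#'
#' By energy equipartition of capillary fluctuations,
#' \eqn{\sigma_{ten} = k_B T / u^2}, where \eqn{u^2} is the time variance of
#' the droplet's linear size, taken here as the radius of gyration of the
#' largest cluster tracked over the analysis window.  The estimator refuses
#' (returns an undefined result, never extrapolates) when the droplet is too
#' small, ever spans the box, or the series is too short or constant.
#'
#' @param rg_series Time series of the droplet's \eqn{R_g}, or a
#'   `cluster_stats` object (its largest-cluster series is used).
#' @param T_star Temperature.
#' @param min_size Minimum droplet size in particles (default 50).
#' @param sizes Optional per-frame droplet sizes (taken from
#'   `cluster_stats` input automatically).
#' @param spanning Optional per-frame spanning flags.
#' @return List of class `surface_tension`: `sigma_ten`, `u_sq`, `T_star`,
#'   `defined`, `reason`.
#' @export
surface_tension <- function(rg_series, T_star, min_size = 50,
                            sizes = NULL, spanning = NULL) {
  if (inherits(rg_series, "cluster_stats")) {
    sizes <- rg_series$size_series_largest
    spanning <- rg_series$spanning_series_largest
    rg_series <- rg_series$rg_series_largest
  }
  refuse <- function(reason)
    structure(list(sigma_ten = NA_real_, u_sq = NA_real_, T_star = T_star,
                   defined = FALSE, reason = reason),
              class = "surface_tension")
  if (length(rg_series) < 100)
    return(refuse("series shorter than 100 frames"))
  if (!is.null(spanning) && any(spanning))
    return(refuse("droplet spans the box within the window"))
  if (!is.null(sizes) && any(sizes < min_size))
    return(refuse(sprintf("droplet smaller than %d particles within the window", min_size)))
  u_sq <- mean((rg_series - mean(rg_series))^2)
  if (u_sq <= 0)
    return(refuse("R_g series is constant; u^2 = 0"))
  structure(list(sigma_ten = T_star / u_sq, u_sq = u_sq, T_star = T_star,
                 defined = TRUE, reason = NULL),
            class = "surface_tension")
}

#' @export
print.surface_tension <- function(x, ...) {
  if (x$defined)
    cat(sprintf("sigma_ten = %.4g (u^2 = %.4g, T* = %.3g)\n",
                x$sigma_ten, x$u_sq, x$T_star))
  else cat(sprintf("surface tension undefined: %s\n", x$reason))
  invisible(x)
}

#' Assemble the four boundary densities at one temperature
#'
#' Applies all locators to a per-density estimator table (as produced by
#' [run_scan()]) restricted to one temperature, and validates the expected
#' ordering \eqn{\rho_V < \rho_{sV} \le \rho_{sL} < \rho_L}.
#'
#' @param tbl Data frame with columns `rho_star`, `P0`, `mean_nlar_norm`,
#'   `mean_n`, `Cv`.
#' @param T_star Temperature of the rows.
#' @param p0_threshold Threshold for [locate_binodal_liquid()].
#' @return A one-row data.frame with `T_star`, `rho_V`, `rho_sV`, `rho_sL`,
#'   `rho_L`, `ordering_ok`, plus per-value defined flags.
#' @export
estimate_boundaries <- function(tbl, T_star, p0_threshold = 0.005) {
  tbl <- tbl[order(tbl$rho_star), ]
  safely <- function(expr)
    tryCatch(expr, error = function(e) undefined_boundary(conditionMessage(e)))
  bL <- safely(locate_binodal_liquid(tbl$rho_star, tbl$P0, p0_threshold))
  bV <- safely(locate_binodal_vapor(tbl$rho_star, tbl$mean_nlar_norm))
  sH <- safely(locate_spinodal_high(tbl$rho_star, tbl$mean_n, tbl$Cv))
  sL <- safely(locate_spinodal_low(tbl$rho_star, tbl$Cv,
                                   rho_high = if (sH$defined) sH$value else NULL))
  vals <- c(rho_V = bV$value, rho_sV = sL$value, rho_sL = sH$value,
            rho_L = bL$value)
  ordering_ok <- if (all(!is.na(vals))) {
    vals["rho_V"] < vals["rho_sV"] && vals["rho_sV"] <= vals["rho_sL"] &&
      vals["rho_sL"] < vals["rho_L"]
  } else NA
  if (isFALSE(ordering_ok))
    warning(sprintf("boundary ordering violated at T* = %.3g: rho_V=%.3g rho_sV=%.3g rho_sL=%.3g rho_L=%.3g",
                    T_star, vals["rho_V"], vals["rho_sV"], vals["rho_sL"],
                    vals["rho_L"]), call. = FALSE)
  data.frame(T_star = T_star,
             rho_V = vals[["rho_V"]], rho_sV = vals[["rho_sV"]],
             rho_sL = vals[["rho_sL"]], rho_L = vals[["rho_L"]],
             rho_V_defined = bV$defined, rho_sV_defined = sL$defined,
             rho_sL_defined = sH$defined, rho_L_defined = bL$defined,
             ordering_ok = ordering_ok)
}
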