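# Contact-graph clustering and cluster geometry under periodic boundaries.
#
# Two particles are in contact when their minimum-image distance does not
# exceed the contact cutoff (1.3 sigma by default).  Atom-level clusters are
# connected components of the contact graph; chain-level clusters are
# components of the chain-quotient graph (two chains adjacent iff they share
# at least one inter-chain atom contact).

as_frame <- function(x) {
  if (inherits(x, "lj_config"))
    return(list(positions = x$positions, box_side = x$box_side,
                chain_id = x$chain_id))
  if (is.list(x) && !is.null(x$positions) && !is.null(x$box_side))
    return(x)
  stop("expected an lj_config or a frame list with positions and box_side")
}

#' Contact graph of a configuration or frame
#'
#' Edges connect particle pairs whose minimum-image distance is at most
#' `contact_cutoff`.  Bonded chain neighbors sit near \eqn{\sigma} and are
#' therefore contacts too.
#'
#' @param x An `lj_config` or a frame from [get_frame()].
#' @param contact_cutoff Contact distance in \eqn{\sigma} (default 1.3).
#' @return Integer matrix with two columns of 1-based particle indices,
#'   one row per undirected edge (i < j), no self-edges.
#' @export
contact_graph <- function(x, contact_cutoff = 1.3) {
  fr <- as_frame(x)
  if (contact_cutoff >= fr$box_side / 2)
    stop("contact_cutoff must be below half the box side")
  cpp_contact_pairs(fr$positions, fr$box_side, contact_cutoff)
}

#' Identify clusters at the atom or chain level
#'
#' Atom level: connected components of the contact graph.  Chain level:
#' connected components over chains, two chains being linked when any
#' inter-chain atom pair is in contact; isolated particles (or chains) form
#' singleton clusters, so the sizes always partition the system.
#'
#' @param x An `lj_config` or frame.
#' @param contact_cutoff Contact distance (default 1.3).
#' @param level `"atom"` or `"chain"`.
#' @return A list of class `cluster_set`: `membership` (per particle or per
#'   chain), `sizes` (per cluster, label order), `level`, `n_units`.
#' @export
find_clusters <- function(x, contact_cutoff = 1.3, level = c("atom", "chain")) {
  level <- match.arg(level)
  fr <- as_frame(x)
  n <- nrow(fr$positions)
  pairs <- contact_graph(fr, contact_cutoff)
  if (level == "atom") {
    labels <- cpp_components(n, pairs)
  } else {
    if (is.null(fr$chain_id))
      stop("chain-level clustering requires chain topology")
    cid <- fr$chain_id
    n_chains <- max(cid)
    if (nrow(pairs) > 0) {
      ci <- cid[pairs[, 1]]
      cj <- cid[pairs[, 2]]
      keep <- ci != cj
      cpairs <- cbind(pmin(ci[keep], cj[keep]), pmax(ci[keep], cj[keep]))
      cpairs <- unique(cpairs)
    } else {
      cpairs <- matrix(integer(0), 0, 2)
    }
    labels <- cpp_components(n_chains, cpairs)
  }
  sizes <- tabulate(labels, max(labels))
  structure(list(membership = labels, sizes = sizes, level = level,
                 n_units = length(labels)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d %s-level clusters over %d units; largest = %d\n",
              length(x$sizes), x$level, x$n_units, max(x$sizes)))
  invisible(x)
}

#' Radius of gyration of one cluster under periodic boundaries
#'
#' Unwraps the member coordinates by breadth-first traversal of the contact
#' graph using minimum-image displacements (so clusters straddling the box
#' boundary are measured correctly), then computes
#' \eqn{R_g = \sqrt{\frac{1}{n}\sum_i |r_i - r_{cm}|^2}}.
#'
#' @param x An `lj_config` or frame.
#' @param members Integer vector of particle indices forming the cluster;
#'   must be connected at the contact cutoff (otherwise unwrapping is
#'   undefined and an error is raised).
#' @param contact_cutoff Contact distance used for the traversal.
#' @return The radius of gyration (length, \eqn{\sigma}).
#' @export
cluster_gyration <- function(x, members, contact_cutoff = 1.3) {
  fr <- as_frame(x)
  members <- sort(unique(as.integer(members)))
  pos <- fr$positions[members, , drop = FALSE]
  sub <- list(positions = pos, box_side = fr$box_side)
  pairs <- contact_graph(sub, contact_cutoff)
  labels <- rep(1L, length(members))
  geo <- cpp_cluster_geometry(pos, fr$box_side, pairs, labels)
  if (!geo$connected[1])
    stop("member set is not connected at the contact cutoff; unwrapping undefined")
  geo$rg[1]
}

frame_cluster_summary <- function(fr, contact_cutoff, level) {
  pairs <- contact_graph(fr, contact_cutoff)
  n <- nrow(fr$positions)
  if (level == "atom") {
    labels <- cpp_components(n, pairs)
    geo_pairs <- pairs
    geo_labels <- labels
    geo_pos <- fr$positions
  } else {
    cs <- find_clusters(fr, contact_cutoff, "chain")
    labels <- cs$membership
    # project chain labels onto beads; add bonds so every chain is internally
    # connected for the unwrapping traversal
    geo_labels <- labels[fr$chain_id]
    idx <- seq_len(n - 1)
    keep <- fr$chain_id[idx] == fr$chain_id[idx + 1]
    bond_pairs <- cbind(idx[keep], idx[keep] + 1L)
    geo_pairs <- rbind(pairs, bond_pairs)
    geo_pos <- fr$positions
  }
  geo <- cpp_cluster_geometry(geo_pos, fr$box_side, geo_pairs, geo_labels)
  sizes <- if (level == "atom") geo$sizes else tabulate(labels, max(labels))
  # largest cluster: maximal size, ties broken by lowest minimum member index
  ord <- order(-sizes, geo$min_index)
  lar <- ord[1]
  list(sizes = sizes, rg = geo$rg, spanning = geo$spanning,
       mean_n = mean(sizes), n_lar = sizes[lar],
       mean_rg = mean(geo$rg), rg_lar = geo$rg[lar],
       lar_spanning = geo$spanning[lar])
}

#' Cluster-size and gyration statistics over a trajectory
#'
#' Per frame: the mean cluster size \eqn{\langle n\rangle} over all clusters
#' (singletons count as clusters of size 1), the size of the largest cluster
#' \eqn{n_{lar}} (ties broken by lowest minimum particle index), the mean
#' radius of gyration over all clusters, and the largest cluster's
#' \eqn{R_g}.  Time averages are taken over all supplied frames; pass an
#' [analysis_window()] trajectory to honor the equilibration split.  The
#' largest cluster's \eqn{R_g} time series, sizes and spanning flags are
#' retained for the surface-tension estimator.
#'
#' @param traj An `lj_trajectory` (use the analysis window).
#' @param contact_cutoff Contact distance (default 1.3).
#' @param level `"atom"` or `"chain"`.
#' @return A list of class `cluster_stats` with fields `mean_size`,
#'   `mean_largest_size`, `mean_rg`, `mean_rg_largest`, a `per_frame`
#'   data.frame, and `rg_series_largest`, `size_series_largest`,
#'   `spanning_series_largest`.
#' @export
trajectory_cluster_stats <- function(traj, contact_cutoff = 1.3,
                                     level = c("atom", "chain")) {
  level <- match.arg(level)
  nf <- n_frames(traj)
  if (nf == 0) stop("trajectory has no frames")
  if (level == "chain" && is.null(traj$chain_id))
    stop("chain-level statistics require chain topology")
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    fr <- list(positions = traj$positions[[i]], box_side = traj$box_side,
               chain_id = traj$chain_id)
    s <- frame_cluster_summary(fr, contact_cutoff, level)
    rows[[i]] <- data.frame(time = traj$times[i], mean_n = s$mean_n,
                            n_lar = s$n_lar, mean_rg = s$mean_rg,
                            rg_lar = s$rg_lar, lar_spanning = s$lar_spanning)
  }
  pf <- do.call(rbind, rows)
  structure(list(mean_size = mean(pf$mean_n),
                 mean_largest_size = mean(pf$n_lar),
                 mean_rg = mean(pf$mean_rg),
                 mean_rg_largest = mean(pf$rg_lar),
                 per_frame = pf,
                 rg_series_largest = pf$rg_lar,
                 size_series_largest = pf$n_lar,
                 spanning_series_largest = pf$lar_spanning,
                 level = level, contact_cutoff = contact_cutoff,
                 n_units = if (level == "atom") traj$n else
                   length(unique(traj$chain_id))),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("Cluster stats (%s level, cutoff %.2f): <n> = %.3g, <n_lar> = %.3g, <Rg> = %.3g, <Rg_lar> = %.3g over %d frames\n",
              x$level, x$contact_cutoff, x$mean_size, x$mean_largest_size,
              x$mean_rg, x$mean_rg_largest, nrow(x$per_frame)))
  invisible(x)
}

#' Export per-frame cluster assignments as CSV
#'
#' @param traj An `lj_trajectory`.
#' @param path Output CSV path.
#' @param contact_cutoff Contact distance.
#' @param level `"atom"` or `"chain"`.
#' @return Invisibly, the path.
#' @export
write_cluster_csv <- function(traj, path, contact_cutoff = 1.3,
                              level = c("atom", "chain")) {
  level <- match.arg(level)
  rows <- vector("list", n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    fr <- list(positions = traj$positions[[i]], box_side = traj$box_side,
               chain_id = traj$chain_id)
    cs <- find_clusters(fr, contact_cutoff, level)
    rows[[i]] <- data.frame(frame_time = traj$times[i],
                            id = seq_along(cs$membership),
                            cluster_label = cs$membership)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
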