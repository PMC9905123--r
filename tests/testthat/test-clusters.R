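# Contact graphs, cluster identification, and gyration under periodic
# boundaries.

frame_of <- function(pos, box, chain_id = NULL)
  list(positions = pos, box_side = box, chain_id = chain_id)

test_that("the contact rule is r <= 1.3 sigma with minimum images", {
  box <- 10
  expect_equal(nrow(contact_graph(frame_of(rbind(c(1, 1, 1), c(2.2, 1, 1)), box))), 1)
  expect_equal(nrow(contact_graph(frame_of(rbind(c(1, 1, 1), c(2.4, 1, 1)), box))), 0)
  # straddling the boundary: x = 0.1 and box - 0.1 are 0.2 apart
  pbc <- rbind(c(0.1, 5, 5), c(box - 0.1, 5, 5))
  expect_equal(nrow(contact_graph(frame_of(pbc, box))), 1)
  # single atom: empty edge set
  expect_equal(nrow(contact_graph(frame_of(matrix(c(1, 1, 1), 1), box))), 0)
})

test_that("grid contact graph equals the exhaustive pair-scan oracle", {
  for (s in 1:10) {
    cfg <- make_fixture("ideal_gas", n = 100, rho_star = 0.3, seed = s)
    got <- contact_graph(cfg, 1.3)
    want <- oracle_contact_pairs(cfg$positions, cfg$box_side, 1.3)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("cluster partitions match the brute-force union-find oracle", {
  for (s in 1:8) {
    cfg <- make_fixture("ideal_gas", n = 80, rho_star = 0.4, seed = 100 + s)
    got <- find_clusters(cfg, 1.3)$membership
    want <- oracle_components(cfg$n,
                              oracle_contact_pairs(cfg$positions, cfg$box_side, 1.3))
    expect_equal(canon_partition(got), canon_partition(want))
    expect_equal(sum(find_clusters(cfg, 1.3)$sizes), cfg$n)  # partition property
  }
})

test_that("well-separated atoms give all-singleton clusters", {
  cfg <- build_configuration(27, 0.001, arrangement = "lattice", seed = 1)
  cs <- find_clusters(cfg, 1.3)
  expect_equal(cs$sizes, rep(1L, 27))
})

test_that("two chains sharing one inter-chain contact form one chain cluster", {
  # two straight 20-bead chains along x; chain 2 shifted far in y except its
  # first bead, placed 1.2 sigma from chain 1's first bead
  box <- 50
  c1 <- cbind(10 + 0:19, 10, 10)
  c2 <- cbind(10 + 0:19, 25, 10)
  c2[1, ] <- c(10, 11.2, 10)
  fr <- frame_of(rbind(c1, c2), box, chain_id = rep(1:2, each = 20))
  cs <- find_clusters(fr, 1.3, level = "chain")
  expect_equal(cs$sizes, 2L)
  # pull the contact bead away: two separate chain clusters
  c2[1, ] <- c(10, 25, 10)
  fr2 <- frame_of(rbind(c1, c2), box, chain_id = rep(1:2, each = 20))
  expect_equal(sort(find_clusters(fr2, 1.3, "chain")$sizes), c(1L, 1L))
  expect_error(find_clusters(frame_of(c1, box), 1.3, "chain"), "topology")
})

test_that("chain-level clustering equals the quotient-graph oracle", {
  for (s in 1:5) {
    cfg <- build_chain_configuration(8, 5, 0.3, seed = 200 + s)
    got <- find_clusters(cfg, 1.3, "chain")$membership
    want <- oracle_chain_components(cfg$positions, cfg$box_side, 1.3,
                                    cfg$chain_id)
    expect_equal(canon_partition(got), canon_partition(want))
  }
})

test_that("gyration radius handles closed forms and boundary straddling", {
  # 8 cube corners of side a: R_g = (sqrt(3)/2) a
  cube <- make_fixture("cube_corners", side = 2)
  expect_equal(cluster_gyration(cube, 1:8, 2.1), sqrt(3), tolerance = 1e-12)
  # two points 0.2 apart across the boundary: R_g = d/2 = 0.1
  box <- 10
  fr <- frame_of(rbind(c(0.05, 5, 5), c(box - 0.15, 5, 5)), box)
  expect_equal(cluster_gyration(fr, 1:2, 1.3), 0.1, tolerance = 1e-12)
  # disconnected member set: unwrapping undefined
  far <- frame_of(rbind(c(1, 1, 1), c(5, 5, 5)), box)
  expect_error(cluster_gyration(far, 1:2, 1.3), "connected")
})

test_that("gyration of an interior blob equals the no-PBC definition", {
  cfg <- make_fixture("multi_cluster", sizes = 30L, box_side = 20, seed = 4)
  rg <- cluster_gyration(cfg, 1:30, 1.3)
  expect_equal(rg, oracle_rg(cfg$positions), tolerance = 1e-12)
})

test_that("gyration is invariant under rigid shifts across the boundary", {
  cfg <- make_fixture("multi_cluster", sizes = 12L, box_side = 15, seed = 6)
  rg0 <- cluster_gyration(cfg, 1:12, 1.3)
  for (shift in list(c(7.3, 0, 0), c(0, -4.1, 9.9), c(3.3, 3.3, 3.3))) {
    moved <- sweep(cfg$positions, 2, -shift) %% cfg$box_side
    fr <- frame_of(moved, cfg$box_side)
    expect_equal(cluster_gyration(fr, 1:12, 1.3), rg0, tolerance = 1e-10)
  }
})

test_that("a cluster wrapping the whole box is flagged as spanning", {
  box <- 12
  line <- cbind(seq(0.5, box - 0.5, by = 1), 6, 6)  # ring through the boundary
  pairs <- contact_graph(frame_of(line, box), 1.3)
  geo <- ljphase:::cpp_cluster_geometry(line, box, pairs,
                                        rep(1L, nrow(line)))
  expect_true(geo$spanning[1])
  blob <- make_fixture("multi_cluster", sizes = 10L, box_side = 15, seed = 2)
  p2 <- contact_graph(blob, 1.3)
  geo2 <- ljphase:::cpp_cluster_geometry(blob$positions, 15, p2, rep(1L, 10))
  expect_false(geo2$spanning[1])
})

test_that("trajectory statistics reproduce hand-computed averages", {
  # frame 1: clusters {3, 3, 4}; frame 2: 10 singletons; frame 3: one 10-blob
  f1 <- make_fixture("multi_cluster", sizes = c(3, 3, 4), box_side = 18, seed = 1)
  f2 <- build_configuration(10, 10 / 18^3, arrangement = "lattice", seed = 1)
  f3 <- make_fixture("multi_cluster", sizes = 10L, box_side = 18, seed = 2)
  traj <- fake_trajectory(list(f1$positions, f2$positions, f3$positions), 18)
  cs <- trajectory_cluster_stats(traj, 1.3)
  expect_equal(cs$per_frame$mean_n, c(10 / 3, 1, 10))
  expect_equal(cs$per_frame$n_lar, c(4, 1, 10))
  expect_equal(cs$mean_size, mean(c(10 / 3, 1, 10)))
  expect_equal(cs$mean_largest_size, 5)
  expect_equal(cs$per_frame$mean_rg[2], 0)  # all singletons
  expect_error(trajectory_cluster_stats(fake_trajectory(list(), 18)), "frames")
})

test_that("mean and largest sizes tie exactly for equal-size partitions", {
  f <- make_fixture("multi_cluster", sizes = c(5, 5, 5), box_side = 20, seed = 3)
  traj <- fake_trajectory(list(f$positions), 20)
  cs <- trajectory_cluster_stats(traj, 1.3)
  expect_equal(cs$mean_size, cs$mean_largest_size)
})
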