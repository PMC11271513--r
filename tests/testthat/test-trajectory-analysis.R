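test_that("ligand RMSD matches hand-computed displacements", {
  ref <- ligand(c(0, 0), c(5, 0))
  cf3 <- rbind(c(0, 0), c(3, 0), c(3, 0))
  o1 <- rbind(c(5, 0), c(8, 0), c(9, 0))
  tr <- manual_trajectory(cf3, o1)
  r <- ligand_rmsd(tr, ref)
  expect_equal(r$rmsd[1], 0)
  expect_equal(r$rmsd[2], 3)                  # both probes displaced by (3, 0)
  expect_equal(r$rmsd[3], sqrt((9 + 16) / 2)) # displacements 3 and 4
  expect_error(ligand_rmsd(tr, ligand(c(0, 0, 0), c(1, 0, 0))), "dimension")
})

test_that("dissociation detection follows the threshold-persistence rule", {
  mk <- function(rmsd) data.frame(time = seq_along(rmsd), rmsd = rmsd)
  expect_true(is.na(detect_dissociation(mk(c(0, 10, 29.9)))))
  expect_equal(detect_dissociation(mk(c(0, 31, 35))), 2L)
  expect_true(is.na(detect_dissociation(mk(rep(0, 10)))))
  # persistence: a single spike does not count, a sustained excursion does
  crit2 <- dissociation_criterion(threshold = 30, persistence = 2)
  expect_true(is.na(detect_dissociation(mk(c(0, 31, 5, 31, 5)), crit2)))
  expect_equal(detect_dissociation(mk(c(0, 31, 31, 5)), crit2), 2L)
})

test_that("raising the threshold never gives an earlier event", {
  set.seed(17)
  for (rep in 1:20) {
    rmsd <- abs(cumsum(stats::rnorm(60, 0.8, 3)))
    s <- data.frame(time = 1:60, rmsd = rmsd)
    ev <- vapply(c(5, 15, 30, 45), function(th) {
      e <- detect_dissociation(s, dissociation_criterion(threshold = th))
      if (is.na(e)) Inf else as.numeric(e)
    }, numeric(1))
    expect_false(is.unsorted(ev))
  }
})

test_that("k-of-n counting matches the event list", {
  ev <- c(5L, NA, 3L, NA, 8L, 1L, NA, 2L, 9L, 4L) # 7 events in 10 runs
  expect_equal(count_dissociations(ev), list(k = 7L, n = 10L))
  expect_equal(count_dissociations(rep(NA_integer_, 4)), list(k = 0L, n = 4L))
  expect_equal(count_dissociations(1:6), list(k = 6L, n = 6L))
  expect_error(count_dissociations(integer(0)), "non-empty")
})

test_that("pair distances are plain Euclidean norms to the anchor", {
  tr <- manual_trajectory(rbind(c(6, 8), c(1, 1)), rbind(c(5, 12), c(2, 2)))
  pd <- pair_distances(tr, c(0, 0))
  expect_equal(pd$d_cf3[1], 10)
  expect_equal(pd$d_o1[1], 13)
  expect_equal(pd$d_cf3[2], sqrt(2))
  set.seed(9)
  cf3 <- matrix(stats::rnorm(10), 5, 2)
  o1 <- matrix(stats::rnorm(10), 5, 2)
  anchor <- c(2, -1)
  pd2 <- pair_distances(manual_trajectory(cf3, o1), anchor)
  for (i in 1:5) {
    expect_equal(pd2$d_cf3[i], sqrt(sum((cf3[i, ] - anchor)^2)))
    expect_equal(pd2$d_o1[i], sqrt(sum((o1[i, ] - anchor)^2)))
  }
  expect_error(pair_distances(tr, c(0, 0, 0)), "dimension")
})

test_that("the canonical gate medians classify into their own gates", {
  pairs <- data.frame(d_cf3 = c(9.42, 6.27, 40), d_o1 = c(9.97, 12.95, 41))
  lab <- classify_gates(pairs)
  expect_equal(as.character(lab$label),
               c("gateA_deep", "gateB_met", "unbound"))
})

test_that("gate labelling is a total, exclusive partition", {
  set.seed(23)
  pairs <- data.frame(d_cf3 = stats::runif(500, 0, 40),
                      d_o1 = stats::runif(500, 0, 40))
  # include window corners to exercise the closed-lower / open-upper rule
  w <- gate_windows()
  pairs <- rbind(pairs,
                 data.frame(d_cf3 = c(w$gateA_cf3, w$gateB_cf3),
                            d_o1 = c(w$gateA_o1, w$gateB_o1)))
  lab <- classify_gates(pairs, w)
  expect_equal(nrow(lab), nrow(pairs))
  expect_false(any(is.na(lab$label)))
  # lower bound closed, upper bound open
  corner <- classify_gates(data.frame(d_cf3 = 7.8, d_o1 = 7.5), w)
  expect_equal(as.character(corner$label), "gateA_deep")
  edge <- classify_gates(data.frame(d_cf3 = 12.5, d_o1 = 10), w)
  expect_equal(as.character(edge$label), "other_bound")
})

test_that("gate window validation rejects malformed rectangles", {
  expect_error(gate_windows(gateA_cf3 = c(5, 5)), "increasing")
  expect_error(gate_windows(gateB_cf3 = c(8, 12.4), gateB_o1 = c(8, 12.4)),
               "disjoint")
})

test_that("snapshot subsampling keeps equally spaced frames from the start", {
  tr <- manual_trajectory(cbind(0:999, 0), cbind(0:999, 5),
                          times = as.numeric(0:999))
  s10 <- subsample_snapshots(tr, stride = 10)
  expect_equal(n_frames(s10), 100)
  expect_equal(s10$cf3[, 1], seq(0, 990, by = 10))
  s1 <- subsample_snapshots(tr, stride = 1)
  expect_equal(n_frames(s1), 1000)
  sn <- subsample_snapshots(tr, stride = 1000)
  expect_equal(n_frames(sn), 1)
  expect_error(subsample_snapshots(tr, stride = 1001), "stride")
  expect_equal(n_frames(subsample_snapshots(tr, target_count = 100)), 100)
})

test_that("occupancy stats: frequencies sum to one, medians match a sort oracle", {
  pairs <- data.frame(
    d_cf3 = c(9, 9.5, 6, 30),
    d_o1 = c(9, 9.5, 12, 30))
  lab <- classify_gates(pairs)
  expect_equal(as.character(lab$label),
               c("gateA_deep", "gateA_deep", "gateB_met", "unbound"))
  st <- gate_occupancy_stats(lab)
  expect_equal(sum(st$frequencies), 1)
  expect_equal(unname(st$frequencies["gateA_deep"]), 0.5)
  expect_equal(unname(st$frequencies["gateB_met"]), 0.25)
  expect_equal(unname(st$frequencies["unbound"]), 0.25)

  # medians against an explicit sort-based computation, even and odd counts
  set.seed(5)
  d1 <- stats::runif(40, 8, 12.4); d2 <- stats::runif(40, 7.6, 12.4)
  labs <- classify_gates(data.frame(d_cf3 = d1, d_o1 = d2))
  ga <- labs$label == "gateA_deep"
  sort_median <- function(v) {
    v <- sort(v); n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  st2 <- gate_occupancy_stats(labs)
  expect_equal(unname(st2$medians$gateA_deep["d_cf3"]),
               sort_median(d1[ga]))
  expect_error(gate_occupancy_stats(labs[0, ]), "empty")
})

test_that("pose clustering recovers two well-separated families", {
  set.seed(77)
  n <- 6
  mk_frames <- function(center, n) {
    cbind(center[1] + stats::rnorm(n, 0, 0.1),
          center[2] + stats::rnorm(n, 0, 0.1))
  }
  cf3 <- rbind(mk_frames(c(0, 0), n), mk_frames(c(10, 0), n))
  o1 <- cf3 + 3
  tr <- manual_trajectory(cf3, o1)
  cl <- cluster_poses(tr, k = 2, seed = 1)
  truth <- rep(1:2, each = n)

  # exhaustive 2-partition oracle minimizing within-cluster dissimilarity
  flat <- cbind(cf3, o1)
  dmat <- as.matrix(stats::dist(flat)) / sqrt(2)
  best <- NULL; best_cost <- Inf
  for (mask in 1:(2^(2 * n - 1) - 1)) {
    g <- as.integer(intToBits(mask))[seq_len(2 * n)] + 1L
    if (length(unique(g)) < 2) next
    cost <- sum(dmat[g == 1, g == 1]) + sum(dmat[g == 2, g == 2])
    if (cost < best_cost) { best_cost <- cost; best <- g }
  }
  agree <- max(mean(cl$assignments == best), mean(cl$assignments == 3 - best))
  expect_equal(agree, 1)
  expect_equal(max(mean(cl$assignments == truth),
                   mean(cl$assignments == 3 - truth)), 1)

  # two distinct frames -> singleton clusters
  tr2 <- manual_trajectory(rbind(c(0, 0), c(9, 9)), rbind(c(1, 1), c(10, 10)))
  cl2 <- cluster_poses(tr2, k = 2)
  expect_equal(sort(cl2$assignments), c(1, 2))

  # degenerate: all frames identical, zero within-cluster dispersion
  tr3 <- manual_trajectory(matrix(1, 4, 2), matrix(2, 4, 2))
  cl3 <- cluster_poses(tr3, k = 2)
  expect_equal(length(cl3$assignments), 4)
  expect_equal(max(cl3$dissimilarity), 0)

  expect_error(cluster_poses(tr2, k = 3), "fewer")
})
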