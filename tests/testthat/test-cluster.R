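test_that("Kabsch RMSD is zero under rigid transforms and matches bio3d", {
  set.seed(31)
  X <- matrix(rnorm(30), 10L, 3L)
  expect_equal(kabsch_rmsd(X, X), 0)
  Y <- apply_rigid(X, rand_rot(), c(5, 5, 5))
  expect_lt(kabsch_rmsd(X, Y), 1e-6)
  # independent oracle: bio3d's fitted RMSD
  for (i in 1:10) {
    A <- matrix(rnorm(12, sd = 2), 4L, 3L)
    B <- matrix(rnorm(12, sd = 2), 4L, 3L)
    ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    # bio3d prints to 3 decimals
    expect_lt(abs(kabsch_rmsd(A, B) - ref), 5.1e-4)
  }
  expect_error(kabsch_rmsd(X[1:2, ], X[1:2, ]), "3 atoms")
})

test_that("reflections are excluded from the superposition", {
  set.seed(32)
  X <- matrix(rnorm(15), 5L, 3L)
  Y <- X %*% diag(c(1, 1, -1))  # improper image
  expect_gt(kabsch_rmsd(X, Y), 1e-3)
})

test_that("symmetry-corrected RMSD minimises over permutations", {
  fx <- gg_refs()
  X <- frame_coords(fx$refs[["sa/as"]], 1)  # swap-asymmetric state
  swap <- fx$topology$symmetry_perms$swap
  Y <- X[swap, ]  # strand-swapped copy
  r <- symmetry_min_rmsd(X, Y, fx$topology, fx$sel)
  expect_lt(r$rmsd, 1e-6)
  expect_equal(r$perm, "swap")
  expect_gt(kabsch_rmsd(X[fx$sel, ], Y[fx$sel, ]), 1)
  # with only the identity registered it reduces to plain Kabsch
  top_id <- fx$topology
  top_id$symmetry_perms <- top_id$symmetry_perms["identity"]
  r2 <- symmetry_min_rmsd(X, Y, top_id, fx$sel)
  expect_equal(r2$rmsd, kabsch_rmsd(X[fx$sel, ], Y[fx$sel, ]))
  # exhaustive over the 2-element group: min <= identity, and symmetric
  set.seed(33)
  Z <- X + matrix(rnorm(length(X)), ncol = 3L)
  rz <- symmetry_min_rmsd(X, Z, fx$topology, fx$sel)
  expect_lte(rz$rmsd, kabsch_rmsd(X[fx$sel, ], Z[fx$sel, ]) + 1e-12)
  expect_equal(rz$rmsd, symmetry_min_rmsd(Z, X, fx$topology, fx$sel)$rmsd,
               tolerance = 1e-9)
})

test_that("greedy clustering recovers separated bundles with exact percentages", {
  ens <- small_ensemble(counts = c("sa/as" = 10, "as/as" = 6, "aa/aa" = 4),
                        noise_sigma = 0.1, seed = 41)
  fx <- gg_refs()
  cl <- greedy_cluster(ens$traj, cutoff = 1.0, selection = fx$sel)
  expect_equal(length(cl$representatives), 3L)
  expect_true(same_partition(cl$labels, ens$labels))
  expect_equal(sort(cl$percentages, decreasing = TRUE), c(50, 30, 20))
  expect_equal(sum(cl$percentages), 100, tolerance = 1e-9)
  # oracle: every frame within cutoff of its representative, farther from others
  D <- loopdyn:::rmsd_matrix(ens$traj, fx$sel)
  for (f in seq_len(n_frames(ens$traj))) {
    own <- cl$representatives[cl$labels[f]]
    expect_lte(D[f, own], 1.0)
    foreign <- cl$representatives[-cl$labels[f]]
    expect_true(all(D[f, foreign] > 1.0))
  }
  # all identical frames -> one cluster at 100%
  one <- small_ensemble(counts = c("aa/aa" = 5), noise_sigma = 0, seed = 42)
  c1 <- greedy_cluster(one$traj, 1.0, fx$sel)
  expect_equal(c1$percentages, 100)
})

test_that("greedy cutoff limits give one-cluster-per-frame and one cluster", {
  ens <- small_ensemble(counts = c("sa/as" = 4, "aa/aa" = 4), seed = 43)
  fx <- gg_refs()
  tiny <- greedy_cluster(ens$traj, cutoff = 1e-9, selection = fx$sel)
  expect_equal(length(tiny$representatives), n_frames(ens$traj))
  huge <- greedy_cluster(ens$traj, cutoff = 1e6, selection = fx$sel)
  expect_equal(length(huge$representatives), 1L)
})

test_that("symmetry merges strand-swapped copies; disabling it splits them", {
  fx <- gg_refs()
  X <- frame_coords(fx$refs[["sa/as"]], 1)
  swap <- fx$topology$symmetry_perms$swap
  coords <- array(NA_real_, dim = c(6L, nrow(X), 3L))
  set.seed(44)
  for (f in 1:6) {
    base <- if (f %% 2L) X else X[swap, ]
    coords[f, , ] <- base + matrix(rnorm(length(X), sd = 0.05), ncol = 3L)
  }
  traj <- trajectory(coords, fx$topology)
  with_sym <- greedy_cluster(traj, 1.0, fx$sel, symmetry = TRUE)
  expect_equal(length(with_sym$representatives), 1L)
  no_sym <- greedy_cluster(traj, 1.0, fx$sel, symmetry = FALSE)
  expect_equal(length(no_sym$representatives), 2L)
})

test_that("average-linkage clustering matches a naive agglomeration oracle", {
  fx <- gg_refs()
  ens <- small_ensemble(counts = c("sa/as" = 6, "as/as" = 5, "as/sa" = 4),
                        noise_sigma = 0.12, seed = 45)
  D <- loopdyn:::rmsd_matrix(ens$traj, fx$sel)
  for (cutoff in c(0.5, 1.2, 2.5)) {
    got <- hier_cluster_average_linkage(ens$traj, cutoff, fx$sel)
    ref <- naive_average_linkage(D, cutoff)
    expect_true(same_partition(got$labels, ref))
    expect_equal(sum(got$percentages), 100, tolerance = 1e-9)
    # representative is the medoid of its cluster
    for (k in seq_along(got$representatives)) {
      members <- which(got$labels == k)
      means <- rowMeans(D[members, members, drop = FALSE])
      expect_equal(D[got$representatives[k], members],
                   D[members[which.min(means)], members])
    }
  }
  expect_error(hier_cluster_average_linkage(ens$traj, 1.2, fx$sel,
                                            max_frames = 5L), "stride")
})

test_that("both methods recover the construction partition when states are separated", {
  # inter-template separations (~1.9 A) exceed 2 x cutoff at 0.9 A;
  # intra-state spread (sigma 0.05) stays far below the cutoff
  ens <- small_ensemble(counts = c("sa/as" = 8, "as/as" = 6, "aa/aa" = 3,
                                   "as/sa" = 3),
                        noise_sigma = 0.05, seed = 46)
  fx <- gg_refs()
  g <- greedy_cluster(ens$traj, 0.9, fx$sel)
  h <- hier_cluster_average_linkage(ens$traj, 0.9, fx$sel)
  expect_true(same_partition(g$labels, ens$labels))
  expect_true(same_partition(h$labels, ens$labels))
})

test_that("cluster report filters, sorts, aggregates and annotates", {
  res <- structure(list(labels = rep(1:4, times = c(60, 30, 19, 1)) * 1L,
                        representatives = c(1L, 61L, 91L, 110L),
                        sizes = c(60L, 30L, 19L, 1L),
                        percentages = c(60, 30, 19 / 1.1, NA)[1:4],
                        method = "greedy", cutoff = 1, selection = 1:3,
                        symmetry = TRUE), class = "ClusterResult")
  res$percentages <- 100 * res$sizes / sum(res$sizes)
  rep1 <- report_clusters(res, min_pct = 1)
  expect_equal(rep1$percentage, c(54.5454545454545, 27.2727272727273,
                                  17.2727272727273, 0.909090909090909),
               tolerance = 1e-10)
  expect_true(is.na(rep1$cluster[4]))
  expect_equal(sum(rep1$percentage), 100, tolerance = 1e-9)
  rep0 <- report_clusters(res, min_pct = 0)
  expect_equal(nrow(rep0), 4L)
  expect_equal(sum(rep0$percentage), 100, tolerance = 1e-9)
  # state annotation via labeler
  ens <- small_ensemble(counts = c("sa/as" = 5, "as/as" = 3), seed = 47)
  fx <- gg_refs()
  cl <- greedy_cluster(ens$traj, 1.0, fx$sel)
  labeler <- function(f) {
    st <- classify_state(chi_series(trajectory(frame_coords(ens$traj, f),
                                               fx$topology), GG_LOOP)$values[1, ])
    loop_state_label(st[1:2], st[3:4])
  }
  tab <- report_clusters(cl, min_pct = 1, state_labeler = labeler)
  expect_equal(tab$state[order(-tab$percentage)], c("as/sa", "as/as"))
})
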