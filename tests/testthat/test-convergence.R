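test_that("PCA removes rigid-body motion and obeys the trace identity", {
  fx <- gg_refs()
  X <- frame_coords(fx$refs[["as/as"]], 1)
  sel <- fx$sel
  set.seed(51)
  rigid <- array(NA_real_, dim = c(8L, nrow(X), 3L))
  for (f in 1:8) rigid[f, , ] <- apply_rigid(X, rand_rot(), rnorm(3, sd = 8))
  pcm <- fit_pca(trajectory(rigid, fx$topology), sel)
  expect_lt(max(pcm$evals), 1e-8)
  # noisy ensemble: total variance = trace = sum of eigenvalues; orthonormal modes
  ens <- small_ensemble(counts = c("sa/as" = 6, "as/as" = 6), seed = 52)
  pcm2 <- fit_pca(ens$traj, sel)
  # trace identity: with n frames only n-1 modes carry variance, and the
  # total projection variance over them equals the eigenvalue sum
  proj <- project_pcs(ens$traj, pcm2, modes = 1:12)
  expect_equal(sum(apply(proj, 2L, stats::var)), sum(pcm2$evals),
               tolerance = 1e-5)
  G <- crossprod(pcm2$evecs[, 1:10])
  expect_equal(G, diag(10), tolerance = 1e-8)
  expect_true(all(diff(pcm2$evals) <= 1e-12))
  expect_error(fit_pca(trajectory(X, fx$topology), sel), "2 frames")
})

test_that("a single-direction construction yields one mode with the exact variance", {
  fx <- gg_refs()
  sel <- fx$sel
  X <- frame_coords(fx$refs[["aa/aa"]], 1)
  set.seed(53)
  # displacement direction orthogonal to the 6 rigid-body modes of the
  # selection, so superposition leaves it untouched and the construction
  # is exactly one PCA mode
  ref_sel <- sweep(X[sel, ], 2L, colMeans(X[sel, ]))
  rigid <- cbind(rep(c(1, 0, 0), nrow(ref_sel)), rep(c(0, 1, 0), nrow(ref_sel)),
                 rep(c(0, 0, 1), nrow(ref_sel)),
                 as.vector(t(cbind(0, -ref_sel[, 3], ref_sel[, 2]))),
                 as.vector(t(cbind(ref_sel[, 3], 0, -ref_sel[, 1]))),
                 as.vector(t(cbind(-ref_sel[, 2], ref_sel[, 1], 0))))
  Q <- qr.Q(qr(rigid))
  v <- rnorm(3 * length(sel))
  v <- v - Q %*% crossprod(Q, v)
  v <- as.vector(v) / sqrt(sum(v^2))
  deltas <- rep(c(-1.5, 1.5), each = 6L)
  coords <- array(NA_real_, dim = c(12L, nrow(X), 3L))
  for (f in 1:12) {
    m <- X
    m[sel, ] <- m[sel, ] + deltas[f] * matrix(v, ncol = 3L, byrow = TRUE)
    coords[f, , ] <- m
  }
  pcm <- fit_pca(trajectory(coords, fx$topology), sel)
  expect_equal(pcm$evals[1L], stats::var(deltas), tolerance = 1e-6)
  expect_equal(sum(pcm$evals), pcm$evals[1L], tolerance = 1e-6)
  expect_lt(pcm$evals[2L], 1e-8)
  # projections reproduce the construction deltas up to sign and superposition
  proj <- project_pcs(trajectory(coords, fx$topology), pcm, modes = 1L)
  s <- sign(sum(proj[, 1L] * deltas))
  expect_equal(s * proj[, 1L], deltas, tolerance = 1e-6)
  # PCA identity: projection variance equals the eigenvalue
  expect_equal(stats::var(proj[, 1L]), pcm$evals[1L], tolerance = 1e-6)
})

test_that("projection of the mean structure is zero and rigid transforms do not matter", {
  ens <- small_ensemble(counts = c("sa/as" = 5, "aa/aa" = 5), seed = 54)
  fx <- gg_refs()
  pcm <- fit_pca(ens$traj, fx$sel)
  na <- dim(ens$traj$coords)[2L]
  mean_full <- frame_coords(ens$traj, 1)
  mean_full[fx$sel, ] <- pcm$mean
  pm <- project_pcs(trajectory(mean_full, fx$topology), pcm, modes = 1:3)
  expect_equal(as.vector(pm), c(0, 0, 0), tolerance = 1e-8)
  expect_error(project_pcs(ens$traj, pcm, modes = 10000L), "mode index")
  # eigenvalues invariant under a global rigid transform of all frames
  set.seed(55)
  R <- rand_rot(); tv <- rnorm(3, sd = 12)
  rot <- ens$traj
  for (f in seq_len(n_frames(rot))) rot$coords[f, , ] <-
    apply_rigid(frame_coords(ens$traj, f), R, tv)
  pcm_rot <- fit_pca(rot, fx$sel)
  expect_equal(pcm_rot$evals[1:5], pcm$evals[1:5], tolerance = 1e-6)
})

test_that("KDE histograms normalise, respect symmetry and match quadrature", {
  set.seed(61)
  x <- rnorm(400)
  h <- kde_histogram(x, nbins = 300)
  expect_equal(sum(h$masses), 1.0)
  xs <- c(x, -x)
  hs <- kde_histogram(xs, nbins = 301)
  expect_equal(hs$masses, rev(hs$masses), tolerance = 1e-10)
  # large-n standard normal: per-bin mass matches the normal integral
  z <- rnorm(50000)
  hz <- kde_histogram(z, nbins = 300, from = -4, to = 4)
  step <- diff(hz$centers[1:2])
  # quadrature oracle: the KDE of a normal sample estimates the kernel-
  # smoothed density N(0, 1 + bw^2); per-bin masses agree within 2% of
  # the peak mass
  s2 <- sqrt(1 + hz$bw^2)
  ref <- pnorm((hz$centers + step / 2) / s2) - pnorm((hz$centers - step / 2) / s2)
  ref <- ref / sum(ref)
  expect_lt(max(abs(hz$masses - ref)), 0.02 * max(ref))
  expect_error(kde_histogram(rep(1, 5)), "degenerate")
})

test_that("KLD is zero on itself, non-negative, and matches the Gaussian closed form", {
  set.seed(62)
  x <- rnorm(2000)
  h <- kde_histogram(x, nbins = 300)
  expect_equal(kl_divergence(h, h), 0, tolerance = 1e-10)
  curve_self <- kld_curve(x, x, n_eval = 20)
  expect_true(all(abs(curve_self$kld) < 1e-10))
  # Gibbs inequality on every computed point of a mismatched pair
  p <- rnorm(3000); q <- rnorm(3000, mean = 1)
  kc <- kld_curve(p, q, n_eval = 25)
  expect_true(all(kc$kld >= 0))
  # closed form KL(N(0,1) || N(1,1)) = 1/2 nat (moderate n here)
  expect_equal(kc$kld[nrow(kc)], 0.5, tolerance = 0.1)
})

test_that("KLD of two segments from one distribution trends downward", {
  set.seed(63)
  p <- rnorm(8000); q <- rnorm(8000)
  kc <- kld_curve(p, q, n_eval = 40)
  rho <- suppressWarnings(cor(kc$frac, kc$kld, method = "spearman"))
  expect_lt(rho, 0)
})

test_that("population traces report trailing-window percentages", {
  expect_equal(unique(population_trace(rep(1L, 50), window = 10)$pct.1), 100)
  tr <- population_trace(rep(c(1L, 2L), 25), window = 2)
  expect_equal(unique(tr$pct.1), 50)
  expect_equal(unique(tr$pct.2), 50)
  # burn-in discards frames; window bound is enforced
  expect_error(population_trace(rep(1L, 10), window = 8, burn_in = 5), "window")
  tr2 <- population_trace(c(rep(2L, 10), rep(1L, 20)), window = 20, burn_in = 10)
  expect_equal(tr2$pct.1, 100)
  # tracked + untracked percentages sum to 100 per window
  set.seed(64)
  lab <- sample(1:3, 500, replace = TRUE)
  tr3 <- population_trace(lab, window = 50)
  expect_equal(tr3$pct.1 + tr3$pct.2 + tr3$pct.3, rep(100, nrow(tr3)))
  expect_true(all(as.matrix(tr3[, -1]) >= 0 & as.matrix(tr3[, -1]) <= 100))
})

test_that("Markov label traces fluctuate about the stationary distribution", {
  P <- matrix(c(0.98, 0.02, 0.03, 0.97), 2L, 2L, byrow = TRUE)
  # stationary pi = (0.6, 0.4)
  lab <- markov_labels(P, 50000L, seed = 65)
  expect_equal(mean(lab == 1L), 0.6, tolerance = 0.03)
  tr <- population_trace(lab, window = 5000)
  expect_equal(mean(tr$pct.1), 60, tolerance = 3)
  expect_equal(mean(tr$pct.2), 40, tolerance = 3)
})
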