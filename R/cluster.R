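# Symmetry-aware minimum-RMSD and conformational clustering.
#
# Two procedures are provided: a deterministic greedy leader algorithm at a
# 1.0 A cutoff (the symmetry-incorporating method used for all reported
# cluster populations) and average-linkage hierarchical agglomeration cut
# at 1.2 A.  Both superpose and measure on the same atom selection
# (typically the heavy atoms of the internal-loop residues) and minimise
# the RMSD over every registered symmetry permutation of the topology.

center_coords <- function(m) sweep(m, 2L, colMeans(m))

# Least-squares RMSD between two pre-centered coordinate sets, proper
# rotations only (Kabsch via SVD of the 3x3 cross-covariance).
kabsch_rmsd_centered <- function(X0, Y0, ssX, ssY) {
  H <- crossprod(X0, Y0)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  s <- sv$d
  msd <- (ssX + ssY - 2 * (s[1L] + s[2L] + d * s[3L])) / nrow(X0)
  sqrt(max(msd, 0))
}

#' Minimum RMSD after optimal superposition
#'
#' Least-squares RMSD over all proper rotations and translations (Kabsch
#' algorithm; reflections excluded).
#'
#' @param X,Y numeric `n x 3` coordinate matrices with matched rows,
#'   `n >= 3`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(X, Y) {
  stopifnot(is.matrix(X), is.matrix(Y), ncol(X) == 3L, ncol(Y) == 3L)
  if (nrow(X) != nrow(Y)) stop("coordinate sets differ in atom count")
  if (nrow(X) < 3L) stop("need at least 3 atoms for superposition")
  X0 <- center_coords(X); Y0 <- center_coords(Y)
  kabsch_rmsd_centered(X0, Y0, sum(X0^2), sum(Y0^2))
}

# Optimal superposition of Y onto X: returns Y rotated and translated.
superpose_coords <- function(Y, X) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  sv <- svd(crossprod(Y0, X0))
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(Y0 %*% R, 2L, cx, "+")
}

#' Symmetry-corrected minimum RMSD between two frames
#'
#' Minimises the superposed RMSD over every symmetry permutation of the
#' topology (for a self-complementary duplex: identity and the C2 strand
#' swap).  Ties are broken towards the identity.
#'
#' @param X,Y full-topology `atoms x 3` coordinate matrices.
#' @param topology a [topology()]; its `symmetry_perms` are used.
#' @param selection atom indices to superpose and measure on.
#' @return list with `rmsd` (Angstrom) and `perm` (name of the permutation
#'   achieving it).
#' @export
symmetry_min_rmsd <- function(X, Y, topology, selection) {
  Xs <- X[selection, , drop = FALSE]
  best <- Inf; best_perm <- NA_character_
  for (pn in names(topology$symmetry_perms)) {
    p <- topology$symmetry_perms[[pn]]
    r <- kabsch_rmsd(Xs, Y[p[selection], , drop = FALSE])
    if (r < best - 1e-12) { best <- r; best_perm <- pn }
  }
  list(rmsd = best, perm = best_perm)
}

# Precompute, per frame and per permutation, centered selection coordinates
# and their sum of squares.
prep_frames <- function(traj, selection, perms) {
  nf <- n_frames(traj)
  lapply(seq_len(nf), function(f) {
    m <- frame_coords(traj, f)
    lapply(perms, function(p) {
      y <- center_coords(m[p[selection], , drop = FALSE])
      list(m = y, ss = sum(y^2))
    })
  })
}

min_rmsd_prepped <- function(xi, yi) {
  # xi under identity vs yi under every permutation
  x <- xi[[1L]]
  best <- Inf
  for (y in yi) {
    r <- kabsch_rmsd_centered(x$m, y$m, x$ss, y$ss)
    if (r < best) best <- r
  }
  best
}

new_cluster_result <- function(labels, representatives, method, cutoff,
                               selection, symmetry) {
  sizes <- tabulate(labels, nbins = length(representatives))
  structure(list(labels = labels, representatives = representatives,
                 sizes = sizes, percentages = 100 * sizes / length(labels),
                 method = method, cutoff = cutoff, selection = selection,
                 symmetry = symmetry),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult (%s, cutoff %.2f A, symmetry %s): %d frames, %d clusters\n",
              x$method, x$cutoff, if (x$symmetry) "on" else "off",
              length(x$labels), length(x$representatives)))
  top <- order(-x$percentages)[seq_len(min(5L, length(x$percentages)))]
  for (k in top)
    cat(sprintf("  cluster %d: %5.1f%% (rep frame %d)\n", k, x$percentages[k],
                x$representatives[k]))
  invisible(x)
}

#' Greedy leader clustering at a fixed RMSD cutoff
#'
#' Deterministic single-pass scheme: frames are scanned in file order; each
#' frame joins the existing cluster whose representative (its founding
#' frame) lies within `cutoff` by symmetry-corrected minimum RMSD, choosing
#' the lowest-RMSD cluster when several qualify, and otherwise founds a new
#' cluster.  Population percentages are cluster sizes over total frames.
#'
#' @param traj a [trajectory()].
#' @param cutoff RMSD cutoff in Angstrom (default 1.0).
#' @param selection atom indices used for superposition and distance.
#' @param symmetry use the topology's symmetry permutations (default TRUE).
#' @return A `ClusterResult`.
#' @export
greedy_cluster <- function(traj, cutoff = 1.0, selection, symmetry = TRUE) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("empty trajectory")
  perms <- if (symmetry) traj$topology$symmetry_perms else
    traj$topology$symmetry_perms["identity"]
  pf <- prep_frames(traj, selection, perms)
  labels <- integer(nf)
  reps <- integer(0)
  for (f in seq_len(nf)) {
    best <- Inf; best_k <- 0L
    for (k in seq_along(reps)) {
      r <- min_rmsd_prepped(pf[[reps[k]]], pf[[f]])
      if (r <= cutoff && r < best) { best <- r; best_k <- k }
    }
    if (best_k == 0L) {
      reps <- c(reps, f)
      labels[f] <- length(reps)
    } else labels[f] <- best_k
  }
  new_cluster_result(labels, reps, "greedy", cutoff, selection, symmetry)
}

# Full symmetry-min RMSD matrix over frames (or a subset).
rmsd_matrix <- function(traj, selection, symmetry = TRUE) {
  perms <- if (symmetry) traj$topology$symmetry_perms else
    traj$topology$symmetry_perms["identity"]
  pf <- prep_frames(traj, selection, perms)
  nf <- length(pf)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
    D[i, j] <- D[j, i] <- min_rmsd_prepped(pf[[i]], pf[[j]])
  }
  D
}

#' Average-linkage hierarchical clustering at an RMSD threshold
#'
#' Agglomerates on the full symmetry-corrected RMSD matrix with average
#' linkage and cuts the dendrogram at `cutoff`.  The representative of each
#' cluster is its medoid (minimum mean intra-cluster distance).
#'
#' @inheritParams greedy_cluster
#' @param cutoff dendrogram cut height in Angstrom (default 1.2).
#' @param max_frames guard on the O(n^2) distance matrix; stride the
#'   trajectory first if exceeded.
#' @return A `ClusterResult`.
#' @export
hier_cluster_average_linkage <- function(traj, cutoff = 1.2, selection,
                                         symmetry = TRUE, max_frames = 20000L) {
  nf <- n_frames(traj)
  if (nf > max_frames)
    stop("trajectory has ", nf, " frames > matrix cap ", max_frames,
         "; stride the trajectory first")
  if (nf == 1L)
    return(new_cluster_result(1L, 1L, "average", cutoff, selection, symmetry))
  D <- rmsd_matrix(traj, selection, symmetry)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  raw <- stats::cutree(hc, h = cutoff)
  # relabel in order of first appearance, pick medoids
  first_seen <- unique(raw)
  labels <- match(raw, first_seen)
  k <- length(first_seen)
  reps <- vapply(seq_len(k), function(c) {
    members <- which(labels == c)
    if (length(members) == 1L) return(members)
    sub <- D[members, members, drop = FALSE]
    members[which.min(rowMeans(sub))]
  }, integer(1))
  new_cluster_result(labels, reps, "average", cutoff, selection, symmetry)
}

#' Cluster population report with a minimum-percentage filter
#'
#' Rows are sorted by descending population; clusters below `min_pct` are
#' aggregated into a final `"other"` row so that percentages always sum to
#' 100.  An optional `state_labeler(frame)` annotates each representative
#' with its canonical loop state label.
#'
#' @param result a `ClusterResult`.
#' @param min_pct reporting threshold in percent (default 1).
#' @param state_labeler optional `function(frame_index) -> character`.
#' @return data.frame of `cluster`, `percentage`, `n_frames`,
#'   `representative`, and `state` when a labeler is given.
#' @export
report_clusters <- function(result, min_pct = 1.0, state_labeler = NULL) {
  ord <- order(-result$percentages, seq_along(result$percentages))
  pct <- result$percentages[ord]
  keep <- pct >= min_pct
  d <- data.frame(cluster = ord[keep],
                  percentage = pct[keep],
                  n_frames = result$sizes[ord][keep],
                  representative = result$representatives[ord][keep],
                  stringsAsFactors = FALSE)
  if (!is.null(state_labeler) && nrow(d) > 0L)
    d$state <- vapply(d$representative, state_labeler, character(1))
  if (any(!keep)) {
    other <- data.frame(cluster = NA_integer_,
                        percentage = sum(pct[!keep]),
                        n_frames = sum(result$sizes[ord][!keep]),
                        representative = NA_integer_,
                        stringsAsFactors = FALSE)
    if (!is.null(state_labeler)) other$state <- "other"
    d <- rbind(d, other)
  }
  rownames(d) <- NULL
  d
}
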