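# Convergence diagnostics: Cartesian PCA, Kullback-Leibler divergence of
# principal-component projection histograms, and windowed cluster
# population traces.
#
# The KLD diagnostic compares two segments of one ensemble treated as
# independent runs: at each evaluation time t, Gaussian kernel density
# histograms P and Q are built from all data of each segment up to t on a
# shared 300-bin grid, normalised to unit mass, and
#   KLD(t) = sum_i P(t,i) ln(P(t,i) / Q(t,i))
# is reported.  Values approach 0 as the two segments sample the same
# distribution.

flatten_frames <- function(traj, selection) {
  # frames x 3m matrix of selection coordinates (x1,y1,z1,x2,...)
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, 3L * length(selection))
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)[selection, , drop = FALSE]
    out[f, ] <- as.vector(t(m))
  }
  out
}

unflatten <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Principal component analysis of RMS-fit coordinates
#'
#' Two-pass procedure: every frame is superposed on the first frame and
#' averaged; all frames are then re-superposed on that average structure
#' (removing rigid-body motion), the average is recomputed, and the
#' covariance matrix of the fitted Cartesian coordinates is diagonalised.
#' Eigenvalues (variances, A^2) are returned in descending order.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom indices to analyse.
#' @return Object of class `PCModel`: `mean` (m x 3 mean structure),
#'   `evecs` (3m x modes, orthonormal columns), `evals` (descending),
#'   `selection`.
#' @export
fit_pca <- function(traj, selection) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames for PCA")
  X <- flatten_frames(traj, selection)
  ref <- unflatten(X[1L, ])
  fit1 <- t(apply(X, 1L, function(v) as.vector(t(superpose_coords(unflatten(v), ref)))))
  avg <- unflatten(colMeans(fit1))
  fit2 <- t(apply(X, 1L, function(v) as.vector(t(superpose_coords(unflatten(v), avg)))))
  mean_vec <- colMeans(fit2)
  C <- stats::cov(fit2)
  eg <- eigen(C, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  structure(list(mean = unflatten(mean_vec), evecs = eg$vectors, evals = evals,
                 selection = selection),
            class = "PCModel")
}

#' @export
print.PCModel <- function(x, ...) {
  tot <- sum(x$evals)
  cat(sprintf("PCModel: %d atoms, total variance %.3f A^2\n",
              nrow(x$mean), tot))
  k <- min(5L, length(x$evals))
  cat(sprintf("  PC%d: %.3f A^2 (%.1f%%)\n", seq_len(k), x$evals[seq_len(k)],
              100 * x$evals[seq_len(k)] / max(tot, .Machine$double.eps)), sep = "")
  invisible(x)
}

#' Project frames onto principal components
#'
#' Each frame is RMS-fit to the model's mean structure before projection.
#'
#' @param traj a [trajectory()].
#' @param model a `PCModel` from [fit_pca()].
#' @param modes mode indices (1 = largest variance).
#' @return Numeric `frames x modes` matrix of projections.
#' @export
project_pcs <- function(traj, model, modes = 1:2) {
  if (any(modes > ncol(model$evecs)))
    stop("mode index exceeds available modes (", ncol(model$evecs), ")")
  X <- flatten_frames(traj, model$selection)
  mean_vec <- as.vector(t(model$mean))
  fit <- t(apply(X, 1L, function(v)
    as.vector(t(superpose_coords(unflatten(v), model$mean)))))
  sweep(fit, 2L, mean_vec) %*% model$evecs[, modes, drop = FALSE]
}

scott_bw <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("degenerate data: fewer than 2 distinct values")
  s * length(x)^(-1 / 5)
}

#' Gaussian KDE histogram normalised to unit mass
#'
#' A Gaussian kernel density estimate (Scott's-rule bandwidth by default)
#' evaluated at `nbins` equispaced centers; the masses are normalised to
#' sum exactly to 1.
#'
#' @param values numeric sample (>= 2 distinct values).
#' @param nbins number of evaluation bins (default 300).
#' @param from,to grid limits (default: data range).
#' @param bw kernel bandwidth; default Scott's rule `sd(x) * n^(-1/5)`.
#' @return Object of class `Histogram`: `centers`, `masses`, `bw`.
#' @export
kde_histogram <- function(values, nbins = 300L, from = NULL, to = NULL, bw = NULL) {
  if (length(unique(values)) < 2L) stop("degenerate data: fewer than 2 distinct values")
  if (is.null(bw)) bw <- scott_bw(values)
  if (is.null(from)) from <- min(values)
  if (is.null(to)) to <- max(values)
  d <- stats::density(values, bw = bw, from = from, to = to, n = nbins)
  structure(list(centers = d$x, masses = d$y / sum(d$y), bw = bw),
            class = "Histogram")
}

#' Kullback-Leibler divergence between two unit-mass histograms
#'
#' Both mass vectors (which must share one bin grid) receive a small
#' epsilon and are renormalised before the log-ratio, so finite-sample
#' empty bins cannot produce infinities; the result is then guaranteed
#' non-negative (Gibbs' inequality).
#'
#' @param p,q `Histogram` objects or bare mass vectors on a common grid.
#' @param eps regulariser added to every bin (default 1e-10).
#' @return KLD in nats, `sum(p * log(p/q))`.
#' @export
kl_divergence <- function(p, q, eps = 1e-10) {
  pm <- if (inherits(p, "Histogram")) p$masses else p
  qm <- if (inherits(q, "Histogram")) q$masses else q
  if (length(pm) != length(qm)) stop("histograms differ in bin count")
  pm <- pm + eps; pm <- pm / sum(pm)
  qm <- qm + eps; qm <- qm / sum(qm)
  sum(pm * log(pm / qm))
}

#' Time-resolved KLD between two projection segments
#'
#' At each evaluation point, both segments are truncated to the same
#' cumulative fraction of their data, KDE histograms are built on a fixed
#' common grid spanning the union of the full data ranges, and the
#' divergence `KLD(t) = sum_i P ln(P/Q)` is computed (P = first segment,
#' Q = second; the statistic is asymmetric by construction).
#'
#' @param projP,projQ numeric vectors: one mode's projections of each
#'   segment.
#' @param nbins histogram bins (default 300).
#' @param n_eval number of evaluation points on the cumulative-time axis.
#' @param eps zero-bin regulariser (see [kl_divergence()]).
#' @return Object of class `KLDSeries`: data.frame with `frac` (cumulative
#'   data fraction), `nP`, `nQ`, `kld` (nats).
#' @export
kld_curve <- function(projP, projQ, nbins = 300L, n_eval = 200L, eps = 1e-10) {
  if (length(projP) < 2L || length(projQ) < 2L) stop("segments too short")
  rng <- range(c(projP, projQ))
  fracs <- seq(1 / n_eval, 1, length.out = n_eval)
  rows <- lapply(fracs, function(f) {
    np <- max(2L, ceiling(f * length(projP)))
    nq <- max(2L, ceiling(f * length(projQ)))
    p <- projP[seq_len(np)]; q <- projQ[seq_len(nq)]
    if (length(unique(p)) < 2L || length(unique(q)) < 2L) return(NULL)
    hp <- kde_histogram(p, nbins, from = rng[1L], to = rng[2L])
    hq <- kde_histogram(q, nbins, from = rng[1L], to = rng[2L])
    data.frame(frac = f, nP = np, nQ = nq, kld = kl_divergence(hp, hq, eps))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("KLDSeries", "data.frame"))
}

#' Windowed cluster population trace
#'
#' After discarding `burn_in` frames, reports for every evaluation index
#' the percentage of each tracked cluster within the trailing window of
#' `window` frames (both in frames; a configuration layer may map
#' nanoseconds to frames).
#'
#' @param labels integer per-frame cluster ids.
#' @param window trailing window length in frames (>= 1).
#' @param burn_in frames discarded from the start (default 0).
#' @param track cluster ids to trace (default: all observed after burn-in).
#' @return data.frame with `frame` (index into the original label vector of
#'   the window end) and one `pct.<id>` column per tracked cluster.
#' @export
population_trace <- function(labels, window, burn_in = 0L, track = NULL) {
  stopifnot(window >= 1L, burn_in >= 0L)
  if (burn_in >= length(labels)) stop("burn_in >= total frames")
  lab <- labels[(burn_in + 1L):length(labels)]
  n <- length(lab)
  if (window > n) stop("window (", window, ") > remaining frames (", n, ")")
  if (is.null(track)) track <- sort(unique(lab))
  ends <- window:n
  out <- data.frame(frame = ends + burn_in)
  for (cl in track) {
    cs <- c(0, cumsum(lab == cl))
    out[[paste0("pct.", cl)]] <- 100 * (cs[ends + 1L] - cs[ends - window + 1L]) / window
  }
  out
}
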