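# Two-dimensional potential-of-mean-force landscapes over principal
# component projections, by direct Boltzmann inversion of a 2D occupancy
# histogram: F(i,j) = -kT ln(N(i,j) / N_max), so the global minimum is 0
# by construction and empty bins are masked.  Surfaces are stored in kT
# units; the kcal/mol conversion at the stated temperature is metadata.

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/(mol K)

#' 2D potential of mean force from projections
#'
#' @param pc1,pc2 equal-length per-frame reaction-coordinate values
#'   (typically the first two PC projections).
#' @param nbins bins per axis (default 100).
#' @param temperature Kelvin (metadata for the kcal/mol conversion).
#' @param limits optional list(x = c(lo, hi), y = c(lo, hi)); default data
#'   range.
#' @return Object of class `PMFGrid`: bin edges/centers, `counts`, free
#'   energy `F` in kT (NA where masked), `mask`, `temperature`, `kT_kcal`.
#' @export
pmf2d <- function(pc1, pc2, nbins = 100L, temperature = 300, limits = NULL) {
  stopifnot(length(pc1) == length(pc2), length(pc1) >= 1L)
  xr <- if (is.null(limits$x)) range(pc1) else limits$x
  yr <- if (is.null(limits$y)) range(pc2) else limits$y
  xe <- seq(xr[1L], xr[2L], length.out = nbins + 1L)
  ye <- seq(yr[1L], yr[2L], length.out = nbins + 1L)
  ix <- pmin(pmax(findInterval(pc1, xe, all.inside = TRUE), 1L), nbins)
  iy <- pmin(pmax(findInterval(pc2, ye, all.inside = TRUE), 1L), nbins)
  counts <- matrix(tabulate((iy - 1L) * nbins + ix, nbins = nbins * nbins),
                   nbins, nbins)
  mask <- counts == 0L
  Fm <- matrix(NA_real_, nbins, nbins)
  Fm[!mask] <- -log(counts[!mask] / max(counts))
  structure(list(xedges = xe, yedges = ye,
                 xcenters = (xe[-1L] + xe[-length(xe)]) / 2,
                 ycenters = (ye[-1L] + ye[-length(ye)]) / 2,
                 counts = counts, F = Fm, mask = mask,
                 temperature = temperature, kT_kcal = KB_KCAL * temperature),
            class = "PMFGrid")
}

#' @export
print.PMFGrid <- function(x, ...) {
  cat(sprintf("PMFGrid: %dx%d bins, %d occupied, F range 0 .. %.2f kT (kT = %.4f kcal/mol at %g K)\n",
              nrow(x$F), ncol(x$F), sum(!x$mask), max(x$F, na.rm = TRUE),
              x$kT_kcal, x$temperature))
  invisible(x)
}

#' @export
plot.PMFGrid <- function(x, ..., max_kT = NULL) {
  Fm <- x$F
  if (!is.null(max_kT)) Fm[Fm > max_kT] <- NA
  graphics::image(x$xcenters, x$ycenters, Fm, xlab = "PC1", ylab = "PC2",
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE), ...)
  invisible(x)
}

grid_neighbors <- function(i, j, n1, n2) {
  di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
  ii <- i + di; jj <- j + dj
  ok <- (ii >= 1L & ii <= n1 & jj >= 1L & jj <= n2) & !(di == 0L & dj == 0L)
  cbind(ii[ok], jj[ok])
}

#' Detect free-energy basins on a PMF grid
#'
#' Local minima over the 8-neighborhood of unmasked bins, with
#' persistence-based merging: scanning bins in ascending free energy, a
#' minimum whose depth below its lowest connecting saddle is less than
#' `depth_threshold` is merged into the deeper basin it first touches
#' (suppressing shot-noise minima).  Each unmasked bin is assigned to the
#' basin it floods into, giving basin population shares.
#'
#' @param grid a [pmf2d()] result.
#' @param depth_threshold minimum basin depth in kT to count as distinct
#'   (default 0.5).
#' @param min_separation minimum Chebyshev bin distance between surviving
#'   minima; closer pairs are merged into the deeper one (default 1,
#'   i.e. only coincident/adjacent bins merge).
#' @param min_share_pct basins that first touch another basin across an
#'   unsampled (masked) saddle while holding less than this percentage of
#'   the total population are absorbed regardless of depth: a smattering
#'   of outlier frames cannot claim a distinct minimum (default 1,
#'   mirroring the cluster reporting filter).
#' @return data.frame of basins sorted by F: `ix`, `iy` (bin indices),
#'   `x`, `y` (bin centers), `F` (kT), `share_pct` (percent of frames in
#'   the basin's catchment).
#' @export
find_minima <- function(grid, depth_threshold = 0.5, min_separation = 1L,
                        min_share_pct = 1.0) {
  Fm <- grid$F
  n1 <- nrow(Fm); n2 <- ncol(Fm)
  open_bins <- which(!grid$mask)
  if (length(open_bins) == 0L) stop("fully masked grid")
  # masked bins are traversable at a level just above the highest occupied
  # bin, so disconnected occupied islands can flood together; an isolated
  # single-count bin then has zero depth and always merges, while a deep
  # well on its own island keeps its full depth and stays distinct
  ceiling_F <- max(Fm[open_bins]) + 1e-9
  Fm[grid$mask] <- ceiling_F
  ord <- order(Fm)
  # union-find
  parent <- seq_len(n1 * n2)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  basin_min <- integer(0)          # root bin index of each basin's minimum
  alive <- logical(0)              # basin not yet merged away
  basin_of_root <- integer(n1 * n2)
  processed <- logical(n1 * n2)
  flooded <- numeric(n1 * n2)      # per-root accumulated occupancy counts
  total_counts <- sum(grid$counts)
  min_counts <- min_share_pct / 100 * total_counts
  for (b in ord) {
    i <- ((b - 1L) %% n1) + 1L; j <- ((b - 1L) %/% n1) + 1L
    nb <- grid_neighbors(i, j, n1, n2)
    nbl <- (nb[, 2L] - 1L) * n1 + nb[, 1L]
    nbl <- nbl[processed[nbl]]
    if (length(nbl) == 0L) {
      basin_min <- c(basin_min, b)
      alive <- c(alive, TRUE)
      basin_of_root[b] <- length(basin_min)
      flooded[b] <- grid$counts[b]
      processed[b] <- TRUE
      next
    }
    roots <- unique(vapply(nbl, find, integer(1)))
    if (length(roots) == 1L) {
      parent[b] <- roots
      flooded[roots] <- flooded[roots] + grid$counts[b]
    } else {
      # b is a saddle between >= 2 basins; merge the shallow ones
      ids <- basin_of_root[roots]
      depths <- Fm[b] - Fm[basin_min[ids]]
      deepest <- which.max(depths)
      target_root <- roots[deepest]
      for (k in seq_along(roots)) {
        if (k == deepest) next
        if (depths[k] < depth_threshold ||
            (grid$mask[b] && flooded[roots[k]] < min_counts)) {
          alive[ids[k]] <- FALSE
          parent[roots[k]] <- target_root
          flooded[target_root] <- flooded[target_root] + flooded[roots[k]]
        }
      }
      parent[b] <- target_root
      flooded[target_root] <- flooded[target_root] + grid$counts[b]
    }
    processed[b] <- TRUE
  }
  live <- which(alive & !grid$mask[basin_min])
  # proximity merging of surviving minima
  if (length(live) > 1L && min_separation >= 1L) {
    mi <- ((basin_min[live] - 1L) %% n1) + 1L
    mj <- ((basin_min[live] - 1L) %/% n1) + 1L
    o <- order(Fm[basin_min[live]])
    keep <- rep(TRUE, length(live))
    for (a in seq_along(o)) for (bb in seq_len(a - 1L)) {
      if (!keep[o[a]] || !keep[o[bb]]) next
      if (max(abs(mi[o[a]] - mi[o[bb]]), abs(mj[o[a]] - mj[o[bb]])) <= min_separation) {
        keep[o[a]] <- FALSE
        parent[find(basin_min[live[o[a]]])] <- find(basin_min[live[o[bb]]])
      }
    }
    alive[live[!keep]] <- FALSE
    live <- which(alive)
  }
  # catchment shares
  root_of <- vapply(open_bins, find, integer(1))
  share <- vapply(live, function(id) {
    sum(grid$counts[open_bins[root_of == find(basin_min[id])]])
  }, numeric(1))
  share <- 100 * share / sum(grid$counts)
  mins <- basin_min[live]
  out <- data.frame(
    ix = ((mins - 1L) %% n1) + 1L,
    iy = ((mins - 1L) %/% n1) + 1L,
    F = Fm[mins],
    share_pct = share)
  out$x <- grid$xcenters[out$ix]
  out$y <- grid$ycenters[out$iy]
  out <- out[order(out$F), c("ix", "iy", "x", "y", "F", "share_pct")]
  rownames(out) <- NULL
  out
}
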