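# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

GG_SEQ <- "UCUGGGGCCAGA"
GG_LOOP <- c(6L, 7L, 18L, 19L)

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
rand_rot <- function() {
  qr_d <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

apply_rigid <- function(m, R, t) sweep(m %*% R, 2L, t, "+")

# second-formula dihedral oracle: arccos of normal angle, sign from the
# triple product of the normals with the central bond
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
  ct <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(max(ct, -1), 1)) * 180 / pi
  s <- sum(pracma::cross(n1, n2) * b2)
  if (s < 0) -ang else ang
}

# independently coded naive average-linkage agglomeration: merge the
# closest pair of clusters (average inter-cluster distance) until the
# minimum exceeds the cutoff; returns per-item partition labels
naive_average_linkage <- function(D, cutoff) {
  groups <- as.list(seq_len(nrow(D)))
  repeat {
    k <- length(groups)
    if (k == 1L) break
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- mean(D[groups[[i]], groups[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    if (best > cutoff) break
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  lab <- integer(nrow(D))
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# partitions equal up to label renaming?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}

# cache the (somewhat expensive) reference duplexes across tests
gg_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tmpls <- gg_loop_templates()
      refs <- lapply(tmpls, function(ch) build_duplex(GG_SEQ, chi = ch))
      top <- set_symmetry(refs[[1L]]$topology, "A", "B")
      cache <<- list(templates = tmpls, refs = refs, topology = top,
                     sel = select_atoms(top, residues = GG_LOOP, atoms = "heavy"))
    }
    cache
  }
})

# small four-state ensemble used by several modules
small_ensemble <- function(counts = c("sa/as" = 10, "as/as" = 6, "aa/aa" = 4),
                           noise_sigma = 0.1, seed = 11, ...) {
  fx <- gg_refs()
  spec <- ensemble_spec(GG_SEQ, templates = fx$templates[names(counts)],
                        counts = counts, noise_sigma = noise_sigma,
                        seed = seed, ...)
  ens <- sample_ensemble(spec)
  ens$traj$topology <- fx$topology
  ens
}

# minimal hand-made topology: one "residue" per atom spec row
toy_topology <- function(names, elements = NULL, chain = "A",
                         resname = "G", resno = NULL) {
  n <- length(names)
  topology(data.frame(
    name = names,
    element = if (is.null(elements)) substr(names, 1L, 1L) else elements,
    chain = rep_len(chain, n),
    resno = if (is.null(resno)) rep(1L, n) else resno,
    resname = rep_len(resname, n), stringsAsFactors = FALSE))
}
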