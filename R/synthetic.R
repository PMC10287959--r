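# Synthetic ground-truth ensembles.
#
# Ensembles are built from an idealized antiparallel duplex: rigid
# ribose/phosphate fragments placed on an A-form-like helix (rise 2.81 A,
# twist 32.7 deg), with each base attached through the glycosidic bond and
# rotated so the computed chi torsion hits its target exactly.  The second
# strand is the image of the first under a proper C2 rotation, so a
# palindromic duplex with a swap-symmetric chi pattern is exactly
# symmetric under the strand swap.  Geometry is internally consistent
# (correct atom names, bond-scale distances, planar bases) but makes no
# claim of stereochemical accuracy: it exists to give the torsion, RMSD,
# and hydrogen-bond machinery inputs with known ground truth.

deg2rad <- function(x) x * pi / 180

rot_z <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3L, 3L)
}

# Rodrigues rotation of points about a unit axis through the origin
rotate_about <- function(pts, axis, deg) {
  t <- deg2rad(deg)
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  R <- diag(3L) + sin(t) * K + (1 - cos(t)) * (K %*% K)
  pts %*% t(R)
}

# regular n-gon in 2D, side length s, centered at origin, vertex 1 on +y
ring2d <- function(n, s) {
  R <- s / (2 * sin(pi / n))
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1L) / n
  cbind(R * cos(ang), R * sin(ang))
}

# hexagon fused on edge A-B (two adjacent vertices), built on the side of
# the edge away from `away`; returns the 4 new vertices walking from A to B
fused_hexagon <- function(A, B, away) {
  side <- sqrt(sum((B - A)^2))
  mid <- (A + B) / 2
  e <- (B - A) / side
  nrm <- c(-e[2], e[1])
  if (sum(nrm * (mid - away)) < 0) nrm <- -nrm
  ctr <- mid + nrm * side * sqrt(3) / 2
  angA <- atan2(A[2] - ctr[2], A[1] - ctr[1])
  angB <- atan2(B[2] - ctr[2], B[1] - ctr[1])
  step <- (angB - angA + 3 * pi) %% (2 * pi) - pi  # signed +-60 deg
  t(vapply(1:4, function(k) {
    a <- angA - k * step
    ctr + side * c(cos(a), sin(a))
  }, numeric(2)))
}

radial_sub <- function(vertex, center, len) {
  d <- vertex - center
  vertex + d / sqrt(sum(d^2)) * len
}

# 2D base template: attachment atom (N9/N1) first, at origin, ring extending
# along +x.  Returns list(names, coords2d).
base_template <- function(letter) {
  if (letter %in% c("G", "A")) {
    pent <- ring2d(5, 1.37)                     # N9 C8 N7 C5 C4
    hex_new <- fused_hexagon(pent[4L, ], pent[5L, ], colMeans(pent))  # C6 N1 C2 N3
    names <- c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "N3")
    xy <- rbind(pent, hex_new)
    hex_ctr <- colMeans(xy[c(4L, 5L, 6L, 7L, 8L, 9L), ])
    if (letter == "G") {
      xy <- rbind(xy, radial_sub(xy[6L, ], hex_ctr, 1.23),   # O6 on C6
                  radial_sub(xy[8L, ], hex_ctr, 1.34))       # N2 on C2
      names <- c(names, "O6", "N2")
    } else {
      xy <- rbind(xy, radial_sub(xy[6L, ], hex_ctr, 1.34))   # N6 on C6
      names <- c(names, "N6")
    }
  } else {
    xy <- ring2d(6, 1.39)                       # N1 C2 N3 C4 C5 C6
    ctr <- c(0, 0)
    names <- c("N1", "C2", "N3", "C4", "C5", "C6")
    xy <- rbind(xy, radial_sub(xy[2L, ], ctr, 1.23))         # O2 on C2
    names <- c(names, "O2")
    if (letter == "C") {
      xy <- rbind(xy, radial_sub(xy[4L, ], ctr, 1.34))       # N4 on C4
      names <- c(names, "N4")
    } else {
      xy <- rbind(xy, radial_sub(xy[4L, ], ctr, 1.23))       # O4 on C4
      names <- c(names, "O4")
    }
  }
  # move attachment atom to origin, point ring centroid along +x
  xy <- sweep(xy, 2L, xy[1L, ])
  ctr <- colMeans(xy[seq_len(if (letter %in% c("G", "A")) 5L else 6L), ])
  ang <- atan2(ctr[2], ctr[1])
  Rm <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2L, 2L)
  list(names = names, xy = xy %*% t(Rm))
}

# One nucleotide in its local frame, base rotated to the chi target.
# Returns list(names, elements, coords).
build_residue_local <- function(letter, chi_target) {
  pent <- ring2d(5, 1.41)  # C1' C2' C3' C4' O4'
  sugar_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  sugar <- cbind(pent, 0)
  ctr <- c(0, 0, 0)
  rad <- function(i, len, dz) {
    d <- sugar[i, ] - ctr; d[3L] <- 0
    sugar[i, ] + d / sqrt(sum(d^2)) * len + c(0, 0, dz)
  }
  o2p <- rad(2L, 1.35, -0.45)
  o3p <- rad(3L, 1.38, -0.30)
  c5p <- rad(4L, 1.25, 0.95)
  o5p <- c5p + (c5p - sugar[4L, ]) / sqrt(sum((c5p - sugar[4L, ])^2)) * 1.42 + c(0, 0, 0.2)
  pat <- o5p + c(0.4, -0.4, 1.45)
  op1 <- pat + c(1.35, 0.55, 0.25)
  op2 <- pat + c(-1.2, 0.75, 0.45)
  bb_names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                "O3'", "C2'", "O2'", "C1'")
  bb <- rbind(pat, op1, op2, o5p, c5p, sugar[4L, ], sugar[5L, ], sugar[3L, ],
              o3p, sugar[2L, ], o2p, sugar[1L, ])
  # glycosidic attachment
  c1 <- sugar[1L, ]; o4 <- sugar[5L, ]
  u <- c(0.15, 0.55, 0.82); u <- u / sqrt(sum(u^2))
  npos <- c1 + 1.47 * u
  bt <- base_template(letter)
  axis <- (npos - c1) / 1.47
  perp <- (o4 - c1) - sum((o4 - c1) * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  base <- t(vapply(seq_len(nrow(bt$xy)), function(i)
    npos + bt$xy[i, 1L] * axis + bt$xy[i, 2L] * perp, numeric(3)))
  # rotate base about the glycosidic axis so chi hits the target exactly
  coords <- rbind(bb, base)
  names_all <- c(bb_names, bt$names)
  chi_ref <- if (letter %in% c("G", "A")) "C4" else "C2"
  q <- match(c("O4'", "C1'", bt$names[1L], chi_ref), names_all)
  cur <- dihedral(coords[q[1L], ], coords[q[2L], ], coords[q[3L], ], coords[q[4L], ])
  nb <- nrow(bb)
  base_rows <- (nb + 1L):nrow(coords)
  shifted <- sweep(coords[base_rows, , drop = FALSE], 2L, npos)
  shifted <- rotate_about(shifted, axis, chi_target - cur)
  coords[base_rows, ] <- sweep(shifted, 2L, npos, "+")
  list(names = names_all, elements = element_from_name(names_all), coords = coords)
}

#' Build an idealized duplex at prescribed chi torsions
#'
#' Places rigid nucleotide fragments on an A-form-like helix and rotates
#' each base about its glycosidic bond so the computed chi equals the
#' target to machine precision.  The second strand is the proper C2 image
#' of the first, so palindromic duplexes with swap-symmetric chi patterns
#' have exact strand-swap symmetry.
#'
#' @param sequence strand sequence (string of A/C/G/U); the duplex pairs
#'   the strand with itself (two chains A and B of this sequence,
#'   antiparallel), or a length-2 vector of strand strings.
#' @param chi per-residue chi targets in degrees, length `2 * L` (strand A
#'   residues 1..L then strand B 1..L), recycled from length 1 (default
#'   -160, anti).
#' @param rise,twist helical rise (A) and twist (deg) per residue.
#' @param radius helix radius offset (A).
#' @return A one-frame [trajectory()] whose topology has chains A and B.
#' @export
build_duplex <- function(sequence, chi = -160, rise = 2.81, twist = 32.7,
                         radius = 4.0) {
  seqs <- if (length(sequence) == 1L) c(sequence, sequence) else sequence
  s1 <- strsplit(toupper(seqs[1L]), "")[[1L]]
  s2 <- strsplit(toupper(seqs[2L]), "")[[1L]]
  if (length(s1) != length(s2)) stop("strands must have equal length")
  bad <- setdiff(c(s1, s2), c("A", "C", "G", "U"))
  if (length(bad)) stop("invalid nucleotide letter: ", paste(bad, collapse = ","))
  L <- length(s1)
  chi <- rep_len(chi, 2L * L)
  H <- rise * (L - 1L)
  place <- function(local, k, strand) {
    p <- sweep(local, 2L, c(radius, 0, 0), "+")
    p <- p %*% t(rot_z(twist * (k - 1L)))
    p <- sweep(p, 2L, c(0, 0, rise * (k - 1L)), "+")
    if (strand == 2L) p <- cbind(p[, 1L], -p[, 2L], H - p[, 3L])
    p
  }
  rows <- list(); coord_list <- list()
  for (strand in 1:2) {
    sq <- if (strand == 1L) s1 else s2
    for (k in seq_len(L)) {
      res <- build_residue_local(sq[k], chi[(strand - 1L) * L + k])
      rows[[length(rows) + 1L]] <- data.frame(
        name = res$names, element = res$elements,
        chain = if (strand == 1L) "A" else "B", resno = k,
        resname = sq[k], stringsAsFactors = FALSE)
      coord_list[[length(coord_list) + 1L]] <- place(res$coords, k, strand)
    }
  }
  top <- topology(do.call(rbind, rows))
  trajectory(do.call(rbind, coord_list), top)
}

#' Chi target vector for a loop state template
#'
#' @param states loop-residue state letters (`"s"`/`"a"`), ordered as
#'   `loop` is.
#' @param loop internal residue indices of the loop residues.
#' @param n_residues total residues in the duplex (both strands).
#' @param syn,anti chi targets (degrees) for syn and anti letters.
#' @param background chi for all non-loop residues (default `anti`).
#' @return Numeric chi vector of length `n_residues`.
#' @export
loop_template <- function(states, loop, n_residues, syn = 25, anti = -160,
                          background = anti) {
  stopifnot(length(states) == length(loop), all(states %in% c("s", "a")))
  chi <- rep(background, n_residues)
  chi[loop] <- ifelse(states == "s", syn, anti)
  chi
}

#' Four-state template set for the 2x2 GG/GG loop duplex
#'
#' The canonical synthetic study system: the self-complementary 12-mer
#' r(UCUGGGGCCAGA)2 whose central 2x2 GG/GG internal loop (residues
#' 6,7 on strand A and 18,19 on strand B, internal indexing) adopts four
#' discrete states: syn-anti/anti-syn ("sa/as"), anti-syn/anti-syn
#' ("as/as"), all-anti ("aa/aa"), and a second, minor state of the
#' sa/as symmetry class ("as/sa").  Because the letter pattern of the
#' minor state is the exact strand-swap image of the major one, it is
#' built at different within-region chi targets (syn -60, anti +130
#' instead of +25/-160) so that it is a geometrically distinct basin
#' rather than the C2 image of the major state; all pairwise
#' symmetry-corrected inter-template RMSDs over loop heavy atoms are then
#' around 2 A, well above the 1 A clustering cutoff.
#'
#' @param loop internal residue indices of the loop (default
#'   `c(6, 7, 18, 19)`).
#' @param n_residues total residues (default 24).
#' @return Named list of four chi target vectors for [build_duplex()].
#' @export
gg_loop_templates <- function(loop = c(6L, 7L, 18L, 19L), n_residues = 24L) {
  list(
    "sa/as" = loop_template(c("s", "a", "a", "s"), loop, n_residues),
    "as/as" = loop_template(c("a", "s", "a", "s"), loop, n_residues),
    "aa/aa" = loop_template(c("a", "a", "a", "a"), loop, n_residues),
    "as/sa" = loop_template(c("a", "s", "s", "a"), loop, n_residues,
                            syn = -60, anti = 130))
}

#' Specification of a synthetic ensemble
#'
#' @param sequence strand sequence passed to [build_duplex()].
#' @param templates named list of per-residue chi target vectors (see
#'   [loop_template()]); the reserved name `"noise"` generates dispersed
#'   frames by large per-atom distortion (sigma `noise_big`) of the first
#'   template, guaranteeing singleton clusters.
#' @param counts named integer vector of exact per-template frame counts,
#'   or `weights` for multinomial draws (exactly one of the two).
#' @param weights optional named numeric weights (normalised internally).
#' @param n total frames (required with `weights`).
#' @param noise_sigma isotropic Gaussian coordinate noise sd in Angstrom
#'   (default 0.15).
#' @param noise_big distortion sd for `"noise"` frames (default 3).
#' @param seed mandatory RNG seed; all draws come from one seeded stream.
#' @param order `"shuffle"` (random frame order), `"block"` (template
#'   blocks in order), or `"markov"` (labels from `transition`).
#' @param transition right-stochastic matrix over templates for
#'   `order = "markov"`.
#' @return Object of class `EnsembleSpec`.
#' @export
ensemble_spec <- function(sequence, templates, counts = NULL, weights = NULL,
                          n = NULL, noise_sigma = 0.15, noise_big = 3.0,
                          seed, order = c("shuffle", "block", "markov"),
                          transition = NULL) {
  order <- match.arg(order)
  if (missing(seed)) stop("seed is mandatory")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(counts) == is.null(weights))
    stop("give exactly one of counts or weights")
  if (!is.null(weights)) {
    if (any(weights < 0) || sum(weights) <= 0) stop("weights must be >= 0 and normalizable")
    if (is.null(n)) stop("n required with weights")
  }
  tn <- names(templates)
  if (is.null(tn) || any(!nzchar(tn))) stop("templates must be named")
  lbl <- names(if (!is.null(counts)) counts else weights)
  if (!all(lbl %in% tn)) stop("counts/weights name not among templates: ",
                              paste(setdiff(lbl, tn), collapse = ","))
  if (order == "markov") {
    if (is.null(transition)) stop("markov order needs a transition matrix")
    if (is.null(n)) stop("n required with markov order")
  }
  structure(list(sequence = sequence, templates = templates, counts = counts,
                 weights = weights, n = n, noise_sigma = noise_sigma,
                 noise_big = noise_big, seed = seed, order = order,
                 transition = transition),
            class = "EnsembleSpec")
}

#' Sample a label sequence from a Markov chain
#'
#' The first label is drawn from the stationary distribution; subsequent
#' labels follow the transition matrix.
#'
#' @param transition right-stochastic matrix (rows sum to 1).
#' @param n sequence length.
#' @param seed RNG seed.
#' @return Integer label sequence in `1..nrow(transition)` (named if the
#'   matrix has rownames).
#' @export
markov_labels <- function(transition, n, seed) {
  P <- as.matrix(transition)
  if (nrow(P) != ncol(P) || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix must be square and right-stochastic")
  set.seed(seed)
  eg <- eigen(t(P))
  i <- which.min(abs(eg$values - 1))
  pi0 <- abs(Re(eg$vectors[, i])); pi0 <- pi0 / sum(pi0)
  k <- nrow(P)
  lab <- integer(n)
  lab[1L] <- sample.int(k, 1L, prob = pi0)
  for (t in seq_len(n - 1L)) lab[t + 1L] <- sample.int(k, 1L, prob = P[lab[t], ])
  if (!is.null(rownames(P))) names(lab) <- rownames(P)[lab]
  lab
}

#' Generate a synthetic duplex ensemble with ground-truth labels
#'
#' Builds one reference structure per template with [build_duplex()],
#' draws a per-frame template label sequence (exact counts, multinomial
#' weights, or Markov-ordered), and perturbs every regular frame with
#' isotropic Gaussian coordinate noise; `"noise"` frames get a large
#' per-atom distortion instead, making each one a dispersed singleton.
#' All randomness comes from one stream seeded with `spec$seed`: label
#' order first, then per-frame noise in frame order, so output is
#' bit-reproducible.
#'
#' @param spec an [ensemble_spec()].
#' @return list with `traj` (a [trajectory()]) and `labels` (character
#'   per-frame template names, the ground truth).
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  refs <- lapply(names(spec$templates), function(nm) {
    if (nm == "noise") return(NULL)
    build_duplex(spec$sequence, chi = spec$templates[[nm]])
  })
  names(refs) <- names(spec$templates)
  base_top <- refs[[which(!vapply(refs, is.null, logical(1)))[1L]]]$topology
  set.seed(spec$seed)
  tnames <- names(spec$templates)
  if (spec$order == "markov") {
    P <- spec$transition
    lab_idx <- {
      # draw from the already-seeded stream (do not reseed)
      eg <- eigen(t(P)); i <- which.min(abs(eg$values - 1))
      pi0 <- abs(Re(eg$vectors[, i])); pi0 <- pi0 / sum(pi0)
      l <- integer(spec$n); l[1L] <- sample.int(nrow(P), 1L, prob = pi0)
      for (t in seq_len(spec$n - 1L)) l[t + 1L] <- sample.int(nrow(P), 1L, prob = P[l[1L + t - 1L], ])
      l
    }
    labels <- tnames[lab_idx]
  } else if (!is.null(spec$counts)) {
    labels <- rep(names(spec$counts), times = spec$counts)
    if (spec$order == "shuffle") labels <- sample(labels)
  } else {
    w <- spec$weights / sum(spec$weights)
    labels <- sample(names(w), size = spec$n, replace = TRUE, prob = w)
  }
  nf <- length(labels)
  na <- n_atoms(base_top)
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  first_ref <- refs[[which(!vapply(refs, is.null, logical(1)))[1L]]]
  for (f in seq_len(nf)) {
    if (labels[f] == "noise") {
      m <- frame_coords(first_ref, 1L) +
        matrix(stats::rnorm(na * 3L, sd = spec$noise_big), na, 3L)
    } else {
      m <- frame_coords(refs[[labels[f]]], 1L)
      if (spec$noise_sigma > 0)
        m <- m + matrix(stats::rnorm(na * 3L, sd = spec$noise_sigma), na, 3L)
    }
    coords[f, , ] <- m
  }
  list(traj = trajectory(coords, base_top), labels = labels)
}
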