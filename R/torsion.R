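# Glycosidic torsions and syn/anti state labels.
#
# chi is the dihedral about the glycosidic bond: O4'-C1'-N9-C4 for purines
# and O4'-C1'-N1-C2 for pyrimidines (IUPAC convention).  Bases with chi in
# [-90, +90) sit over the sugar (syn, "s"); all other values are anti ("a").

CHI_ATOMS <- list(purine = c("O4'", "C1'", "N9", "C4"),
                  pyrimidine = c("O4'", "C1'", "N1", "C2"))

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction on the two plane normals; the sign follows
#' the IUPAC convention (positive clockwise looking from p2 towards p3).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate dihedral: collinear or coincident points")
  x <- sum(n1 * n2)
  y <- sum(b1 * n2) * nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Glycosidic chi torsions over a trajectory
#'
#' @param traj a [trajectory()].
#' @param residues internal residue indices to analyse (default: all
#'   residues with known base type).
#' @return Object of class `ChiSeries`: `values` (frames x residues matrix,
#'   degrees), `residues`, and the per-residue atom convention used.
#' @export
chi_series <- function(traj, residues = NULL) {
  top <- traj$topology
  if (is.null(residues)) residues <- which(!is.na(top$residues$base_type))
  at <- top$atoms
  quads <- lapply(residues, function(r) {
    bt <- top$residues$base_type[r]
    if (is.na(bt)) stop("residue ", r, " has unknown base type; cannot compute chi")
    names4 <- CHI_ATOMS[[bt]]
    rng <- top$residues$first[r]:top$residues$last[r]
    idx <- rng[match(names4, trimws(at$name[rng]))]
    if (anyNA(idx))
      stop("residue ", r, " lacks atom ", names4[which(is.na(idx))[1L]],
           " required for chi")
    idx
  })
  nf <- n_frames(traj)
  vals <- matrix(NA_real_, nf, length(residues))
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    for (j in seq_along(quads)) {
      q <- quads[[j]]
      vals[f, j] <- dihedral(m[q[1L], ], m[q[2L], ], m[q[3L], ], m[q[4L], ])
    }
  }
  colnames(vals) <- as.character(residues)
  structure(list(values = vals, residues = residues,
                 convention = CHI_ATOMS,
                 base_type = traj$topology$residues$base_type[residues]),
            class = "ChiSeries")
}

#' Classify a chi torsion as syn or anti
#'
#' The syn window is the half-open interval [-90, +90) degrees; everything
#' else is anti.  The boundaries are a documented convention chosen for
#' determinism; no intermediate ("high-anti") class is used.
#'
#' @param chi torsion(s) in degrees, each in (-180, 180].
#' @return Character vector of `"s"` / `"a"`.
#' @export
classify_state <- function(chi) {
  ifelse(chi >= -90 & chi < 90, "s", "a")
}

#' Canonical loop state label
#'
#' A 2xN internal loop state is written as strand-1 letters (5'->3'), "/",
#' strand-2 letters (5'->3'), e.g. `"sa/as"`.  With `symmetry = TRUE` the
#' label is identified with its strand-swapped reading and the
#' lexicographic minimum of the two is returned, so that the label of a
#' self-complementary duplex does not depend on which strand is called
#' first.
#'
#' @param strand1,strand2 per-residue state letters (`"s"`/`"a"`), 5'->3'.
#' @param symmetry identify strand-swapped readings?
#' @return Canonical label string.
#' @export
loop_state_label <- function(strand1, strand2, symmetry = TRUE) {
  ok <- function(x) length(x) > 0 && all(x %in% c("s", "a"))
  if (!ok(strand1) || !ok(strand2))
    stop("loop residue without a valid state letter")
  lab <- paste0(paste(strand1, collapse = ""), "/", paste(strand2, collapse = ""))
  if (!symmetry) return(lab)
  swapped <- paste0(paste(strand2, collapse = ""), "/", paste(strand1, collapse = ""))
  min(lab, swapped)
}

#' Tabulate loop states over a structure collection
#'
#' @param labels character vector of (canonical) state labels, one per
#'   structure.
#' @return data.frame of `state`, `count`, `percentage`, sorted by
#'   descending count (ties by label); percentages sum to 100.
#' @export
tabulate_states <- function(labels) {
  if (length(labels) == 0L) stop("empty structure collection")
  tab <- table(labels)
  out <- data.frame(state = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percentage <- 100 * out$count / sum(out$count)
  out <- out[order(-out$count, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-frame loop state labels from chi torsions
#'
#' Convenience wrapper: computes chi for the loop residues, classifies each
#' as syn/anti and forms the canonical loop label frame by frame.
#'
#' @param traj a [trajectory()].
#' @param strand1,strand2 internal residue indices of the loop on each
#'   strand, 5'->3'.
#' @param symmetry identify strand-swapped readings (see
#'   [loop_state_label()]).
#' @return Character vector of labels, one per frame.
#' @export
frame_state_labels <- function(traj, strand1, strand2, symmetry = TRUE) {
  cs <- chi_series(traj, c(strand1, strand2))
  letters <- matrix(classify_state(cs$values), nrow = nrow(cs$values))
  n1 <- length(strand1)
  vapply(seq_len(nrow(letters)), function(f) {
    loop_state_label(letters[f, seq_len(n1)],
                     letters[f, n1 + seq_along(strand2)], symmetry = symmetry)
  }, character(1))
}
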