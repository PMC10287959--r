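# Geometric hydrogen-bond detection and C/C mismatch state classification.
#
# Criteria: heavy-atom donor-acceptor distance d(D...A) <= d_max (default
# 3.5 A) and, when an explicit hydrogen is bonded to the donor, angle
# D-H...A >= a_min (default 135 deg).  Topologies without hydrogens fall
# back to the distance criterion alone.  These are the common MD-analysis
# defaults and are recorded in the output.

vec_angle <- function(a, b, c) {
  # angle a-b-c in degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# hydrogens covalently bonded to atom i: same residue, element H, < 1.25 A
bonded_hydrogens <- function(coords, topology, i) {
  at <- topology$atoms
  res <- at$residue[i]
  cand <- which(at$residue == res & at$element == "H")
  if (length(cand) == 0L) return(integer(0))
  d2 <- rowSums((coords[cand, , drop = FALSE] -
                   matrix(coords[i, ], length(cand), 3L, byrow = TRUE))^2)
  cand[d2 < 1.25^2]
}

#' Detect hydrogen bonds in one frame
#'
#' All donor-acceptor pairs satisfying the distance criterion and, when the
#' donor carries at least one explicit hydrogen, the D-H...A angle
#' criterion for some such hydrogen.
#'
#' @param coords `atoms x 3` coordinates of one frame.
#' @param topology the [topology()].
#' @param donors,acceptors atom indices (donors should be N/O).
#' @param d_max maximum heavy-atom D...A distance in Angstrom.
#' @param a_min minimum D-H...A angle in degrees.
#' @return data.frame of `donor`, `hydrogen` (NA in heavy-atom-only mode),
#'   `acceptor`, `distance`, `angle` (NA without H).
#' @export
detect_hbonds <- function(coords, topology, donors, acceptors,
                          d_max = 3.5, a_min = 135) {
  if (length(donors) == 0L || length(acceptors) == 0L)
    stop("empty donor or acceptor set")
  out <- list()
  for (d in donors) {
    hyd <- bonded_hydrogens(coords, topology, d)
    for (a in acceptors) {
      if (a == d) next
      dist <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dist > d_max) next
      if (length(hyd) == 0L) {
        out[[length(out) + 1L]] <- data.frame(donor = d, hydrogen = NA_integer_,
                                              acceptor = a, distance = dist,
                                              angle = NA_real_)
      } else {
        angs <- vapply(hyd, function(h)
          vec_angle(coords[d, ], coords[h, ], coords[a, ]), numeric(1))
        best <- which.max(angs)
        if (angs[best] >= a_min)
          out[[length(out) + 1L]] <- data.frame(donor = d, hydrogen = hyd[best],
                                                acceptor = a, distance = dist,
                                                angle = angs[best])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

cyt_atoms <- function(topology, r, names) {
  rng <- topology$residues$first[r]:topology$residues$last[r]
  idx <- rng[match(names, trimws(topology$atoms$name[rng]))]
  idx[!is.na(idx)]
}

#' Classify the pairing state of a C/C mismatch
#'
#' For a cytosine-cytosine mismatch the Watson-Crick face offers the N4
#' amino group as donor and N3/O2 as acceptors.  Counts, per frame, the
#' inter-residue hydrogen bonds (donor on either cytosine, acceptor on the
#' other) and summarises the ensemble as fractions of frames with 0, 1 and
#' >= 2 bonds.
#'
#' @param traj a [trajectory()].
#' @param mismatch length-2 vector of internal residue indices (both must
#'   be cytosines).
#' @param d_max,a_min geometric criteria (see [detect_hbonds()]).
#' @return list with `counts` (per-frame integer), `fractions` (named
#'   `n0`/`n1`/`n2plus`, summing to 1), `pairs` (data.frame of observed
#'   donor-acceptor pairs with frame counts), and the criteria used.
#' @export
classify_cc_state <- function(traj, mismatch, d_max = 3.5, a_min = 135) {
  top <- traj$topology
  stopifnot(length(mismatch) == 2L)
  resn <- top$residues$resname[mismatch]
  if (!all(substr(resn, 1L, 1L) == "C" & resn %in% PYRIMIDINES))
    stop("mismatch residues must be cytosines; got ", paste(resn, collapse = "/"))
  don <- lapply(mismatch, function(r) cyt_atoms(top, r, "N4"))
  acc <- lapply(mismatch, function(r) cyt_atoms(top, r, c("N3", "O2")))
  if (any(lengths(don) == 0L) || any(lengths(acc) == 0L))
    stop("cytosine WC-face atoms (N4, N3/O2) missing")
  nf <- n_frames(traj)
  counts <- integer(nf)
  pair_keys <- character(0)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    hb <- rbind(detect_hbonds(m, top, don[[1L]], acc[[2L]], d_max, a_min),
                detect_hbonds(m, top, don[[2L]], acc[[1L]], d_max, a_min))
    counts[f] <- nrow(hb)
    if (nrow(hb))
      pair_keys <- c(pair_keys, paste0(trimws(top$atoms$name[hb$donor]), "(",
                                       top$atoms$residue[hb$donor], ")...",
                                       trimws(top$atoms$name[hb$acceptor]), "(",
                                       top$atoms$residue[hb$acceptor], ")"))
  }
  fr <- c(n0 = mean(counts == 0L), n1 = mean(counts == 1L),
          n2plus = mean(counts >= 2L))
  pairs <- if (length(pair_keys)) {
    tb <- table(pair_keys)
    data.frame(pair = names(tb), frames = as.integer(tb), stringsAsFactors = FALSE)
  } else data.frame(pair = character(0), frames = integer(0))
  list(counts = counts, fractions = fr, pairs = pairs,
       criteria = list(d_max = d_max, a_min = a_min))
}
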