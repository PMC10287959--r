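# Data model and structure/trajectory I/O.
#
# A Topology describes the atoms and residues of one solute molecule
# (typically an RNA duplex); a Trajectory is an ordered stack of coordinate
# frames sharing that topology.  Coordinates are always in Angstrom.

PURINES <- c("A", "G", "ADE", "GUA", "RA", "RG", "A3", "A5", "G3", "G5", "DA", "DG")
PYRIMIDINES <- c("C", "U", "T", "CYT", "URA", "THY", "RC", "RU", "C3", "C5", "U3", "U5", "DC", "DT")

#' Construct a Topology from an atom table
#'
#' Low-level constructor.  Most users obtain a Topology from
#' [load_topology()] or [build_duplex()].
#'
#' @param atoms data.frame with columns `name` (PDB atom name), `element`,
#'   `chain` (single character), `resno` (author residue number, metadata
#'   only) and `resname` (nucleotide code).  Atoms must be grouped by
#'   residue in file order.
#' @return An object of class `Topology`: atom table with an internal
#'   1-based contiguous `residue` index, a residue table with purine /
#'   pyrimidine typing, and `symmetry_perms` (initially just the identity).
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  need <- c("name", "element", "chain", "resno", "resname")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(atoms$name))) stop("empty atom name in atom table")
  key <- paste(atoms$chain, atoms$resno)
  res_id <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  atoms$residue <- res_id
  first <- match(unique(res_id), res_id)
  resname <- toupper(trimws(atoms$resname[first]))
  base_type <- rep(NA_character_, length(first))
  base_type[resname %in% PURINES] <- "purine"
  base_type[resname %in% PYRIMIDINES] <- "pyrimidine"
  if (anyNA(base_type)) {
    warning("unknown residue name(s): ",
            paste(unique(resname[is.na(base_type)]), collapse = ", "),
            " - base_type marked unknown, excluded from chi analysis")
  }
  residues <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    resname = resname,
    base_type = base_type,
    first = first,
    last = c(first[-1L] - 1L, nrow(atoms)),
    stringsAsFactors = FALSE
  )
  structure(
    list(atoms = atoms, residues = residues,
         symmetry_perms = list(identity = seq_len(nrow(atoms)))),
    class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s), %d symmetry permutation(s)\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$atoms$chain)), length(x$symmetry_perms)))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)
n_residues <- function(top) nrow(top$residues)

# Element from a PDB atom name: strip leading digits, take first letter.
element_from_name <- function(name) {
  nm <- sub("^[0-9]+", "", trimws(name))
  toupper(substr(nm, 1L, 1L))
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records (first model only) and groups atoms into
#' residues by chain and author residue number.  Residues whose name is not
#' a standard nucleotide are kept but flagged with unknown `base_type` and
#' excluded from glycosidic torsion analysis.
#'
#' @param path path to a PDB file.
#' @return A [topology()] object.
#' @export
load_topology <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) < 1L) stop("no ATOM/HETATM records in '", path, "'")
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- element_from_name(at$elety[bad])
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  topology(data.frame(name = at$elety, element = toupper(trimws(elem)),
                      chain = chain, resno = at$resno, resname = at$resid,
                      stringsAsFactors = FALSE))
}

#' Construct a Trajectory
#'
#' @param coords numeric array `frames x atoms x 3` (Angstrom), or a single
#'   `atoms x 3` matrix for a one-frame trajectory.
#' @param topology the shared [topology()].
#' @param times frame times (arbitrary units, default frame index 0..N-1);
#'   must be strictly increasing.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(coords, topology, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  if (dim(coords)[2L] != n_atoms(topology))
    stop("coordinate atom count (", dim(coords)[2L],
         ") does not match topology (", n_atoms(topology), ")")
  if (is.null(times)) times <- seq_len(dim(coords)[1L]) - 1
  if (length(times) != dim(coords)[1L]) stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(coords = coords, times = as.numeric(times), topology = topology),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms (times %g .. %g)\n",
              n_frames(x), dim(x$coords)[2L], x$times[1L], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

# Coordinates of one frame as an atoms x 3 matrix.
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = TRUE]
  dim(m) <- c(dim(traj$coords)[2L], 3L)
  m
}

#' Read a coordinate ensemble
#'
#' Two plain-text dialects are supported: multi-model PDB (MODEL/ENDMDL
#' blocks, or a single implicit model) and a columnar CSV dialect with
#' header `frame,time,atom,x,y,z`, one row per atom per frame in fixed atom
#' order.  Frame times default to 0..N-1; the columnar `time` column, when
#' present and non-degenerate, is used instead.
#'
#' @param path input file.
#' @param topology the [topology()] the frames must match.
#' @param format `"auto"` (by extension/content), `"pdb"` or `"columnar"`.
#' @return A [trajectory()].
#' @export
load_trajectory <- function(path, topology, format = c("auto", "pdb", "columnar")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^frame[ ,]", first)) "columnar" else "pdb"
  }
  if (format == "pdb") load_trajectory_pdb(path, topology) else
    load_trajectory_columnar(path, topology)
}

load_trajectory_pdb <- function(path, topology) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  na <- n_atoms(topology)
  if (length(model_starts) == 0L) {
    counts <- sum(is_atom)
    bounds <- c(0L, length(lines) + 1L)
    nmod <- 1L
  } else {
    model_ends <- grep("^ENDMDL", lines)
    nmod <- length(model_starts)
    counts <- vapply(seq_len(nmod), function(i) {
      hi <- if (i <= length(model_ends)) model_ends[i] else length(lines) + 1L
      sum(is_atom[model_starts[i]:min(hi, length(lines))])
    }, integer(1))
  }
  bad <- which(counts != na)
  if (length(bad))
    stop("model ", bad[1L], " has ", counts[bad[1L]],
         " atoms; topology expects ", na)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  trajectory(coords, topology)
}

load_trajectory_columnar <- function(path, topology) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(d))) stop("columnar trajectory needs columns ",
                                     paste(need, collapse = ","))
  na <- n_atoms(topology)
  frames <- unique(d$frame)
  nf <- length(frames)
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  times <- numeric(nf)
  for (i in seq_len(nf)) {
    rows <- d[d$frame == frames[i], , drop = FALSE]
    if (nrow(rows) != na)
      stop("model ", i, " has ", nrow(rows), " atoms; topology expects ", na)
    rows <- rows[order(rows$atom), , drop = FALSE]
    coords[i, , ] <- cbind(rows$x, rows$y, rows$z)
    times[i] <- if ("time" %in% names(rows)) rows$time[1L] else i - 1
  }
  if (any(diff(times) <= 0)) times <- seq_len(nf) - 1
  trajectory(coords, topology, times)
}

#' Write a trajectory to disk
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"pdb"` (multi-model, coordinates to 3 decimals) or
#'   `"columnar"` (`frame,time,atom,x,y,z` CSV, full precision).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "columnar")) {
  format <- match.arg(format)
  if (format == "columnar") {
    na <- n_atoms(traj$topology)
    nf <- n_frames(traj)
    d <- data.frame(
      frame = rep(seq_len(nf) - 1L, each = na),
      time = rep(traj$times, each = na),
      atom = rep(seq_len(na) - 1L, nf),
      x = as.vector(t(matrix(traj$coords[, , 1L], nrow = nf))),
      y = as.vector(t(matrix(traj$coords[, , 2L], nrow = nf))),
      z = as.vector(t(matrix(traj$coords[, , 3L], nrow = nf))))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(traj, f)
    nm <- at$name
    # PDB name field: element-aligned for short names
    nm4 <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), nm)
    writeLines(sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       seq_len(nrow(at)), nm4, substr(at$resname, 1L, 3L),
                       at$chain, at$resno, m[, 1L], m[, 2L], m[, 3L],
                       1.0, 0.0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by residue and atom-name filter
#'
#' @param topology a [topology()].
#' @param residues internal residue indices (1-based) to keep; `NULL` keeps
#'   all residues.
#' @param atoms `"all"`, `"heavy"` (drop hydrogens by element), or a
#'   character vector of atom names to keep.
#' @return Strictly increasing integer vector of atom indices.
#' @export
select_atoms <- function(topology, residues = NULL, atoms = "heavy") {
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(residues)) {
    residues <- as.integer(residues)
    bad <- setdiff(residues, seq_len(n_residues(topology)))
    if (length(bad)) stop("no such residue index: ", paste(bad, collapse = ", "))
    keep <- at$residue %in% residues
  }
  if (identical(atoms, "heavy")) {
    keep <- keep & at$element != "H"
  } else if (!identical(atoms, "all")) {
    keep <- keep & trimws(at$name) %in% atoms
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty atom selection")
  idx
}

#' Parse a selection expression string
#'
#' Accepts the compact form used in configuration files, e.g.
#' `"residues=6,7,18,19;atoms=heavy"`.
#'
#' @param spec selection string.
#' @return list with `residues` (integer or NULL) and `atoms`.
#' @export
parse_selection <- function(spec) {
  out <- list(residues = NULL, atoms = "all")
  for (part in strsplit(spec, ";", fixed = TRUE)[[1L]]) {
    kv <- strsplit(trimws(part), "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad selection clause: '", part, "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key == "residues") {
      out$residues <- as.integer(strsplit(val, ",", fixed = TRUE)[[1L]])
    } else if (key == "atoms") {
      out$atoms <- if (val %in% c("all", "heavy")) val else
        strsplit(val, ",", fixed = TRUE)[[1L]]
    } else stop("unknown selection key: '", key, "'")
  }
  out
}

#' Register the strand-swap symmetry of a self-complementary duplex
#'
#' For a palindromic duplex the two chains are chemically identical, so
#' exchanging them yields an equivalent structure (a C2 operation).  The
#' resulting atom permutation maps atom i of chain A residue k to the
#' same-named atom of chain B residue k, and vice versa.  RMSD-based
#' analyses minimise over all registered permutations.
#'
#' @param topology a [topology()] with exactly the two chains named.
#' @param chain_a,chain_b chain identifiers to swap.
#' @return The topology with `symmetry_perms = list(identity, swap)`.
#' @export
set_symmetry <- function(topology, chain_a = "A", chain_b = "B") {
  res <- topology$residues
  ra <- which(res$chain == chain_a)
  rb <- which(res$chain == chain_b)
  if (length(ra) == 0L || length(rb) == 0L)
    stop("chain not found: ", if (length(ra) == 0L) chain_a else chain_b)
  if (length(ra) != length(rb))
    stop("chains ", chain_a, " and ", chain_b, " differ in residue count (",
         length(ra), " vs ", length(rb), ")")
  if (any(res$resname[ra] != res$resname[rb])) {
    k <- which(res$resname[ra] != res$resname[rb])[1L]
    stop("sequence mismatch at residue ", k, ": ",
         res$resname[ra][k], " vs ", res$resname[rb][k])
  }
  at <- topology$atoms
  perm <- integer(nrow(at))
  pair_res <- function(i, j) {
    ai <- res$first[i]:res$last[i]
    aj <- res$first[j]:res$last[j]
    ni <- trimws(at$name[ai]); nj <- trimws(at$name[aj])
    if (length(ai) != length(aj) || !setequal(ni, nj) ||
        anyDuplicated(ni) || anyDuplicated(nj)) {
      stop("atom-name mismatch between ", res$chain[i], " residue ", i,
           " and ", res$chain[j], " residue ", j)
    }
    perm[ai] <<- aj[match(ni, nj)]
  }
  for (k in seq_along(ra)) {
    pair_res(ra[k], rb[k])
    pair_res(rb[k], ra[k])
  }
  stopifnot(!anyDuplicated(perm))
  topology$symmetry_perms <- list(identity = seq_len(nrow(at)), swap = perm)
  topology
}
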