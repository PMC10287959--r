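test_that("PDB round trip preserves topology and coordinates to 3 decimals", {
  fx <- gg_refs()
  traj <- fx$refs[["sa/as"]]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path, format = "pdb")
  top2 <- load_topology(path)
  expect_equal(nrow(top2$atoms), nrow(traj$topology$atoms))
  expect_equal(nrow(top2$residues), 24L)
  expect_equal(sort(unique(top2$atoms$chain)), c("A", "B"))
  expect_equal(trimws(top2$atoms$name), trimws(traj$topology$atoms$name))
  expect_equal(top2$residues$base_type, traj$topology$residues$base_type)
  back <- load_trajectory(path, top2)
  expect_equal(n_frames(back), 1L)
  expect_true(max(abs(frame_coords(back, 1) - frame_coords(traj, 1))) <= 5.5e-4)
})

test_that("multi-model PDB and columnar dialect load with matching frames", {
  fx <- gg_refs()
  set.seed(3)
  nf <- 5L
  na <- nrow(fx$topology$atoms)
  coords <- array(rnorm(nf * na * 3), dim = c(nf, na, 3L))
  traj <- trajectory(coords, fx$topology)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, pdb, "pdb")
  write_trajectory(traj, csv, "columnar")
  t_pdb <- load_trajectory(pdb, fx$topology)
  t_csv <- load_trajectory(csv, fx$topology)
  expect_equal(n_frames(t_pdb), nf)
  expect_equal(n_frames(t_csv), nf)
  # columnar keeps full precision, PDB 3 decimals
  expect_equal(t_csv$coords, traj$coords, tolerance = 1e-12)
  expect_equal(max(abs(t_pdb$coords - traj$coords)), 0, tolerance = 5.5e-4)
  # columnar header time column becomes frame_times
  expect_equal(t_csv$times, traj$times)
})

test_that("atom-count mismatch in a model is reported with its index", {
  fx <- gg_refs()
  traj <- trajectory(array(0, dim = c(3L, nrow(fx$topology$atoms), 3L)), fx$topology)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path, "pdb")
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines)
  # drop one atom from model 3
  lines <- lines[-atom_lines[2L * nrow(fx$topology$atoms) + 5L]]
  writeLines(lines, path)
  expect_error(load_trajectory(path, fx$topology), "model 3")
})

test_that("unknown residue names load with a warning and no base type", {
  lines <- c(
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1:3, c("C1'", "N9", "C4"), "G", "A", 1, c(0, 1.5, 2.5), 0:2, 0, 1, 0,
            c("C", "N", "C")),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            4:5, c("C1", "C2"), "CB2", "A", 2, c(8, 9), 0, 0, 1, 0, c("C", "C")))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  expect_warning(top <- load_topology(path), "CB2")
  expect_equal(nrow(top$residues), 2L)
  expect_equal(top$residues$base_type, c("purine", NA))
})

test_that("atom selection respects residues and the heavy filter", {
  top <- toy_topology(c("C1'", "N9", "H1'", "O2'", "H2'"),
                      elements = c("C", "N", "H", "O", "H"))
  expect_equal(select_atoms(top, atoms = "heavy"), c(1L, 2L, 4L))
  expect_equal(select_atoms(top, atoms = "all"), 1:5)
  # idempotent and order-stable
  fx <- gg_refs()
  sel <- select_atoms(fx$topology, residues = GG_LOOP, atoms = "heavy")
  expect_true(all(diff(sel) > 0))
  expect_identical(sel, select_atoms(fx$topology, residues = GG_LOOP, atoms = "heavy"))
  expect_equal(length(unique(fx$topology$atoms$residue[sel])), 4L)
  expect_true(all(fx$topology$atoms$element[sel] != "H"))
  expect_error(select_atoms(fx$topology, residues = 99L), "99")
  expect_error(select_atoms(top, atoms = "XX9"), "empty")
})

test_that("selection expression strings parse to residue/atom filters", {
  s <- parse_selection("residues=6,7,18,19;atoms=heavy")
  expect_equal(s$residues, c(6L, 7L, 18L, 19L))
  expect_equal(s$atoms, "heavy")
  expect_error(parse_selection("what=1"), "unknown selection key")
})

test_that("strand-swap symmetry is a name-preserving involution", {
  fx <- gg_refs()
  swap <- fx$topology$symmetry_perms$swap
  expect_equal(length(fx$topology$symmetry_perms), 2L)
  # bijection mapping each atom to an identically named atom
  expect_equal(sort(swap), seq_along(swap))
  expect_equal(trimws(fx$topology$atoms$name[swap]), trimws(fx$topology$atoms$name))
  # involution: applying the swap twice is the identity
  expect_equal(swap[swap], seq_along(swap))
  # chains of different composition refuse to pair
  top_bad <- toy_topology(rep(c("C1'", "N1"), 3L),
                          chain = c("A", "A", "B", "B", "B", "B"),
                          resno = c(1L, 1L, 1L, 1L, 2L, 2L), resname = "C")
  expect_error(set_symmetry(top_bad, "A", "B"), "residue count")
})
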