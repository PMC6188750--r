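pdb_line <- function(serial, name, alt, resid, chain, resnum, x, y, z,
                     occ = 1, elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resid, chain, resnum, x, y, z, occ, 0, elem)
}

test_that("euclid matches hand-worked distances", {
  expect_equal(euclid(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclid(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclid(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_error(euclid(c(0, 0, Inf), c(0, 0, 0)), "finite")
})

test_that("euclid is symmetric and satisfies the triangle inequality", {
  set.seed(31)
  a <- matrix(runif(30000, -50, 50), ncol = 3)
  b <- matrix(runif(30000, -50, 50), ncol = 3)
  c <- matrix(runif(30000, -50, 50), ncol = 3)
  expect_equal(euclid(a, b), euclid(b, a))
  expect_true(all(euclid(a, c) <= euclid(a, b) + euclid(b, c) + 1e-12))
})

test_that("PDB read/write round trip preserves atoms, order and coordinates", {
  cx <- make_complex(seed = 42)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx$atoms, path)
  back <- read_complex(path, "P")
  expect_equal(nrow(back), nrow(cx$atoms))
  expect_equal(back$name, cx$atoms$name)
  expect_equal(back$chain, cx$atoms$chain)
  expect_equal(back$resnum, cx$atoms$resnum)
  expect_equal(back$role, cx$atoms$role)
  # fixed-column PDB carries 3 decimals
  expect_equal(back$x, cx$atoms$x, tolerance = 6e-4)
  expect_equal(back$y, cx$atoms$y, tolerance = 6e-4)
  expect_equal(back$z, cx$atoms$z, tolerance = 6e-4)
})

test_that("missing peptide chain errors and names available chains", {
  cx <- make_complex(seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx$atoms, path)
  expect_error(read_complex(path, "Q"), "A, P")
})

test_that("altLoc resolves to highest occupancy, ties alphabetically", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.6),
    pdb_line(2, "N", "B", "ALA", "A", 1, 5, 0, 0, occ = 0.4),
    pdb_line(3, "CA", "B", "ALA", "A", 1, 1.5, 0, 0, occ = 0.5),
    pdb_line(4, "CA", "C", "ALA", "A", 1, 6.5, 0, 0, occ = 0.5),
    pdb_line(5, "N", " ", "GLY", "P", 1, 10, 0, 0),
    "END"
  ), path)
  atoms <- read_complex(path, "P")
  expect_equal(nrow(atoms), 3)
  # occupancy 0.6 wins for N; the B/C occupancy tie resolves to B
  expect_equal(atoms$x[atoms$name == "N" & atoms$chain == "A"], 0)
  expect_equal(atoms$x[atoms$name == "CA"], 1.5)
})

test_that("waters and ions are dropped; other HETATM honour keep_het", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    pdb_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_line(2, "O", " ", "HOH", "A", 90, 3, 0, 0)),
    sub("^ATOM  ", "HETATM", pdb_line(3, "ZN", " ", "ZN", "A", 91, 4, 0, 0,
                                      elem = "ZN")),
    sub("^ATOM  ", "HETATM", pdb_line(4, "C1", " ", "FAD", "A", 92, 5, 0, 0,
                                      elem = "C")),
    pdb_line(5, "N", " ", "GLY", "P", 1, 10, 0, 0),
    "END"
  )
  writeLines(lines, path)
  expect_equal(nrow(read_complex(path, "P")), 2)
  kept <- read_complex(path, "P", keep_het = TRUE)
  expect_equal(nrow(kept), 3)
  expect_true("FAD" %in% kept$residue)
  expect_false("HOH" %in% kept$residue)
})

test_that("only the first model of a multi-model file is read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", " ", "GLY", "P", 1, 5, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", " ", "GLY", "A", 1, 100, 0, 0),
    pdb_line(2, "CA", " ", "GLY", "P", 1, 105, 0, 0),
    "ENDMDL",
    "END"
  ), path)
  atoms <- read_complex(path, "P")
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$x, c(0, 5))
})

test_that("malformed ATOM records error with the line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
    "ATOM      2  CA  GLY A   2      bad coords here",
    "END"
  ), path)
  expect_error(read_complex(path, "P"), "line 2")
})

test_that("atom classification counts side-chain and backbone atoms", {
  # glycine: four heavy backbone atoms, no heavy side chain
  gly <- mk_atoms(c("N", "CA", "C", "O", "CA"),
                  c("N", "C", "C", "O", "C"),
                  c("A", "A", "A", "A", "P"),
                  c(1L, 1L, 1L, 1L, 1L),
                  x = c(0, 1.5, 2.5, 3.5, 50), y = 0, z = 0)
  counts <- classify_atoms(gly)
  rec_bb <- counts[counts$role == "receptor" &
                     counts$atom_class == "backbone", ]
  rec_sc <- counts[counts$role == "receptor" &
                     counts$atom_class == "side_chain", ]
  expect_equal(rec_bb$n_all, 4)
  expect_equal(rec_sc$n_all, 0)

  # alanine: one heavy side-chain atom (CB)
  ala <- mk_atoms(c("N", "CA", "C", "O", "CB", "CA"),
                  c("N", "C", "C", "O", "C", "C"),
                  c("A", "A", "A", "A", "A", "P"),
                  c(1L, 1L, 1L, 1L, 1L, 1L),
                  x = c(0, 1.5, 2.5, 3.5, 1.5, 50), y = c(0, 0, 0, 0, 1.5, 0),
                  z = 0, residue = "ALA")
  counts <- classify_atoms(ala)
  expect_equal(counts$n_heavy[counts$role == "receptor" &
                                counts$atom_class == "side_chain"], 1)
  expect_equal(counts$n_heavy[counts$role == "receptor" &
                                counts$atom_class == "backbone"], 4)

  # fully protonated arginine: 6 backbone (N CA C O H HA), 18 side chain
  arg_names <- c("N", "CA", "C", "O", "H", "HA",
                 "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2",
                 "HB2", "HB3", "HG2", "HG3", "HD2", "HD3", "HE",
                 "HH11", "HH12", "HH21", "HH22")
  arg_elem <- substr(arg_names, 1, 1)
  n <- length(arg_names)
  arg <- mk_atoms(c(arg_names, "CA"), c(arg_elem, "C"),
                  c(rep("A", n), "P"), c(rep(1L, n), 1L),
                  x = c(seq_len(n) * 2, 200), y = 0, z = 0,
                  residue = "ARG")
  counts <- classify_atoms(arg)
  expect_equal(counts$n_all[counts$role == "receptor" &
                              counts$atom_class == "side_chain"], 18)
  expect_equal(counts$n_all[counts$role == "receptor" &
                              counts$atom_class == "backbone"], 6)
  expect_equal(counts$n_all[counts$role == "receptor" &
                              counts$atom_class == "ratio_sc_bb"], 3)
})
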