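test_that("grid-accelerated contact search equals the all-pairs oracle", {
  set.seed(51)
  for (i in 1:100) {
    atoms <- random_atom_cloud(sample(10:60, 1), sample(5:40, 1))
    cutoff <- sample(c(2, 4, 6), 1)
    got <- close_contacts(atoms, cutoff)
    rec <- atoms[atoms$role == "receptor", ]
    pep <- atoms[atoms$role == "peptide", ]
    want <- oracle_pairs(as.matrix(rec[, c("x", "y", "z")]),
                         as.matrix(pep[, c("x", "y", "z")]), cutoff)
    got_keys <- sort(paste(got$receptor_serial, got$peptide_serial))
    want_keys <- sort(paste(rec$serial[want[, 1]], pep$serial[want[, 2]]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("close contacts honour the inclusive 4.0 A boundary", {
  expect_equal(nrow(close_contacts(mk_pair(3.9))), 1)
  expect_equal(nrow(close_contacts(mk_pair(4.0))), 1)
  expect_equal(nrow(close_contacts(mk_pair(4.0000001))), 0)
  expect_equal(nrow(close_contacts(mk_pair(50))), 0)
})

test_that("hydrophobic contacts require carbon on both sides", {
  expect_equal(nrow(hydrophobic_contacts(mk_pair(3.8))), 1)
  no_c <- mk_pair(3.0, name_a = "N", elem_a = "N", name_b = "O", elem_b = "O")
  expect_equal(nrow(hydrophobic_contacts(no_c)), 0)
  expect_equal(nrow(close_contacts(no_c)), 1)
  expect_equal(nrow(hydrophobic_contacts(mk_pair(4.5))), 0)
})

test_that("hydrogen bonds gate on distance and D-H...A deviation", {
  good <- make_complex(hbonds = data.frame(distance = 2.9, deviation = 5,
                                           donor_side = "receptor"),
                       close = numeric(0), hydrophobic = numeric(0),
                       salt_bridges = NULL, pipi = NULL, seed = 2)
  hb <- hydrogen_bonds(good$atoms)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_side, "receptor")
  expect_equal(hb$d_a_distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$deviation, 5, tolerance = 1e-6)

  bent <- make_complex(hbonds = data.frame(distance = 2.9, deviation = 45,
                                           donor_side = "receptor"),
                       close = numeric(0), hydrophobic = numeric(0),
                       salt_bridges = NULL, pipi = NULL, seed = 2)
  expect_equal(nrow(hydrogen_bonds(bent$atoms)), 0)

  far <- make_complex(hbonds = data.frame(distance = 4.2, deviation = 5,
                                          donor_side = "receptor"),
                      close = numeric(0), hydrophobic = numeric(0),
                      salt_bridges = NULL, pipi = NULL, seed = 2)
  expect_equal(nrow(hydrogen_bonds(far$atoms)), 0)
})

test_that("peptide-side donors are attributed correctly", {
  cx <- make_complex(hbonds = data.frame(distance = 3.1, deviation = 10,
                                         donor_side = "peptide"),
                     close = numeric(0), hydrophobic = numeric(0),
                     salt_bridges = NULL, pipi = NULL, seed = 3)
  hb <- hydrogen_bonds(cx$atoms)
  expect_equal(hb$donor_side, "peptide")
  expect_equal(hb$donor_chain, "P")
})

test_that("models without hydrogens fall back to a stricter distance rule", {
  close_pair <- mk_pair(3.4, name_a = "N", elem_a = "N",
                        name_b = "O", elem_b = "O")
  hb <- hydrogen_bonds(close_pair)
  expect_equal(nrow(hb), 1)
  expect_true(hb$geometry_incomplete)
  expect_true(is.na(hb$donor_side))
  # 3.5 < d <= 4.0 passes the full rule but not the fallback
  borderline <- mk_pair(3.8, name_a = "N", elem_a = "N",
                        name_b = "O", elem_b = "O")
  expect_equal(nrow(hydrogen_bonds(borderline)), 0)
})

test_that("salt bridges pair opposite charges only", {
  cx <- make_complex(salt_bridges = data.frame(distance = 3.5,
                                               variant = "side_chain"),
                     close = numeric(0), hydrophobic = numeric(0),
                     hbonds = NULL, pipi = NULL, seed = 4)
  sb <- salt_bridges(cx$atoms)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$positive_residue, "LYS")
  expect_equal(sb$negative_residue, "GLU")
  expect_equal(sb$min_distance, 3.5, tolerance = 1e-6)

  # like charges never bridge: receptor Arg guanidinium vs peptide Lys
  like <- mk_atoms(
    name = c("NH1", "O", "NZ", "O"),
    element = c("N", "O", "N", "O"),
    chain = c("A", "A", "P", "P"),
    resnum = c(1L, 2L, 1L, 2L),
    x = c(0, -30, 3.5, 33), y = 0, z = 0,
    residue = c("ARG", "GLY", "LYS", "GLY")
  )
  expect_equal(nrow(salt_bridges(like)), 0)

  # beyond the cutoff
  farcx <- make_complex(salt_bridges = data.frame(distance = 4.6,
                                                  variant = "side_chain"),
                        close = numeric(0), hydrophobic = numeric(0),
                        hbonds = NULL, pipi = NULL, seed = 4)
  expect_equal(nrow(salt_bridges(farcx$atoms)), 0)
})

test_that("the peptide C-terminal carboxylate acts as a charged group", {
  cx <- make_complex(salt_bridges = data.frame(distance = 3.4,
                                               variant = "c_terminus"),
                     close = numeric(0), hydrophobic = numeric(0),
                     hbonds = NULL, pipi = NULL, seed = 5)
  sb <- salt_bridges(cx$atoms)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$positive_residue, "ARG")
  expect_equal(sb$negative_group, "c_terminus")
  expect_equal(sb$min_distance, 3.4, tolerance = 1e-6)
})

test_that("pi-pi stacking gates on centroid distance and plane angle", {
  good <- make_complex(pipi = data.frame(distance = 4.0, angle = 0),
                       close = numeric(0), hydrophobic = numeric(0),
                       hbonds = NULL, salt_bridges = NULL, seed = 6)
  pp <- pipi_stacks(good$atoms)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$centroid_distance, 4.0, tolerance = 1e-6)
  expect_equal(pp$plane_angle, 0, tolerance = 1e-6)

  tilted <- make_complex(pipi = data.frame(distance = 4.0, angle = 60),
                         close = numeric(0), hydrophobic = numeric(0),
                         hbonds = NULL, salt_bridges = NULL, seed = 6)
  expect_equal(nrow(pipi_stacks(tilted$atoms)), 0)

  far <- make_complex(pipi = data.frame(distance = 8.0, angle = 0),
                      close = numeric(0), hydrophobic = numeric(0),
                      hbonds = NULL, salt_bridges = NULL, seed = 6)
  expect_equal(nrow(pipi_stacks(far$atoms)), 0)
})

test_that("incomplete aromatic rings are skipped with a warning", {
  cx <- make_complex(pipi = data.frame(distance = 4.0, angle = 0),
                     close = numeric(0), hydrophobic = numeric(0),
                     hbonds = NULL, salt_bridges = NULL, seed = 7)
  atoms <- cx$atoms
  drop <- which(atoms$role == "peptide" & atoms$name %in% c("CD1", "CE1"))
  expect_warning(pp <- pipi_stacks(atoms[-drop, ]), "skipped")
  expect_equal(nrow(pp), 0)
})

test_that("all detections are invariant under rigid-body transformation", {
  ref <- make_complex(seed = 8, rotate = FALSE)
  rot <- make_complex(seed = 8, rotate = TRUE)
  for (cx in list(ref, rot)) {
    cc <- close_contacts(cx$atoms)
    hb <- hydrogen_bonds(cx$atoms)
    sb <- salt_bridges(cx$atoms)
    pp <- pipi_stacks(cx$atoms)
    if (identical(cx, ref)) {
      base <- list(cc, hb, sb, pp)
    } else {
      expect_equal(cc$receptor_serial, base[[1]]$receptor_serial)
      expect_equal(cc$distance, base[[1]]$distance, tolerance = 1e-6)
      expect_equal(hb$deviation, base[[2]]$deviation, tolerance = 1e-6)
      expect_equal(sb$min_distance, base[[3]]$min_distance, tolerance = 1e-6)
      expect_equal(pp$plane_angle, base[[4]]$plane_angle, tolerance = 1e-6)
    }
  }
})

test_that("every hydrogen-bond pair also appears among close contacts", {
  cx <- make_complex(hbonds = data.frame(distance = c(2.9, 3.6),
                                         deviation = c(5, 20),
                                         donor_side = c("receptor", "peptide")),
                     seed = 9)
  hb <- hydrogen_bonds(cx$atoms)
  cc <- close_contacts(cx$atoms)
  cc_keys <- paste(pmin(cc$receptor_serial, cc$peptide_serial),
                   pmax(cc$receptor_serial, cc$peptide_serial))
  hb_keys <- paste(pmin(hb$donor_serial, hb$acceptor_serial),
                   pmax(hb$donor_serial, hb$acceptor_serial))
  expect_true(all(hb_keys %in% cc_keys))
})

test_that("swapping role labels transposes donor sides, preserves counts", {
  cx <- make_complex(seed = 10)
  swapped <- cx$atoms
  swapped$role <- ifelse(swapped$role == "receptor", "peptide", "receptor")
  expect_equal(nrow(close_contacts(swapped)), nrow(close_contacts(cx$atoms)))
  expect_equal(nrow(salt_bridges(swapped)), nrow(salt_bridges(cx$atoms)))
  expect_equal(nrow(pipi_stacks(swapped)), nrow(pipi_stacks(cx$atoms)))
  hb <- hydrogen_bonds(cx$atoms)
  hb_sw <- hydrogen_bonds(swapped)
  expect_equal(nrow(hb_sw), nrow(hb))
  expect_equal(sum(hb_sw$donor_side == "peptide"),
               sum(hb$donor_side == "receptor"))
})

test_that("profile participation statistics match planted arithmetic", {
  # peptide: 10 side-chain and 5 backbone atoms; receptor probes touch
  # exactly 2 side-chain and 2 backbone atoms
  pep_names <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ",
                 "N", "CB", "CG", "CD", "CE", "NZ")
  pep_res <- rep(c(1L, 2L), c(9, 6))
  pep_x <- seq(0, by = 10, length.out = 15)
  rec_targets <- c(5, 6, 1, 10)  # CB, CG (side chain); N res1, N res2
  atoms <- mk_atoms(
    name = c(pep_names, rep("CA", 4), "O"),
    element = c(substr(pep_names, 1, 1), rep("C", 4), "O"),
    chain = c(rep("P", 15), rep("A", 5)),
    resnum = c(pep_res, 1:4, 5L),
    x = c(pep_x, pep_x[rec_targets] + 3, 500),
    y = c(rep(0, 15), rep(0, 4), 0),
    z = 0,
    residue = "LYS"
  )
  prof <- interaction_profile(atoms)
  expect_equal(prof$n_close_contacts, 4)
  expect_equal(prof$frac_sc_in_contacts, 0.2)
  expect_equal(prof$frac_bb_in_contacts, 0.4)
  expect_equal(prof$unique_sc_bb_ratio, 1)
  expect_equal(prof$overall_sc_bb_ratio, 2)
  expect_equal(prof$contacts_per_sc_atom, 1)
})

test_that("a complex with no interface yields an all-zero profile", {
  atoms <- mk_pair(60)
  prof <- interaction_profile(atoms)
  expect_equal(prof$n_close_contacts, 0)
  expect_equal(prof$n_hbonds, 0)
  expect_equal(prof$n_salt_bridges, 0)
  expect_equal(prof$n_pipi, 0)
  expect_false(prof$has_salt_bridge)
  expect_true(is.na(prof$frac_donor_protein))
})

test_that("profiles flag coexisting salt bridges and stacks", {
  cx <- make_complex(seed = 11)
  prof <- interaction_profile(cx$atoms, system_id = "both_case")
  expect_true(prof$has_salt_bridge)
  expect_true(prof$has_pipi)
  ints <- profile_interactions(prof)
  expect_named(ints, c("close", "close_heavy", "hydrophobic", "hbonds",
                       "salt_bridges", "pipi"))
})
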