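snap_row <- function(system_id, snapshot, role, g, ts = NA_real_) {
  tibble::tibble(system_id = system_id, snapshot = snapshot, role = role,
                 e_bnd = g, e_el = 0, e_vdw = 0, g_pol = 0, g_np = 0,
                 ts = ts)
}

test_that("the Gibbs sum adds five terms and subtracts entropy when present", {
  e <- tibble::tibble(e_bnd = 1, e_el = 2, e_vdw = 3, g_pol = 4, g_np = 5)
  expect_equal(gibbs_sum(e)$g_total, 15)
  e$ts <- 5
  expect_equal(gibbs_sum(e)$g_total, 10)
  zeros <- tibble::tibble(e_bnd = 0, e_el = 0, e_vdw = 0, g_pol = 0,
                          g_np = 0)
  expect_equal(gibbs_sum(zeros)$g_total, 0)
  bad <- tibble::tibble(e_bnd = NaN, e_el = 0, e_vdw = 0, g_pol = 0,
                        g_np = 0)
  expect_error(gibbs_sum(bad), "non-finite")
})

test_that("binding free energy averages per-snapshot differences", {
  e <- dplyr::bind_rows(
    snap_row("s", 1:3, "complex", c(-10, -12, -14)),
    snap_row("s", 1:3, "protein", 0),
    snap_row("s", 1:3, "peptide", 0)
  )
  out <- delta_g_bind(e)
  expect_equal(out$dg_bind, -12)
  expect_equal(out$dg_sd, 2)
  expect_equal(out$n_snapshots, 3)

  single <- dplyr::bind_rows(
    snap_row("s", 1, "complex", -7),
    snap_row("s", 1, "protein", 0),
    snap_row("s", 1, "peptide", 0)
  )
  expect_warning(one <- delta_g_bind(single), "single snapshot")
  expect_equal(one$dg_bind, -7)
  expect_equal(one$dg_sd, 0)

  missing_role <- dplyr::bind_rows(
    snap_row("s", 1:2, "complex", -7),
    snap_row("s", 1:2, "protein", 0),
    snap_row("s", 1, "peptide", 0)
  )
  expect_error(delta_g_bind(missing_role), "snapshot 2")
})

test_that("binding free energy is invariant to snapshot order", {
  dec <- make_decomposition(dg_star = -30, n_snapshots = 25, noise_sd = 3,
                            seed = 71)
  shuffled <- dec$energies[sample.int(nrow(dec$energies)), ]
  expect_equal(delta_g_bind(shuffled)$dg_bind,
               delta_g_bind(dec$energies)$dg_bind)
})

test_that("the overall mean lies between the means of complementary halves", {
  dec <- make_decomposition(dg_star = -20, n_snapshots = 40, noise_sd = 5,
                            seed = 72)
  e <- gibbs_sum(dec$energies)
  wide <- tidyr::pivot_wider(
    dplyr::select(e, "system_id", "snapshot", "role", "g_total"),
    names_from = "role", values_from = "g_total"
  )
  dg <- wide$complex - wide$protein - wide$peptide
  halves <- sort(c(mean(dg[1:20]), mean(dg[21:40])))
  expect_gte(mean(dg), halves[1])
  expect_lte(mean(dg), halves[2])
})

test_that("prominent-residue selection applies the 40 percent rule", {
  contribs <- tibble::tibble(
    system_id = "s",
    chain_role = "protein",
    res_name = c("ARG", "GLU", "TRP", "LYS"),
    res_index = 1:4,
    dg_contrib = c(-10.0, -4.1, -3.9, +4.5)
  )
  sel <- select_prominent(contribs, 0.4)
  expect_equal(sel$dg_contrib, c(-10.0, -4.1, 4.5))
  expect_equal(sel$threshold, rep(4, 3))

  one <- select_prominent(contribs[1, ], 0.4)
  expect_equal(nrow(one), 1)

  maximal <- select_prominent(contribs, 1.0)
  expect_equal(maximal$dg_contrib, -10)
})

test_that("prominent-residue selection is scale-invariant", {
  set.seed(73)
  contribs <- tibble::tibble(
    system_id = rep(c("a", "b"), each = 12),
    chain_role = "protein",
    res_name = "ALA",
    res_index = rep(1:12, 2),
    dg_contrib = rnorm(24, 0, 4)
  )
  base <- select_prominent(contribs, 0.4)
  for (c_scale in c(0.01, 3, 250)) {
    scaled <- dplyr::mutate(contribs, dg_contrib = dg_contrib * c_scale)
    sel <- select_prominent(scaled, 0.4)
    expect_equal(paste(sel$system_id, sel$res_index),
                 paste(base$system_id, base$res_index))
  }
})

test_that("all-zero contributions warn and yield an empty selection", {
  zero <- tibble::tibble(system_id = "z", chain_role = "protein",
                         res_name = "GLY", res_index = 1:3,
                         dg_contrib = 0)
  expect_warning(sel <- select_prominent(zero), "all-zero")
  expect_equal(nrow(sel), 0)
})

test_that("position classes split termini from internal residues", {
  expect_equal(position_class(1, 8), "N-terminal")
  expect_equal(position_class(8, 8), "C-terminal")
  expect_equal(position_class(4, 8), "internal")
  expect_equal(position_class(c(1, 3, 8), 8),
               c("N-terminal", "internal", "C-terminal"))
  expect_error(position_class(9, 8), "out of")
  expect_error(position_class(0, 8), "out of")
})

test_that("contribution summaries average by type, role and position", {
  sel <- tibble::tibble(
    system_id = c("a", "b", "a", "b"),
    chain_role = c("protein", "protein", "peptide", "peptide"),
    res_name = c("ARG", "ARG", "ARG", "ARG"),
    res_index = c(10L, 20L, 1L, 3L),
    dg_contrib = c(-5, -3, 2, -3),
    position_class = c(NA, NA, "N-terminal", "internal")
  )
  cs <- contribution_summary(sel)
  prot_arg <- cs$by_residue[cs$by_residue$chain_role == "protein", ]
  expect_equal(prot_arg$n, 2)
  expect_equal(prot_arg$mean_dg, -4)
  expect_equal(nrow(cs$by_position), 2)
  nterm <- cs$by_position[cs$by_position$position_class == "N-terminal", ]
  expect_equal(nterm$mean_dg, 2)
})

test_that("planted per-residue contributions are recovered exactly", {
  dec <- make_decomposition(dg_star = -48.02, n_snapshots = 5,
                            noise_sd = 0, seed = 74)
  # decomposition table sums to the planted total
  expect_equal(sum(dec$contribs$dg_contrib), -48.02, tolerance = 1e-9)
  # noiseless snapshots recover it exactly
  expect_equal(delta_g_bind(dec$energies)$dg_bind, -48.02,
               tolerance = 1e-9)
  # contributions are consistent with the aggregated binding energy
  expect_equal(sum(dec$contribs$dg_contrib) -
                 delta_g_bind(dec$energies)$dg_bind, 0, tolerance = 1e-9)
})

test_that("energy and decomposition TSV readers validate their schemas", {
  dec <- make_decomposition(dg_star = -10, n_snapshots = 3, seed = 75)
  epath <- withr::local_tempfile(fileext = ".tsv")
  rpath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dec$energies, epath)
  readr::write_tsv(dec$contribs, rpath)
  expect_equal(delta_g_bind(read_energy_tsv(epath))$dg_bind, -10,
               tolerance = 1e-6)
  expect_equal(nrow(read_decomposition_tsv(rpath)), nrow(dec$contribs))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("system_id\tsnapshot\nx\t1", bad)
  expect_error(read_energy_tsv(bad), "lacks column")
})
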