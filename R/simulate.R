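# Synthetic complexes are geometric scaffolds, not foldable proteins:
# each planted interaction occupies an isolated "station" along the x
# axis (40 A spacing), so no unintended chemistry-class detection can
# arise between stations. Distance-defined ground truth (close and
# hydrophobic contacts) is enumerated from the final coordinates; the
# chemistry classes (H-bonds, salt bridges, pi-pi) carry the planted
# list as truth, with an `expected` flag for deliberately out-of-gate
# plants.

STATION_SPACING <- 40

atom_row <- function(name, element, residue, chain, resnum, x, y, z) {
  tibble::tibble(name = name, element = element, residue = residue,
                 chain = chain, resnum = resnum, ins = "",
                 x = x, y = y, z = z, occupancy = 1, is_het = FALSE)
}

# four-atom scaffold with all atoms >= ~5 A from the station's partner
# side; `sgn` mirrors it to the -x (receptor) or +x (peptide) side
scaffold_gly <- function(chain, resnum, cx, sgn, skip = character(0)) {
  offs <- list(N = c(4, 3), CA = c(8, 3), C = c(8, -3), O = c(12, 0))
  rows <- purrr::imap(offs, function(o, nm) {
    if (nm %in% skip) return(NULL)
    atom_row(nm, substr(nm, 1, 1), "GLY", chain, resnum,
             cx + sgn * o[1], o[2], 0)
  })
  dplyr::bind_rows(rows)
}

station_close <- function(cx, chain_r, res_r, res_p, d) {
  rec <- dplyr::bind_rows(
    atom_row("CA", "C", "GLY", chain_r, res_r, cx, 0, 0),
    scaffold_gly(chain_r, res_r, cx, -1, skip = "CA")
  )
  pep <- dplyr::bind_rows(
    atom_row("N", "N", "GLY", "P", res_p, cx + d, 0, 0),
    scaffold_gly("P", res_p, cx + d, +1, skip = "N")
  )
  list(rec = rec, pep = pep)
}

station_hydrophobic <- function(cx, chain_r, res_r, res_p, d) {
  rec <- dplyr::bind_rows(
    atom_row("CA", "C", "GLY", chain_r, res_r, cx, 0, 0),
    scaffold_gly(chain_r, res_r, cx, -1, skip = "CA")
  )
  pep <- dplyr::bind_rows(
    atom_row("CA", "C", "GLY", "P", res_p, cx + d, 0, 0),
    scaffold_gly("P", res_p, cx + d, +1, skip = "CA")
  )
  list(rec = rec, pep = pep)
}

station_hbond <- function(cx, chain_r, res_r, res_p, d, deviation,
                          donor_side) {
  # donor N with its H pointing at the acceptor O; the acceptor sits so
  # that |D-A| = d and the D-H...A deviation from linearity = deviation
  delta <- deg2rad(deviation)
  r <- -cos(delta) + sqrt(cos(delta)^2 - 1 + d^2)
  if (donor_side == "receptor") {
    ax <- cx + 1 + r * cos(delta); ay <- r * sin(delta)
    rec <- dplyr::bind_rows(
      atom_row("N", "N", "GLY", chain_r, res_r, cx, 0, 0),
      atom_row("H", "H", "GLY", chain_r, res_r, cx + 1, 0, 0),
      scaffold_gly(chain_r, res_r, cx, -1, skip = "N")
    )
    pep <- dplyr::bind_rows(
      atom_row("O", "O", "GLY", "P", res_p, ax, ay, 0),
      scaffold_gly("P", res_p, cx + d, +1, skip = "O")
    )
  } else {
    ax <- cx + d - 1 - r * cos(delta); ay <- r * sin(delta)
    pep <- dplyr::bind_rows(
      atom_row("N", "N", "GLY", "P", res_p, cx + d, 0, 0),
      atom_row("H", "H", "GLY", "P", res_p, cx + d - 1, 0, 0),
      scaffold_gly("P", res_p, cx + d, +1, skip = "N")
    )
    rec <- dplyr::bind_rows(
      atom_row("O", "O", "GLY", chain_r, res_r, ax, ay, 0),
      scaffold_gly(chain_r, res_r, cx, -1, skip = "O")
    )
  }
  list(rec = rec, pep = pep)
}

station_salt_bridge <- function(cx, chain_r, res_r, res_p, d, variant) {
  if (variant == "side_chain") {
    rec <- dplyr::bind_rows(
      atom_row("NZ", "N", "LYS", chain_r, res_r, cx, 0, 0),
      scaffold_gly(chain_r, res_r, cx, -1) |>
        dplyr::mutate(residue = "LYS")
    )
    pep <- dplyr::bind_rows(
      atom_row("OE1", "O", "GLU", "P", res_p, cx + d, 0, 0),
      atom_row("OE2", "O", "GLU", "P", res_p, cx + d + 2.2, 0, 0),
      scaffold_gly("P", res_p, cx + d, +1) |>
        dplyr::mutate(residue = "GLU")
    )
  } else {  # peptide C-terminal carboxylate against a receptor arginine
    rec <- dplyr::bind_rows(
      atom_row("NH2", "N", "ARG", chain_r, res_r, cx, 0, 0),
      atom_row("NH1", "N", "ARG", chain_r, res_r, cx - 2, 1, 0),
      atom_row("NE", "N", "ARG", chain_r, res_r, cx - 2, -1, 0),
      scaffold_gly(chain_r, res_r, cx - 4, -1) |>
        dplyr::mutate(residue = "ARG")
    )
    pep <- dplyr::bind_rows(
      atom_row("O", "O", "GLY", "P", res_p, cx + d, 0, 0),
      atom_row("OXT", "O", "GLY", "P", res_p, cx + d + 2, 1, 0),
      scaffold_gly("P", res_p, cx + d, +1, skip = "O")
    )
  }
  list(rec = rec, pep = pep)
}

hexagon <- function(center, u, v, radius = 1.39, offset = 0) {
  th <- deg2rad(seq(0, 300, by = 60) + offset)
  t(vapply(th, function(a) center + radius * (cos(a) * u + sin(a) * v),
           numeric(3)))
}

station_pipi <- function(cx, chain_r, res_r, res_p, d, angle) {
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  xyz_r <- hexagon(c(cx, 0, 0), c(0, 1, 0), c(0, 0, 1))
  al <- deg2rad(angle)
  # peptide ring tilted about z so the plane angle equals `angle`;
  # vertices staggered 30 degrees to keep atom pairs off the boundary
  xyz_p <- hexagon(c(cx + d, 0, 0), c(-sin(al), cos(al), 0), c(0, 0, 1),
                   offset = 30)
  rec <- dplyr::bind_rows(
    purrr::map2(ring_names, seq_len(6), function(nm, k) {
      atom_row(nm, "C", "PHE", chain_r, res_r,
               xyz_r[k, 1], xyz_r[k, 2], xyz_r[k, 3])
    }),
    scaffold_gly(chain_r, res_r, cx - 2, -1) |>
      dplyr::mutate(residue = "PHE")
  )
  pep <- dplyr::bind_rows(
    purrr::map2(ring_names, seq_len(6), function(nm, k) {
      atom_row(nm, "C", "PHE", "P", res_p,
               xyz_p[k, 1], xyz_p[k, 2], xyz_p[k, 3])
    }),
    scaffold_gly("P", res_p, cx + d + 2, +1) |>
      dplyr::mutate(residue = "PHE")
  )
  list(rec = rec, pep = pep)
}

random_rotation <- function() {
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- runif(1, 0, 2 * pi)
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

enumerate_contacts <- function(atoms, cutoff, carbons_only = FALSE) {
  a <- atoms
  if (carbons_only) a <- a[a$element == "C", , drop = FALSE]
  rec <- a[a$role == "receptor", , drop = FALSE]
  pep <- a[a$role == "peptide", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(pep))) {
      d2 <- (rec$x[i] - pep$x[j])^2 + (rec$y[i] - pep$y[j])^2 +
        (rec$z[i] - pep$z[j])^2
      if (within_cutoff2(d2, cutoff)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          receptor_serial = rec$serial[i], peptide_serial = pep$serial[j],
          distance = sqrt(d2)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic docked complex with planted interactions
#'
#' Builds a toy protein-peptide complex in which every interaction of
#' interest is planted at exactly known geometry, each in an isolated
#' region of space, so that detector output can be compared against
#' ground truth. The structure is a geometric scaffold: residues carry
#' correct atom names and elements for the interaction chemistry, but
#' no realistic fold. A seeded rigid-body rotation and translation is
#' applied to the whole complex (disable with `rotate = FALSE` to keep
#' planted coordinates axis-aligned).
#'
#' @param close Numeric vector of planted close-contact distances
#'   (receptor carbon to peptide nitrogen), Angstrom.
#' @param hydrophobic Planted carbon-carbon contact distances.
#' @param hbonds Data frame with columns `distance`, `deviation`
#'   (degrees from linear) and `donor_side` (`"receptor"` or
#'   `"peptide"`).
#' @param salt_bridges Data frame with columns `distance` and `variant`
#'   (`"side_chain"`: Lys-Glu; `"c_terminus"`: receptor Arg against the
#'   peptide C-terminal carboxylate).
#' @param pipi Data frame with columns `distance` (centroid-centroid)
#'   and `angle` (plane angle, degrees).
#' @param interface Numeric vector of CA-CA distances planted between
#'   two receptor chains A and B.
#' @param seed Integer seed; fully determines the output.
#' @param rotate Apply the seeded rigid-body transform (default `TRUE`).
#' @return A list of class `pep_synthetic_complex` with elements
#'   `atoms` (atom tibble with roles) and `truth` (per-class ground
#'   truth tables; `close` and `hydrophobic` enumerate all in-cutoff
#'   pairs, the chemistry classes list the planted geometries with an
#'   `expected` flag).
#' @export
make_complex <- function(close = 3.9,
                         hydrophobic = 3.8,
                         hbonds = data.frame(distance = 2.9, deviation = 5,
                                             donor_side = "receptor"),
                         salt_bridges = data.frame(distance = 3.5,
                                                   variant = "side_chain"),
                         pipi = data.frame(distance = 4.5, angle = 10),
                         interface = numeric(0),
                         seed = 1, rotate = TRUE) {
  norm_df <- function(x, proto) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
      proto[0, , drop = FALSE]
    } else {
      tibble::as_tibble(x)
    }
  }
  hbonds <- norm_df(hbonds, data.frame(distance = numeric(0),
                                       deviation = numeric(0),
                                       donor_side = character(0)))
  salt_bridges <- norm_df(salt_bridges,
                          data.frame(distance = numeric(0),
                                     variant = character(0)))
  pipi <- norm_df(pipi, data.frame(distance = numeric(0),
                                   angle = numeric(0)))
  if (any(salt_bridges$variant == "c_terminus") &&
      sum(salt_bridges$variant == "c_terminus") > 1) {
    stop("at most one c_terminus salt bridge can be planted", call. = FALSE)
  }

  # station order: c_terminus bridge (if any) must hold the peptide's
  # last residue, so it is placed last
  plants <- c(
    purrr::map(close, ~ list(kind = "close", d = .x)),
    purrr::map(hydrophobic, ~ list(kind = "hydrophobic", d = .x)),
    purrr::map(seq_len(nrow(hbonds)),
               ~ list(kind = "hbond", d = hbonds$distance[.x],
                      deviation = hbonds$deviation[.x],
                      donor_side = hbonds$donor_side[.x])),
    purrr::map(which(salt_bridges$variant != "c_terminus"),
               ~ list(kind = "salt_bridge", d = salt_bridges$distance[.x],
                      variant = salt_bridges$variant[.x])),
    purrr::map(seq_len(nrow(pipi)),
               ~ list(kind = "pipi", d = pipi$distance[.x],
                      angle = pipi$angle[.x])),
    purrr::map(interface, ~ list(kind = "interface", d = .x)),
    purrr::map(which(salt_bridges$variant == "c_terminus"),
               ~ list(kind = "salt_bridge", d = salt_bridges$distance[.x],
                      variant = "c_terminus"))
  )
  if (length(plants) == 0) stop("nothing to plant", call. = FALSE)

  rec_rows <- list(); pep_rows <- list()
  truth_hb <- list(); truth_sb <- list(); truth_pp <- list()
  truth_if <- list()
  res_r <- 1L; res_p <- 1L
  # inert cap residues isolate the chain termini charged groups
  xmax <- STATION_SPACING * (length(plants) + 1)
  rec_rows[[1]] <- scaffold_gly("A", res_r, -80, -1)
  res_r <- res_r + 1L
  pep_rows[[1]] <- dplyr::bind_rows(
    scaffold_gly("P", res_p, -80, +1) |>
      dplyr::mutate(y = .data$y + 50),
    atom_row("H1", "H", "GLY", "P", res_p, -80 + 4 - 1, 53, 0)
  )
  res_p <- res_p + 1L

  has_cterm_bridge <- any(salt_bridges$variant == "c_terminus")
  n_b <- 0L
  for (k in seq_along(plants)) {
    pl <- plants[[k]]
    cx <- STATION_SPACING * k
    st <- switch(pl$kind,
      close = station_close(cx, "A", res_r, res_p, pl$d),
      hydrophobic = station_hydrophobic(cx, "A", res_r, res_p, pl$d),
      hbond = station_hbond(cx, "A", res_r, res_p, pl$d, pl$deviation,
                            pl$donor_side),
      salt_bridge = station_salt_bridge(cx, "A", res_r, res_p, pl$d,
                                        pl$variant),
      pipi = station_pipi(cx, "A", res_r, res_p, pl$d, pl$angle),
      interface = {
        n_b <- n_b + 1L
        list(
          rec = dplyr::bind_rows(
            atom_row("CA", "C", "GLY", "A", res_r, cx, 0, 0),
            atom_row("N", "N", "GLY", "A", res_r, cx - 4, 3, 0),
            atom_row("CA", "C", "GLY", "B", n_b, cx + pl$d, 0, 0),
            atom_row("N", "N", "GLY", "B", n_b, cx + pl$d + 4, 3, 0)
          ),
          pep = NULL
        )
      }
    )
    rec_rows[[length(rec_rows) + 1L]] <- st$rec
    if (!is.null(st$pep)) pep_rows[[length(pep_rows) + 1L]] <- st$pep
    if (pl$kind == "hbond") {
      donor_on_rec <- pl$donor_side == "receptor"
      truth_hb[[length(truth_hb) + 1L]] <- tibble::tibble(
        donor_chain = if (donor_on_rec) "A" else "P",
        donor_resnum = if (donor_on_rec) res_r else res_p,
        acceptor_chain = if (donor_on_rec) "P" else "A",
        acceptor_resnum = if (donor_on_rec) res_p else res_r,
        distance = pl$d, deviation = pl$deviation,
        donor_side = pl$donor_side,
        expected = pl$d <= 4.0 & pl$deviation <= 40
      )
    }
    if (pl$kind == "salt_bridge") {
      truth_sb[[length(truth_sb) + 1L]] <- tibble::tibble(
        positive_chain = "A", positive_resnum = res_r,
        negative_chain = "P", negative_resnum = res_p,
        distance = pl$d, variant = pl$variant,
        expected = pl$d <= 4.0
      )
    }
    if (pl$kind == "pipi") {
      truth_pp[[length(truth_pp) + 1L]] <- tibble::tibble(
        receptor_resnum = res_r, peptide_resnum = res_p,
        distance = pl$d, angle = pl$angle,
        expected = pl$d <= 5.5 & pl$angle <= 30
      )
    }
    if (pl$kind == "interface") {
      truth_if[[length(truth_if) + 1L]] <- tibble::tibble(
        chain_a_resnum = res_r, chain_b_resnum = n_b,
        distance = pl$d, expected = pl$d < 6.0
      )
    }
    res_r <- res_r + 1L
    if (pl$kind != "interface") res_p <- res_p + 1L
  }
  if (!has_cterm_bridge) {
    pep_rows[[length(pep_rows) + 1L]] <- scaffold_gly("P", res_p, xmax + 80,
                                                      +1) |>
      dplyr::mutate(y = .data$y + 50)
  }
  rec_rows[[length(rec_rows) + 1L]] <- scaffold_gly("A", res_r, xmax + 80, -1)

  atoms <- dplyr::bind_rows(dplyr::bind_rows(rec_rows),
                            dplyr::bind_rows(pep_rows))
  atoms <- dplyr::arrange(atoms, .data$chain, .data$resnum)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$is_hydrogen <- atoms$element == "H"
  atoms$is_backbone <- atoms$name %in% BACKBONE_ATOMS
  atoms <- set_roles(atoms, "P")

  if (rotate) {
    set.seed(seed)
    rot <- random_rotation()
    shift <- runif(3, -5, 5)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
    atoms$x <- xyz[, 1] + shift[1]
    atoms$y <- xyz[, 2] + shift[2]
    atoms$z <- xyz[, 3] + shift[3]
  }

  truth <- list(
    close = enumerate_contacts(atoms, 4.0),
    hydrophobic = enumerate_contacts(atoms, 4.0, carbons_only = TRUE),
    hbonds = dplyr::bind_rows(truth_hb),
    salt_bridges = dplyr::bind_rows(truth_sb),
    pipi = dplyr::bind_rows(truth_pp),
    interface = dplyr::bind_rows(truth_if)
  )
  structure(list(atoms = atoms, truth = truth),
            class = "pep_synthetic_complex")
}

#' Synthetic binding-site screening table with known signals
#'
#' Generates a screening table of `m0` true-null hits (p ~ Uniform(0,1))
#' and `m1` true signals (p ~ Beta(0.1, 10)), with pocket residue sets
#' attached and truth labels, to exercise the BH/FDR machinery.
#'
#' @param m0 Number of null tests.
#' @param m1 Number of signal tests.
#' @param seed Integer seed.
#' @return A tibble with columns `fragment_id`, `structure_id`, `chain`,
#'   `p_raw`, `pocket` (list-column) and `is_signal`.
#' @export
make_screening_table <- function(m0 = 100, m1 = 20, seed = 1) {
  stopifnot(m0 >= 0, m1 >= 0, m0 + m1 >= 1)
  set.seed(seed)
  m <- m0 + m1
  p <- c(runif(m0), pmax(rbeta(m1, 0.1, 10), 1e-300))
  is_signal <- rep(c(FALSE, TRUE), c(m0, m1))
  pocket_a <- paste0("A:", 10:14)
  pocket_b <- paste0("A:", 40:44)
  hits <- tibble::tibble(
    fragment_id = sprintf("frag%04d", seq_len(m)),
    structure_id = sprintf("STR%03d", (seq_len(m) - 1) %% 20 + 1),
    chain = "A",
    p_raw = p,
    pocket = purrr::map(seq_len(m), function(i) {
      if (is_signal[i]) pocket_a else pocket_b
    }),
    is_signal = is_signal
  )
  hits[sample.int(m), , drop = FALSE]
}

#' Synthetic MM/GBSA tables with known binding free energy
#'
#' Builds per-snapshot energy tables whose per-snapshot binding free
#' energy is `dg_star` plus zero-mean Gaussian noise, together with a
#' per-residue decomposition table whose contributions sum exactly to
#' `dg_star`.
#'
#' @param dg_star True binding free energy in kcal/mol.
#' @param n_snapshots Number of conformational snapshots (default 100).
#' @param noise_sd Per-snapshot SD of the binding energy (kcal/mol).
#' @param n_protein_res Number of protein residues in the decomposition.
#' @param peptide_length Number of peptide residues.
#' @param prominent_factor The first protein residue's |contribution| is
#'   this multiple of the mean remaining magnitude (default 1; set high
#'   to plant a dominant residue).
#' @param seed Integer seed.
#' @param system_id System identifier (default `"sys1"`).
#' @return A list with `energies` (snapshot table for
#'   [delta_g_bind()]), `contribs` (decomposition table with
#'   `position_class` set for peptide residues) and `dg_star`.
#' @export
make_decomposition <- function(dg_star = -48.02, n_snapshots = 100,
                               noise_sd = 0, n_protein_res = 8,
                               peptide_length = 10, prominent_factor = 1,
                               seed = 1, system_id = "sys1") {
  stopifnot(n_snapshots >= 1, n_protein_res >= 1, peptide_length >= 2)
  set.seed(seed)
  n_res <- n_protein_res + peptide_length
  w <- abs(rnorm(n_res, 1, 0.3)) + 0.1
  w[1] <- prominent_factor * mean(w[-1])
  contrib <- w / sum(w) * dg_star
  aa_pool <- c("ARG", "LYS", "GLU", "ASP", "TRP", "PHE", "TYR", "LEU",
               "SER", "THR", "ALA", "GLY")
  contribs <- tibble::tibble(
    system_id = system_id,
    chain_role = rep(c("protein", "peptide"), c(n_protein_res, peptide_length)),
    res_name = sample(aa_pool, n_res, replace = TRUE),
    res_index = c(seq_len(n_protein_res), seq_len(peptide_length)),
    dg_contrib = contrib
  )
  contribs$position_class <- NA_character_
  pep <- contribs$chain_role == "peptide"
  contribs$position_class[pep] <- position_class(contribs$res_index[pep],
                                                 peptide_length)

  terms <- c("e_bnd", "e_el", "e_vdw", "g_pol", "g_np")
  base <- list(
    protein = setNames(rnorm(5, c(1500, -12000, -1200, -2500, 180), 10), terms),
    peptide = setNames(rnorm(5, c(120, -800, -90, -250, 15), 5), terms)
  )
  delta <- dg_star + rnorm(n_snapshots, 0, noise_sd)
  rows <- purrr::map(seq_len(n_snapshots), function(s) {
    fluct <- setNames(rnorm(5, 0, 2), terms)
    prot <- base$protein + fluct
    pept <- base$peptide + setNames(rnorm(5, 0, 1), terms)
    comp <- prot + pept
    comp[["e_el"]] <- comp[["e_el"]] + delta[s]
    dplyr::bind_rows(
      tibble::tibble(system_id = system_id, snapshot = s, role = "complex",
                     !!!as.list(comp)),
      tibble::tibble(system_id = system_id, snapshot = s, role = "protein",
                     !!!as.list(prot)),
      tibble::tibble(system_id = system_id, snapshot = s, role = "peptide",
                     !!!as.list(pept))
    )
  })
  list(energies = dplyr::bind_rows(rows), contribs = contribs,
       dg_star = dg_star)
}

rtruncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- rnorm(sum(x < 0), mean, sd)
  x
}

#' Synthetic cohort of interaction profiles and binding energies
#'
#' Draws a cohort of per-system interaction statistics from the
#' distributions that characterize a large docking study of short
#' stress-induced peptides against plant proteins: close contacts
#' ~ Normal(167, 49) truncated at 0, hydrophobic contacts
#' ~ Normal(24, 8), hydrogen bonds ~ Normal(4.5, 2), protein-side donor
#' fraction centred on 0.51, the salt-bridge/pi-pi category split
#' (52 : 7.7 : 5.8 : 34.6 for bridge-only : stack-only : both :
#' neither), conditional bridge and stack counts ~ Normal(1.72, 1) and
#' Normal(1.63, 0.7) (at least 1), peptide-atom participation fractions
#' centred on 0.238 (side chain) and 0.387 (backbone), and binding free
#' energies ~ Normal(-20, 9) kcal/mol, under which about 99 percent of
#' systems bind favourably.
#'
#' @param n_systems Number of systems (default 104).
#' @param seed Integer seed.
#' @param contact_mean,contact_sd Close-contact count distribution.
#' @param dg_mean,dg_sd Binding free-energy distribution (kcal/mol).
#' @param category_probs Named probabilities for `salt_bridge_only`,
#'   `pipi_only`, `both`, `neither` (normalized internally).
#' @return A list of class `pep_cohort` with `profiles` (tibble shaped
#'   like rows of [interaction_profile()]), `energies` (tibble shaped
#'   like [delta_g_bind()] output) and `params` (the generator
#'   parameters).
#' @export
make_cohort <- function(n_systems = 104, seed = 1,
                        contact_mean = 167, contact_sd = 49,
                        dg_mean = -20, dg_sd = 9,
                        category_probs = c(salt_bridge_only = 0.520,
                                           pipi_only = 0.077,
                                           both = 0.058,
                                           neither = 0.346)) {
  stopifnot(n_systems >= 1)
  set.seed(seed)
  probs <- category_probs / sum(category_probs)
  category <- sample(names(probs), n_systems, replace = TRUE, prob = probs)
  has_sb <- category %in% c("salt_bridge_only", "both")
  has_pp <- category %in% c("pipi_only", "both")
  n_sb <- ifelse(has_sb, pmax(1, round(rnorm(n_systems, 1.72, 1))), 0)
  n_pp <- ifelse(has_pp, pmax(1, round(rnorm(n_systems, 1.63, 0.7))), 0)
  n_pep_atoms <- round(rtruncnorm0(n_systems, 75, 15))
  overall_ratio <- rtruncnorm0(n_systems, 3.2, 0.3)
  n_bb <- pmax(4, round(n_pep_atoms / (1 + overall_ratio)))
  n_sc <- pmax(1, n_pep_atoms - n_bb)
  profiles <- tibble::tibble(
    system_id = sprintf("sys%03d", seq_len(n_systems)),
    n_close_contacts = round(rtruncnorm0(n_systems, contact_mean, contact_sd)),
    n_hydrophobic = round(rtruncnorm0(n_systems, 24, 8)),
    n_hbonds = pmax(1, round(rnorm(n_systems, 4.5, 2))),
    n_salt_bridges = n_sb,
    n_pipi = n_pp,
    has_salt_bridge = has_sb,
    has_pipi = has_pp,
    frac_donor_protein = rbeta(n_systems, 51, 49),
    n_peptide_sc_atoms = n_sc,
    n_peptide_bb_atoms = n_bb,
    frac_sc_in_contacts = rbeta(n_systems, 23.8, 76.2),
    frac_bb_in_contacts = rbeta(n_systems, 38.7, 61.3),
    contacts_per_sc_atom = rtruncnorm0(n_systems, 3.6, 0.5),
    contacts_per_bb_atom = rtruncnorm0(n_systems, 2.8, 0.5),
    unique_sc_bb_ratio = rtruncnorm0(n_systems, 2.0, 0.5),
    overall_sc_bb_ratio = n_sc / n_bb
  )
  energies <- tibble::tibble(
    system_id = profiles$system_id,
    dg_bind = rnorm(n_systems, dg_mean, dg_sd),
    dg_sd = runif(n_systems, 1, 4),
    n_snapshots = 100L
  )
  structure(list(
    profiles = profiles, energies = energies,
    params = list(n_systems = n_systems, contact_mean = contact_mean,
                  contact_sd = contact_sd, dg_mean = dg_mean, dg_sd = dg_sd,
                  category_probs = as.list(probs))
  ), class = "pep_cohort")
}
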