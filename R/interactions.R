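# boundary rule shared by every "within X Angstrom" criterion: inclusive,
# with a 1e-9 guard so analytically planted boundary geometries (e.g. a
# pair at exactly 4.0 A) are not lost to floating-point representation
within_cutoff2 <- function(d2, cutoff) d2 <= cutoff^2 + 1e-9

# cell-list neighbor search: all pairs (i in A, j in B) with
# |A_i - B_j| <= cutoff; identical output to the all-pairs scan
grid_pairs <- function(A, B, cutoff) {
  empty <- tibble::tibble(i = integer(0), j = integer(0), distance = numeric(0))
  if (nrow(A) == 0 || nrow(B) == 0) return(empty)
  ca <- floor(A / cutoff)
  cb <- floor(B / cutoff)
  key_b <- paste(cb[, 1], cb[, 2], cb[, 3], sep = ",")
  bmap <- split(seq_len(nrow(B)), key_b)
  key_a <- paste(ca[, 1], ca[, 2], ca[, 3], sep = ",")
  amap <- split(seq_len(nrow(A)), key_a)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pieces <- list()
  for (key in names(amap)) {
    cc <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    nkeys <- paste(cc[1] + offs[, 1], cc[2] + offs[, 2], cc[3] + offs[, 3],
                   sep = ",")
    cand <- unlist(bmap[nkeys[nkeys %in% names(bmap)]], use.names = FALSE)
    if (length(cand) == 0) next
    ai <- amap[[key]]
    d2 <- outer(A[ai, 1], B[cand, 1], "-")^2 +
      outer(A[ai, 2], B[cand, 2], "-")^2 +
      outer(A[ai, 3], B[cand, 3], "-")^2
    hit <- which(within_cutoff2(d2, cutoff), arr.ind = TRUE)
    if (nrow(hit) == 0) next
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      i = ai[hit[, 1]], j = cand[hit[, 2]],
      distance = sqrt(d2[hit])
    )
  }
  if (length(pieces) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(pieces), .data$i, .data$j)
}

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

check_roles <- function(atoms) {
  stopifnot(is.data.frame(atoms), "role" %in% names(atoms))
  if (!all(c("receptor", "peptide") %in% atoms$role)) {
    stop("model must contain both receptor and peptide atoms", call. = FALSE)
  }
  invisible(atoms)
}

pair_table <- function(rec, pep, pairs, kind) {
  tibble::tibble(
    receptor_serial  = rec$serial[pairs$i],
    receptor_name    = rec$name[pairs$i],
    receptor_residue = rec$residue[pairs$i],
    receptor_chain   = rec$chain[pairs$i],
    receptor_resnum  = rec$resnum[pairs$i],
    peptide_serial   = pep$serial[pairs$j],
    peptide_name     = pep$name[pairs$j],
    peptide_residue  = pep$residue[pairs$j],
    peptide_chain    = pep$chain[pairs$j],
    peptide_resnum   = pep$resnum[pairs$j],
    distance         = pairs$distance,
    kind             = kind
  )
}

#' Close contacts at the protein-peptide interface
#'
#' Every receptor atom within `cutoff` Angstrom of any peptide atom
#' (inclusive boundary) forms a close contact. All resolved atoms are
#' used by default, hydrogens included when present; `heavy_only = TRUE`
#' restricts both sides to heavy atoms.
#'
#' @param atoms Atom tibble with a `role` column.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @param heavy_only Drop hydrogens before searching (default `FALSE`).
#' @return A tibble, one row per contacting atom pair, with atom
#'   identities, `distance` and `kind = "close"`.
#' @export
close_contacts <- function(atoms, cutoff = 4.0, heavy_only = FALSE) {
  check_roles(atoms)
  if (heavy_only) atoms <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  rec <- atoms[atoms$role == "receptor", , drop = FALSE]
  pep <- atoms[atoms$role == "peptide", , drop = FALSE]
  pairs <- grid_pairs(coords_of(rec), coords_of(pep), cutoff)
  pair_table(rec, pep, pairs, "close")
}

#' Hydrophobic contacts at the protein-peptide interface
#'
#' Peptide carbon atoms within `cutoff` Angstrom of receptor carbon
#' atoms.
#'
#' @inheritParams close_contacts
#' @return A contact tibble with `kind = "hydrophobic"`.
#' @export
hydrophobic_contacts <- function(atoms, cutoff = 4.0) {
  check_roles(atoms)
  carbons <- atoms[atoms$element == "C", , drop = FALSE]
  rec <- carbons[carbons$role == "receptor", , drop = FALSE]
  pep <- carbons[carbons$role == "peptide", , drop = FALSE]
  pairs <- grid_pairs(coords_of(rec), coords_of(pep), cutoff)
  pair_table(rec, pep, pairs, "hydrophobic")
}

# hydrogens covalently attached to each heavy atom (same residue,
# within 1.25 A)
attached_hydrogens <- function(atoms) {
  hy <- atoms[atoms$is_hydrogen, , drop = FALSE]
  heavy <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  if (nrow(hy) == 0) return(NULL)
  pairs <- grid_pairs(coords_of(heavy), coords_of(hy), 1.25)
  same_res <- heavy$chain[pairs$i] == hy$chain[pairs$j] &
    heavy$resnum[pairs$i] == hy$resnum[pairs$j]
  pairs <- pairs[same_res, , drop = FALSE]
  tibble::tibble(
    heavy_serial = heavy$serial[pairs$i],
    h_serial     = hy$serial[pairs$j]
  )
}

#' Hydrogen bonds at the protein-peptide interface
#'
#' Detects cross-role donor...acceptor pairs. Donors and acceptors are
#' nitrogen and oxygen atoms; a donor must carry a covalently bound
#' hydrogen. A pair is a hydrogen bond when the donor-acceptor distance
#' is at most `d_cutoff` and the deviation of D-H...A from linearity
#' (minimized over the donor's hydrogens) is at most `angle_cutoff`
#' degrees.
#'
#' For models without any explicit hydrogens the angle gate cannot be
#' evaluated; such models fall back to a stricter distance-only rule
#' (D-A distance <= `d_cutoff_noh`), with `geometry_incomplete = TRUE`,
#' undirected pairs and `donor_side = NA`.
#'
#' @param atoms Atom tibble with a `role` column.
#' @param d_cutoff Donor-acceptor distance cutoff in Angstrom
#'   (default 4.0).
#' @param angle_cutoff Maximum deviation from a linear D-H...A in
#'   degrees (default 40).
#' @param d_cutoff_noh Distance-only cutoff used when the model carries
#'   no hydrogens (default 3.5).
#' @return A tibble with one row per hydrogen bond: donor and acceptor
#'   atom identities, `d_a_distance`, `deviation`, `donor_side`
#'   (`"receptor"` or `"peptide"`), `geometry_incomplete`.
#' @export
hydrogen_bonds <- function(atoms, d_cutoff = 4.0, angle_cutoff = 40,
                           d_cutoff_noh = 3.5) {
  check_roles(atoms)
  polar <- atoms[atoms$element %in% c("N", "O"), , drop = FALSE]
  rec <- polar[polar$role == "receptor", , drop = FALSE]
  pep <- polar[polar$role == "peptide", , drop = FALSE]
  empty <- tibble::tibble(
    donor_serial = integer(0), donor_name = character(0),
    donor_residue = character(0), donor_chain = character(0),
    donor_resnum = integer(0),
    acceptor_serial = integer(0), acceptor_name = character(0),
    acceptor_residue = character(0), acceptor_chain = character(0),
    acceptor_resnum = integer(0),
    d_a_distance = numeric(0), deviation = numeric(0),
    donor_side = character(0), geometry_incomplete = logical(0)
  )
  hmap <- attached_hydrogens(atoms)

  if (is.null(hmap)) {
    # no explicit hydrogens anywhere: distance-only fallback
    pairs <- grid_pairs(coords_of(rec), coords_of(pep), d_cutoff_noh)
    if (nrow(pairs) == 0) return(empty)
    return(tibble::tibble(
      donor_serial = rec$serial[pairs$i], donor_name = rec$name[pairs$i],
      donor_residue = rec$residue[pairs$i], donor_chain = rec$chain[pairs$i],
      donor_resnum = rec$resnum[pairs$i],
      acceptor_serial = pep$serial[pairs$j], acceptor_name = pep$name[pairs$j],
      acceptor_residue = pep$residue[pairs$j],
      acceptor_chain = pep$chain[pairs$j],
      acceptor_resnum = pep$resnum[pairs$j],
      d_a_distance = pairs$distance, deviation = NA_real_,
      donor_side = NA_character_, geometry_incomplete = TRUE
    ))
  }

  xyz <- coords_of(atoms)
  rownames(xyz) <- as.character(atoms$serial)
  one_direction <- function(donors, acceptors, donor_side) {
    donors <- donors[donors$serial %in% hmap$heavy_serial, , drop = FALSE]
    if (nrow(donors) == 0 || nrow(acceptors) == 0) return(NULL)
    pairs <- grid_pairs(coords_of(donors), coords_of(acceptors), d_cutoff)
    if (nrow(pairs) == 0) return(NULL)
    dev <- purrr::map_dbl(seq_len(nrow(pairs)), function(k) {
      dser <- donors$serial[pairs$i[k]]
      aser <- acceptors$serial[pairs$j[k]]
      hs <- hmap$h_serial[hmap$heavy_serial == dser]
      min(purrr::map_dbl(hs, function(h) {
        180 - angle3(xyz[as.character(dser), ],
                     xyz[as.character(h), ],
                     xyz[as.character(aser), ])
      }))
    })
    keep <- dev <= angle_cutoff + 1e-9
    pairs <- pairs[keep, , drop = FALSE]
    dev <- dev[keep]
    if (nrow(pairs) == 0) return(NULL)
    tibble::tibble(
      donor_serial = donors$serial[pairs$i],
      donor_name = donors$name[pairs$i],
      donor_residue = donors$residue[pairs$i],
      donor_chain = donors$chain[pairs$i],
      donor_resnum = donors$resnum[pairs$i],
      acceptor_serial = acceptors$serial[pairs$j],
      acceptor_name = acceptors$name[pairs$j],
      acceptor_residue = acceptors$residue[pairs$j],
      acceptor_chain = acceptors$chain[pairs$j],
      acceptor_resnum = acceptors$resnum[pairs$j],
      d_a_distance = pairs$distance, deviation = dev,
      donor_side = donor_side, geometry_incomplete = FALSE
    )
  }
  out <- dplyr::bind_rows(
    one_direction(rec, pep, "receptor"),
    one_direction(pep, rec, "peptide")
  )
  if (nrow(out) == 0) empty else out
}

# formal-charge group table; His is treated as positively charged,
# consistent with counting it among the charged residues
positive_group_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                             HIS = c("ND1", "NE2"))
negative_group_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

charged_groups <- function(atoms) {
  heavy <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  groups <- list()
  push <- function(groups, rows, charge, group_type) {
    if (nrow(rows) == 0) return(groups)
    groups[[length(groups) + 1L]] <- list(
      role = rows$role[1], chain = rows$chain[1], resnum = rows$resnum[1],
      residue = rows$residue[1], charge = charge, group_type = group_type,
      serials = rows$serial, xyz = coords_of(rows)
    )
    groups
  }
  res <- dplyr::distinct(heavy, .data$role, .data$chain, .data$resnum,
                         .data$residue)
  for (k in seq_len(nrow(res))) {
    sel <- heavy$chain == res$chain[k] & heavy$resnum == res$resnum[k]
    rr <- heavy[sel, , drop = FALSE]
    resname <- res$residue[k]
    if (resname %in% names(positive_group_atoms)) {
      groups <- push(groups,
                     rr[rr$name %in% positive_group_atoms[[resname]], ],
                     "positive", "side_chain")
    }
    if (resname %in% names(negative_group_atoms)) {
      groups <- push(groups,
                     rr[rr$name %in% negative_group_atoms[[resname]], ],
                     "negative", "side_chain")
    }
  }
  # chain termini: N-terminal amine (positive), C-terminal carboxylate
  for (ch in unique(heavy$chain)) {
    cr <- heavy[heavy$chain == ch, , drop = FALSE]
    first <- min(cr$resnum); last <- max(cr$resnum)
    groups <- push(groups, cr[cr$resnum == first & cr$name == "N", ],
                   "positive", "n_terminus")
    groups <- push(groups, cr[cr$resnum == last & cr$name %in% c("O", "OXT"), ],
                   "negative", "c_terminus")
  }
  groups
}

#' Salt bridges at the protein-peptide interface
#'
#' Pairs of oppositely charged groups on opposite roles whose minimal
#' inter-group heavy-atom distance is at most `cutoff`. Charged groups
#' are the guanidinium of Arg, the ammonium of Lys, the imidazole of
#' His, the carboxylates of Asp and Glu, plus every chain's N-terminal
#' amine and C-terminal carboxylate.
#'
#' @param atoms Atom tibble with a `role` column.
#' @param cutoff Minimal inter-group atom distance in Angstrom
#'   (default 4.0).
#' @return A tibble with one row per bridge: positive- and
#'   negative-group residue identities and group types, `min_distance`,
#'   and which role carries the positive charge (`positive_role`).
#' @export
salt_bridges <- function(atoms, cutoff = 4.0) {
  check_roles(atoms)
  groups <- charged_groups(atoms)
  pos <- purrr::keep(groups, ~ .x$charge == "positive")
  neg <- purrr::keep(groups, ~ .x$charge == "negative")
  rows <- list()
  for (p in pos) {
    for (q in neg) {
      if (p$role == q$role) next
      d2 <- outer(p$xyz[, 1], q$xyz[, 1], "-")^2 +
        outer(p$xyz[, 2], q$xyz[, 2], "-")^2 +
        outer(p$xyz[, 3], q$xyz[, 3], "-")^2
      dmin <- sqrt(min(d2))
      if (within_cutoff2(dmin^2, cutoff)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          positive_residue = p$residue, positive_chain = p$chain,
          positive_resnum = p$resnum, positive_group = p$group_type,
          positive_role = p$role,
          negative_residue = q$residue, negative_chain = q$chain,
          negative_resnum = q$resnum, negative_group = q$group_type,
          min_distance = dmin
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      positive_residue = character(0), positive_chain = character(0),
      positive_resnum = integer(0), positive_group = character(0),
      positive_role = character(0),
      negative_residue = character(0), negative_chain = character(0),
      negative_resnum = integer(0), negative_group = character(0),
      min_distance = numeric(0)
    ))
  }
  dplyr::bind_rows(rows)
}

AROMATIC_RINGS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
             ring6 = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

ring_geometries <- function(atoms) {
  heavy <- atoms[!atoms$is_hydrogen &
                   atoms$residue %in% names(AROMATIC_RINGS), , drop = FALSE]
  res <- dplyr::distinct(heavy, .data$role, .data$chain, .data$resnum,
                         .data$residue)
  rings <- list()
  for (k in seq_len(nrow(res))) {
    rr <- heavy[heavy$chain == res$chain[k] & heavy$resnum == res$resnum[k], ,
                drop = FALSE]
    defs <- AROMATIC_RINGS[[res$residue[k]]]
    for (ring_name in names(defs)) {
      sel <- rr[rr$name %in% defs[[ring_name]], , drop = FALSE]
      if (nrow(sel) < 5) {
        warning(sprintf(
          "aromatic ring %s of %s %s:%d has %d resolved atoms; skipped",
          ring_name, res$residue[k], res$chain[k], res$resnum[k], nrow(sel)
        ), call. = FALSE)
        next
      }
      xyz <- coords_of(sel)
      centroid <- colMeans(xyz)
      normal <- svd(sweep(xyz, 2, centroid))$v[, 3]
      rings[[length(rings) + 1L]] <- list(
        role = res$role[k], chain = res$chain[k], resnum = res$resnum[k],
        residue = res$residue[k], ring = ring_name,
        centroid = centroid, normal = normal
      )
    }
  }
  rings
}

#' Pi-pi stacking at the protein-peptide interface
#'
#' Detects near-parallel aromatic ring pairs across roles. Rings are the
#' six-membered rings of Phe and Tyr, the imidazole of His, and both
#' rings of Trp; ring planes come from a least-squares fit. A pair
#' stacks when the centroid distance is at most `centroid_cutoff` and
#' the angle between ring planes (folded to [0, 90] degrees) is at most
#' `angle_cutoff`. T-shaped geometries are not classed as stacks.
#'
#' @param atoms Atom tibble with a `role` column.
#' @param centroid_cutoff Centroid-centroid cutoff in Angstrom
#'   (default 5.5).
#' @param angle_cutoff Maximum inter-plane angle in degrees
#'   (default 30).
#' @return A tibble with one row per stack: both ring identities,
#'   `centroid_distance`, `plane_angle`.
#' @export
pipi_stacks <- function(atoms, centroid_cutoff = 5.5, angle_cutoff = 30) {
  check_roles(atoms)
  rings <- ring_geometries(atoms)
  rec <- purrr::keep(rings, ~ .x$role == "receptor")
  pep <- purrr::keep(rings, ~ .x$role == "peptide")
  rows <- list()
  for (a in rec) {
    for (b in pep) {
      d <- sqrt(sum((a$centroid - b$centroid)^2))
      if (!within_cutoff2(d^2, centroid_cutoff)) next
      cosang <- abs(sum(a$normal * b$normal))
      ang <- rad2deg(acos(pmin(1, cosang)))
      if (ang <= angle_cutoff + 1e-9) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          receptor_residue = a$residue, receptor_chain = a$chain,
          receptor_resnum = a$resnum, receptor_ring = a$ring,
          peptide_residue = b$residue, peptide_chain = b$chain,
          peptide_resnum = b$resnum, peptide_ring = b$ring,
          centroid_distance = d, plane_angle = ang
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      receptor_residue = character(0), receptor_chain = character(0),
      receptor_resnum = integer(0), receptor_ring = character(0),
      peptide_residue = character(0), peptide_chain = character(0),
      peptide_resnum = integer(0), peptide_ring = character(0),
      centroid_distance = numeric(0), plane_angle = numeric(0)
    ))
  }
  dplyr::bind_rows(rows)
}
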