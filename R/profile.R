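#' Full interaction profile of a docked complex
#'
#' Runs every interaction detector on a complex and summarizes the
#' results into the per-complex statistics used for dataset-level
#' characterization: interaction counts, the hydrogen-bond donor-side
#' split, which peptide atoms participate in close contacts (split into
#' side chain and backbone), contacts per interacting atom, and
#' side-chain:backbone atom ratios.
#'
#' @param atoms Atom tibble with a `role` column (from
#'   [read_complex()] or [make_complex()]).
#' @param system_id Identifier recorded in the output (default `"complex"`).
#' @param close_cutoff,hydrophobic_cutoff Distance cutoffs in Angstrom
#'   (default 4.0).
#' @param hbond_d_cutoff,hbond_angle_cutoff Hydrogen-bond criteria
#'   (default 4.0 Angstrom, 40 degrees).
#' @param salt_bridge_cutoff Minimal inter-group distance (default 4.0).
#' @param pipi_centroid_cutoff,pipi_angle_cutoff Stacking criteria
#'   (default 5.5 Angstrom, 30 degrees).
#' @return A one-row tibble of class `pep_profile` with the count and
#'   participation statistics; the individual interaction tables are
#'   attached as the `"interactions"` attribute.
#' @export
interaction_profile <- function(atoms, system_id = "complex",
                                close_cutoff = 4.0,
                                hydrophobic_cutoff = 4.0,
                                hbond_d_cutoff = 4.0,
                                hbond_angle_cutoff = 40,
                                salt_bridge_cutoff = 4.0,
                                pipi_centroid_cutoff = 5.5,
                                pipi_angle_cutoff = 30) {
  check_roles(atoms)
  cc <- close_contacts(atoms, close_cutoff)
  cc_heavy <- close_contacts(atoms, close_cutoff, heavy_only = TRUE)
  hc <- hydrophobic_contacts(atoms, hydrophobic_cutoff)
  hb <- hydrogen_bonds(atoms, hbond_d_cutoff, hbond_angle_cutoff)
  sb <- salt_bridges(atoms, salt_bridge_cutoff)
  pp <- pipi_stacks(atoms, pipi_centroid_cutoff, pipi_angle_cutoff)

  pep <- atoms[atoms$role == "peptide", , drop = FALSE]
  n_sc <- sum(!pep$is_backbone)
  n_bb <- sum(pep$is_backbone)
  contacted <- unique(cc$peptide_serial)
  sc_serials <- pep$serial[!pep$is_backbone]
  bb_serials <- pep$serial[pep$is_backbone]
  uniq_sc <- sum(contacted %in% sc_serials)
  uniq_bb <- sum(contacted %in% bb_serials)
  n_cc_sc <- sum(cc$peptide_serial %in% sc_serials)
  n_cc_bb <- sum(cc$peptide_serial %in% bb_serials)

  donor_known <- hb$donor_side[!is.na(hb$donor_side)]

  prof <- tibble::tibble(
    system_id            = system_id,
    n_close_contacts     = nrow(cc),
    n_close_heavy        = nrow(cc_heavy),
    n_hydrophobic        = nrow(hc),
    n_hbonds             = nrow(hb),
    n_salt_bridges       = nrow(sb),
    n_pipi               = nrow(pp),
    has_salt_bridge      = nrow(sb) > 0,
    has_pipi             = nrow(pp) > 0,
    frac_donor_protein   = if (length(donor_known) > 0)
      mean(donor_known == "receptor") else NA_real_,
    n_peptide_sc_atoms   = n_sc,
    n_peptide_bb_atoms   = n_bb,
    frac_sc_in_contacts  = if (n_sc > 0) uniq_sc / n_sc else NA_real_,
    frac_bb_in_contacts  = if (n_bb > 0) uniq_bb / n_bb else NA_real_,
    contacts_per_sc_atom = if (uniq_sc > 0) n_cc_sc / uniq_sc else NA_real_,
    contacts_per_bb_atom = if (uniq_bb > 0) n_cc_bb / uniq_bb else NA_real_,
    unique_sc_bb_ratio   = if (uniq_bb > 0) uniq_sc / uniq_bb else NA_real_,
    overall_sc_bb_ratio  = if (n_bb > 0) n_sc / n_bb else NA_real_
  )
  attr(prof, "interactions") <- list(
    close = cc, close_heavy = cc_heavy, hydrophobic = hc,
    hbonds = hb, salt_bridges = sb, pipi = pp
  )
  class(prof) <- c("pep_profile", class(prof))
  prof
}

#' Individual interaction tables of a profile
#'
#' @param profile A `pep_profile` from [interaction_profile()].
#' @return Named list of tibbles (`close`, `close_heavy`, `hydrophobic`,
#'   `hbonds`, `salt_bridges`, `pipi`).
#' @export
profile_interactions <- function(profile) {
  out <- attr(profile, "interactions")
  if (is.null(out)) stop("no interaction detail attached", call. = FALSE)
  out
}

#' Write per-complex profile JSON and flat interaction TSV
#'
#' @param profile A `pep_profile`.
#' @param json_path Output JSON path for the summary row.
#' @param tsv_path Optional output TSV of individual contacts/bonds
#'   (one row each, with a `kind` column).
#' @return `json_path`, invisibly.
#' @export
write_profile <- function(profile, json_path, tsv_path = NULL) {
  jsonlite::write_json(as.list(tibble::as_tibble(profile)[1, ]), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(tsv_path)) {
    ints <- profile_interactions(profile)
    flat <- dplyr::bind_rows(
      dplyr::mutate(ints$close, .kind = "close"),
      dplyr::mutate(ints$hydrophobic, .kind = "hydrophobic"),
      if (nrow(ints$hbonds) > 0)
        dplyr::mutate(ints$hbonds, .kind = "hbond"),
      if (nrow(ints$salt_bridges) > 0)
        dplyr::mutate(ints$salt_bridges, .kind = "salt_bridge"),
      if (nrow(ints$pipi) > 0)
        dplyr::mutate(ints$pipi, .kind = "pipi")
    )
    readr::write_tsv(flat, tsv_path)
  }
  invisible(json_path)
}
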