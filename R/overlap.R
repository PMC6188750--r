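#' Inter-chain interface residues
#'
#' Finds the residues at the interface between two receptor chains:
#' every residue pair whose CA-CA distance is strictly below `cutoff`
#' Angstrom marks both residues as interacting. The criterion is
#' deliberately strict-inequality (`< 6.0` by default), unlike the
#' inclusive 4.0 Angstrom close-contact rule. Residues lacking a CA atom
#' are skipped with a warning.
#'
#' @param atoms Atom tibble (roles not required).
#' @param chain_a,chain_b Chain identifiers; order does not matter.
#' @param cutoff CA-CA distance bound in Angstrom (default 6.0,
#'   exclusive).
#' @return A tibble of interface residues with columns `chain`,
#'   `resnum`, `residue` and `n_partners` (number of sub-cutoff partners
#'   on the other chain).
#' @export
interface_residues <- function(atoms, chain_a, chain_b, cutoff = 6.0) {
  stopifnot(is.data.frame(atoms))
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  a <- ca[ca$chain == chain_a, , drop = FALSE]
  b <- ca[ca$chain == chain_b, , drop = FALSE]
  if (nrow(a) == 0) stop("chain ", chain_a, " has no CA atoms", call. = FALSE)
  if (nrow(b) == 0) stop("chain ", chain_b, " has no CA atoms", call. = FALSE)
  for (ch in c(chain_a, chain_b)) {
    all_res <- unique(atoms$resnum[atoms$chain == ch])
    with_ca <- unique(ca$resnum[ca$chain == ch])
    miss <- setdiff(all_res, with_ca)
    if (length(miss) > 0) {
      warning(sprintf("chain %s: %d residue(s) lack a CA atom and are skipped",
                      ch, length(miss)), call. = FALSE)
    }
  }
  pairs <- grid_pairs(coords_of(a), coords_of(b), cutoff)
  pairs <- pairs[pairs$distance < cutoff, , drop = FALSE]  # strict bound
  if (nrow(pairs) == 0) {
    return(tibble::tibble(chain = character(0), resnum = integer(0),
                          residue = character(0), n_partners = integer(0)))
  }
  dplyr::bind_rows(
    tibble::tibble(chain = a$chain[pairs$i], resnum = a$resnum[pairs$i],
                   residue = a$residue[pairs$i]),
    tibble::tibble(chain = b$chain[pairs$j], resnum = b$resnum[pairs$j],
                   residue = b$residue[pairs$j])
  ) |>
    dplyr::count(.data$chain, .data$resnum, .data$residue,
                 name = "n_partners") |>
    dplyr::arrange(.data$chain, .data$resnum)
}

residue_tokens <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chain", "resnum") %in% names(x)))
    paste0(x$chain, ":", x$resnum)
  } else {
    as.character(x)
  }
}

#' Does a predicted pocket overlap an interface or annotated site?
#'
#' Flags overlap when the pocket shares at least `min_shared` residues
#' with the reference set. Residues are compared as `chain:resnum`
#' tokens.
#'
#' @param pocket Character vector of `chain:resnum` tokens, or a data
#'   frame with `chain` and `resnum` columns.
#' @param reference The reference residue set in the same form (e.g.
#'   from [interface_residues()] or a row of a site annotation table).
#' @param min_shared Minimum number of shared residues to flag overlap
#'   (default 1).
#' @return A one-row tibble with `overlaps`, `n_shared` and a
#'   list-column `shared` of the shared residue tokens.
#' @export
pocket_overlap <- function(pocket, reference, min_shared = 1) {
  p <- unique(residue_tokens(pocket))
  r <- unique(residue_tokens(reference))
  shared <- intersect(p, r)
  tibble::tibble(
    overlaps = length(shared) >= min_shared && length(shared) > 0,
    n_shared = length(shared),
    shared   = list(shared)
  )
}

#' @rdname pocket_overlap
#' @param iface An interface residue table from [interface_residues()].
#' @export
pocket_at_interface <- function(pocket, iface, min_shared = 1) {
  pocket_overlap(pocket, iface, min_shared)
}

#' Test a pocket against annotated ligand/cofactor/catalytic sites
#'
#' @param pocket Pocket residue set (see [pocket_overlap()]).
#' @param sites Site annotation tibble from [read_site_annotations()]
#'   (or with columns `structure_id`, `site_kind`, `ligand_code`,
#'   `residues` list-column).
#' @param min_shared Minimum shared residues (default 1).
#' @return `sites` with `overlaps`, `n_shared` and `shared` columns
#'   appended, one row per annotation.
#' @export
pocket_at_site <- function(pocket, sites, min_shared = 1) {
  stopifnot(is.data.frame(sites), "residues" %in% names(sites))
  res <- purrr::map(sites$residues,
                    ~ pocket_overlap(pocket, .x, min_shared))
  dplyr::bind_cols(sites, dplyr::bind_rows(res))
}

#' Read ligand/cofactor/catalytic site annotations from TSV
#'
#' Expects columns `structure_id`, `site_kind` (`ligand`, `cofactor` or
#' `catalytic`), `ligand_code` (3-letter HET code; empty only for
#' catalytic sites) and `residues` (semicolon-joined `chain:resnum`
#' tokens).
#'
#' @param path TSV file path.
#' @return A tibble with a `residues` list-column.
#' @export
read_site_annotations <- function(path) {
  sites <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             ligand_code = readr::col_character()
                           ))
  need <- c("structure_id", "site_kind", "ligand_code", "residues")
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0) {
    stop("site table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sites$ligand_code[is.na(sites$ligand_code)] <- ""
  bad <- sites$ligand_code == "" & sites$site_kind != "catalytic"
  if (any(bad)) {
    stop("empty ligand_code is only permitted for catalytic sites (row ",
         which(bad)[1], ")", call. = FALSE)
  }
  sites$residues <- strsplit(as.character(sites$residues), ";", fixed = TRUE)
  if (any(lengths(sites$residues) == 0)) {
    stop("site annotations must list at least one residue", call. = FALSE)
  }
  tibble::as_tibble(sites)
}
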