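#' Read MM/GBSA snapshot energy tables from TSV
#'
#' Expects columns `system_id`, `snapshot`, `role` (`complex`, `protein`
#' or `peptide`), the energy terms `e_bnd`, `e_el`, `e_vdw`, `g_pol`,
#' `g_np` in kcal/mol and optionally `ts` (the entropy term, usually
#' absent).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_energy_tsv <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("system_id", "snapshot", "role",
            "e_bnd", "e_el", "e_vdw", "g_pol", "g_np")
  missing <- setdiff(need, names(e))
  if (length(missing) > 0) {
    stop("energy table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(e)
}

#' Read per-residue decomposition tables from TSV
#'
#' Expects columns `system_id`, `chain_role` (`protein` or `peptide`),
#' `res_name`, `res_index` and `dg_contrib` (kcal/mol).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_decomposition_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("system_id", "chain_role", "res_name", "res_index", "dg_contrib")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("decomposition table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Gibbs energy of one snapshot
#'
#' Sums the MM/GBSA terms of one species in one snapshot:
#' G = E_bnd + E_el + E_vdw + G_pol + G_np - TS. The entropy term TS is
#' usually omitted from the workflow and defaults to zero.
#'
#' @param energies Data frame with columns `e_bnd`, `e_el`, `e_vdw`,
#'   `g_pol`, `g_np` and optionally `ts` (NA treated as absent).
#' @return The input with a `g_total` column appended (kcal/mol).
#' @export
gibbs_sum <- function(energies) {
  stopifnot(is.data.frame(energies))
  need <- c("e_bnd", "e_el", "e_vdw", "g_pol", "g_np")
  stopifnot(all(need %in% names(energies)))
  terms <- as.matrix(energies[, need])
  if (any(!is.finite(terms))) {
    stop("non-finite energy term", call. = FALSE)
  }
  ts <- if ("ts" %in% names(energies)) {
    tsv <- energies$ts
    tsv[is.na(tsv)] <- 0
    if (any(!is.finite(tsv))) stop("non-finite entropy term", call. = FALSE)
    tsv
  } else {
    0
  }
  energies$g_total <- rowSums(terms) - ts
  tibble::as_tibble(energies)
}

#' MM/GBSA binding free energy from snapshot tables
#'
#' For each system and snapshot computes
#' Delta G = G_complex - G_protein - G_peptide and averages over
#' snapshots: `dg_bind` is the arithmetic mean, `dg_sd` the sample
#' standard deviation (n - 1 denominator; a single snapshot reports
#' `dg_sd = 0` with a warning).
#'
#' @param energies Snapshot energy tibble (see [read_energy_tsv()]);
#'   every `(system_id, snapshot)` must have all three roles.
#' @return A tibble with one row per system: `system_id`, `dg_bind`,
#'   `dg_sd`, `n_snapshots`.
#' @export
delta_g_bind <- function(energies) {
  stopifnot(is.data.frame(energies))
  energies <- gibbs_sum(energies)
  wide <- energies |>
    dplyr::select("system_id", "snapshot", "role", "g_total") |>
    tidyr::pivot_wider(names_from = "role", values_from = "g_total")
  for (role in c("complex", "protein", "peptide")) {
    if (!role %in% names(wide) || anyNA(wide[[role]])) {
      bad <- if (!role %in% names(wide)) wide$snapshot else
        wide$snapshot[is.na(wide[[role]])]
      stop(sprintf("snapshot %s lacks role '%s'", bad[1], role),
           call. = FALSE)
    }
  }
  per_snap <- wide |>
    dplyr::mutate(dg = .data$complex - .data$protein - .data$peptide)
  out <- per_snap |>
    dplyr::group_by(.data$system_id) |>
    dplyr::summarise(
      dg_bind = mean(.data$dg),
      dg_sd = if (dplyr::n() > 1) sd(.data$dg) else 0,
      n_snapshots = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_snapshots == 1)) {
    warning("system(s) with a single snapshot report dg_sd = 0",
            call. = FALSE)
  }
  out
}

#' Select residues with prominent binding contributions
#'
#' Within each system, finds the residue with the largest absolute
#' contribution to binding (stabilizing or destabilizing), sets the
#' threshold to `fraction` of that value, and returns every residue
#' whose absolute contribution meets the threshold (inclusive). The
#' screening default is 40 percent.
#'
#' @param contribs Per-residue contribution tibble (see
#'   [read_decomposition_tsv()]).
#' @param fraction Fraction of the maximal absolute contribution
#'   (default 0.4).
#' @return The selected subset of `contribs`, with a `threshold` column.
#' @export
select_prominent <- function(contribs, fraction = 0.4) {
  stopifnot(is.data.frame(contribs), "dg_contrib" %in% names(contribs))
  if (nrow(contribs) == 0) stop("empty contribution table", call. = FALSE)
  stopifnot(fraction >= 0, fraction <= 1)
  out <- contribs |>
    dplyr::group_by(.data$system_id) |>
    dplyr::mutate(threshold = fraction * max(abs(.data$dg_contrib))) |>
    dplyr::ungroup()
  degenerate <- unique(out$system_id[out$threshold == 0 &
                                       abs(out$dg_contrib) == 0])
  all_zero <- out |>
    dplyr::group_by(.data$system_id) |>
    dplyr::summarise(zero = all(.data$dg_contrib == 0), .groups = "drop")
  if (any(all_zero$zero)) {
    warning("system(s) with all-zero contributions yield empty selections: ",
            paste(all_zero$system_id[all_zero$zero], collapse = ", "),
            call. = FALSE)
    out <- out[!(out$system_id %in% all_zero$system_id[all_zero$zero]), ,
               drop = FALSE]
  }
  out[abs(out$dg_contrib) >= out$threshold - 1e-12, , drop = FALSE]
}

#' Positional class of a peptide residue
#'
#' @param res_index 1-based residue index (vectorized).
#' @param peptide_length Peptide length in residues.
#' @return `"N-terminal"`, `"C-terminal"` or `"internal"`.
#' @export
position_class <- function(res_index, peptide_length) {
  if (any(res_index < 1 | res_index > peptide_length)) {
    stop("res_index out of 1..peptide_length", call. = FALSE)
  }
  dplyr::case_when(
    res_index == 1 ~ "N-terminal",
    res_index == peptide_length ~ "C-terminal",
    TRUE ~ "internal"
  )
}

#' Cross-system summary of prominent residue contributions
#'
#' Counts appearances and averages the binding contribution of each
#' amino-acid type, separately for protein- and peptide-side residues,
#' and additionally by peptide positional class (N-terminal, internal,
#' C-terminal) when a `position_class` column is present.
#'
#' @param selected Selected contributions from [select_prominent()];
#'   for the positional table add a `position_class` column (see
#'   [position_class()]).
#' @return A list of class `pep_contribution_summary` with tibbles
#'   `by_residue` (chain_role, res_name, n, mean_dg) and `by_position`
#'   (res_name, position_class, n, mean_dg; peptide side only, `NULL`
#'   when no positional classes are available).
#' @export
contribution_summary <- function(selected) {
  stopifnot(is.data.frame(selected),
            all(c("chain_role", "res_name", "dg_contrib") %in% names(selected)))
  if (nrow(selected) == 0) stop("no selected residues", call. = FALSE)
  by_residue <- selected |>
    dplyr::group_by(.data$chain_role, .data$res_name) |>
    dplyr::summarise(n = dplyr::n(), mean_dg = mean(.data$dg_contrib),
                     .groups = "drop")
  by_position <- NULL
  if ("position_class" %in% names(selected)) {
    pep <- selected[selected$chain_role == "peptide" &
                      !is.na(selected$position_class), , drop = FALSE]
    if (nrow(pep) > 0) {
      by_position <- pep |>
        dplyr::group_by(.data$res_name, .data$position_class) |>
        dplyr::summarise(n = dplyr::n(), mean_dg = mean(.data$dg_contrib),
                         .groups = "drop")
    }
  }
  structure(list(by_residue = by_residue, by_position = by_position),
            class = "pep_contribution_summary")
}

#' @export
print.pep_contribution_summary <- function(x, ...) {
  cat("Prominent residue contributions\n\nBy residue type and chain role:\n")
  print(x$by_residue)
  if (!is.null(x$by_position)) {
    cat("\nPeptide residues by position class:\n")
    print(x$by_position)
  }
  invisible(x)
}
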