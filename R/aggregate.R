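#' Dataset-level summary of interaction profiles
#'
#' Aggregates per-complex interaction profiles (and optionally binding
#' free energies) into the statistics used to characterize a cohort of
#' docked protein-peptide pairs: mean and sample SD of contact,
#' hydrophobic-contact and hydrogen-bond counts; the pooled fraction of
#' hydrogen bonds donated by the protein; the partition of systems into
#' salt-bridge-only, pi-pi-only, both and neither, with conditional mean
#' counts over the systems possessing each interaction; peptide atom
#' participation statistics; and the fraction of systems with negative
#' binding free energy.
#'
#' @param profiles A tibble with one row per system, as produced by
#'   [interaction_profile()] (rows may be bound together) or
#'   [make_cohort()].
#' @param energies Optional tibble from [delta_g_bind()] with a
#'   `dg_bind` column.
#' @return An object of class `pep_dataset_summary`; see [tidy()] and
#'   [glance()] methods.
#' @export
aggregate_profiles <- function(profiles, energies = NULL) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) == 0) stop("no profiles to aggregate", call. = FALSE)
  p <- tibble::as_tibble(profiles)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0

  counts <- tibble::tibble(
    kind = c("close_contacts", "hydrophobic", "hbonds"),
    mean = c(mean(p$n_close_contacts), mean(p$n_hydrophobic),
             mean(p$n_hbonds)),
    sd = c(sd0(p$n_close_contacts), sd0(p$n_hydrophobic), sd0(p$n_hbonds))
  )

  system_category <- dplyr::case_when(
    p$has_salt_bridge & p$has_pipi ~ "both",
    p$has_salt_bridge ~ "salt_bridge_only",
    p$has_pipi ~ "pipi_only",
    TRUE ~ "neither"
  )
  cats <- c("salt_bridge_only", "pipi_only", "both", "neither")
  categories <- tibble::tibble(
    category = cats,
    fraction = purrr::map_dbl(cats, ~ mean(system_category == .x))
  )
  with_sb <- p$n_salt_bridges[p$has_salt_bridge]
  with_pp <- p$n_pipi[p$has_pipi]

  donor_frac <- if (all(is.na(p$frac_donor_protein))) NA_real_ else {
    ok <- !is.na(p$frac_donor_protein) & p$n_hbonds > 0
    sum(p$frac_donor_protein[ok] * p$n_hbonds[ok]) / sum(p$n_hbonds[ok])
  }

  dg <- NULL
  if (!is.null(energies)) {
    stopifnot(is.data.frame(energies), "dg_bind" %in% names(energies))
    dg <- list(
      n_systems = nrow(energies),
      n_negative = sum(energies$dg_bind < 0),
      frac_negative = mean(energies$dg_bind < 0),
      mean_dg = mean(energies$dg_bind),
      sd_dg = sd0(energies$dg_bind)
    )
  }

  structure(list(
    n_systems = nrow(p),
    counts = counts,
    frac_donor_protein = donor_frac,
    categories = categories,
    mean_bridges_when_present = if (length(with_sb) > 0) mean(with_sb) else NA_real_,
    sd_bridges_when_present = if (length(with_sb) > 0) sd0(with_sb) else NA_real_,
    mean_pipi_when_present = if (length(with_pp) > 0) mean(with_pp) else NA_real_,
    sd_pipi_when_present = if (length(with_pp) > 0) sd0(with_pp) else NA_real_,
    mean_frac_sc_in_contacts = mean(p$frac_sc_in_contacts, na.rm = TRUE),
    mean_frac_bb_in_contacts = mean(p$frac_bb_in_contacts, na.rm = TRUE),
    mean_contacts_per_sc_atom = mean(p$contacts_per_sc_atom, na.rm = TRUE),
    mean_contacts_per_bb_atom = mean(p$contacts_per_bb_atom, na.rm = TRUE),
    mean_unique_sc_bb_ratio = mean(p$unique_sc_bb_ratio, na.rm = TRUE),
    mean_overall_sc_bb_ratio = mean(p$overall_sc_bb_ratio, na.rm = TRUE),
    dg = dg
  ), class = "pep_dataset_summary")
}

#' @export
print.pep_dataset_summary <- function(x, ...) {
  cat(sprintf("Dataset summary over %d systems\n", x$n_systems))
  for (k in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-16s %6.1f +/- %.1f per system\n",
                x$counts$kind[k], x$counts$mean[k], x$counts$sd[k]))
  }
  if (!is.na(x$frac_donor_protein)) {
    cat(sprintf("  H-bond donors on protein: %.1f%%\n",
                100 * x$frac_donor_protein))
  }
  for (k in seq_len(nrow(x$categories))) {
    cat(sprintf("  %-16s %5.1f%%\n", x$categories$category[k],
                100 * x$categories$fraction[k]))
  }
  if (!is.null(x$dg)) {
    cat(sprintf("  negative dG_bind: %d / %d systems (%.1f%%)\n",
                x$dg$n_negative, x$dg$n_systems, 100 * x$dg$frac_negative))
  }
  invisible(x)
}

#' Tidy a dataset summary into a long statistic table
#'
#' @param x A `pep_dataset_summary`.
#' @param ... Unused.
#' @return A tibble with columns `statistic` and `value`.
#' @export
tidy.pep_dataset_summary <- function(x, ...) {
  rows <- list(
    tibble::tibble(statistic = "n_systems", value = x$n_systems),
    tibble::tibble(statistic = paste0("mean_", x$counts$kind),
                   value = x$counts$mean),
    tibble::tibble(statistic = paste0("sd_", x$counts$kind),
                   value = x$counts$sd),
    tibble::tibble(statistic = "frac_donor_protein",
                   value = x$frac_donor_protein),
    tibble::tibble(statistic = paste0("frac_", x$categories$category),
                   value = x$categories$fraction),
    tibble::tibble(
      statistic = c("mean_bridges_when_present", "sd_bridges_when_present",
                    "mean_pipi_when_present", "sd_pipi_when_present",
                    "mean_frac_sc_in_contacts", "mean_frac_bb_in_contacts",
                    "mean_contacts_per_sc_atom", "mean_contacts_per_bb_atom",
                    "mean_unique_sc_bb_ratio", "mean_overall_sc_bb_ratio"),
      value = c(x$mean_bridges_when_present, x$sd_bridges_when_present,
                x$mean_pipi_when_present, x$sd_pipi_when_present,
                x$mean_frac_sc_in_contacts, x$mean_frac_bb_in_contacts,
                x$mean_contacts_per_sc_atom, x$mean_contacts_per_bb_atom,
                x$mean_unique_sc_bb_ratio, x$mean_overall_sc_bb_ratio)
    )
  )
  if (!is.null(x$dg)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      statistic = c("n_negative_dg", "frac_negative_dg", "mean_dg", "sd_dg"),
      value = c(x$dg$n_negative, x$dg$frac_negative, x$dg$mean_dg, x$dg$sd_dg)
    )
  }
  dplyr::bind_rows(rows)
}

#' One-row overview of a dataset summary
#'
#' @param x A `pep_dataset_summary`.
#' @param ... Unused.
#' @return A one-row wide tibble.
#' @export
glance.pep_dataset_summary <- function(x, ...) {
  long <- tidy(x)
  tidyr::pivot_wider(long, names_from = "statistic", values_from = "value")
}

#' Write a dataset summary as JSON
#'
#' @param x A `pep_dataset_summary`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  long <- tidy(x)
  jsonlite::write_json(as.list(setNames(long$value, long$statistic)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
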