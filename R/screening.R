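#' Benjamini-Hochberg adjustment of screening p-values
#'
#' Applies the step-up Benjamini-Hochberg procedure to raw binding-site
#' p-values: sort ascending, multiply p_(i) by m/i, enforce monotonicity
#' by a cumulative minimum from the largest rank, cap at 1, and restore
#' input order. Ties are handled stably and the result is
#' permutation-equivariant.
#'
#' @param p Numeric vector of raw p-values, all in (0, 1].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Read binding-site screening hits from TSV
#'
#' Expects columns `fragment_id`, `structure_id`, `chain`, `p_raw` and
#' `pocket`, the pocket being a semicolon-joined list of
#' `chain:resnum` tokens (e.g. `"A:10;A:11;B:40"`).
#'
#' @param path TSV file path.
#' @return A tibble with a list-column `pocket` of character vectors.
#' @export
read_screening_tsv <- function(path) {
  hits <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("fragment_id", "structure_id", "chain", "p_raw", "pocket")
  missing <- setdiff(need, names(hits))
  if (length(missing) > 0) {
    stop("screening table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  hits$pocket <- strsplit(as.character(hits$pocket), ";", fixed = TRUE)
  tibble::as_tibble(hits)
}

#' Adjust and filter screening hits at an FDR cutoff
#'
#' Adds BH-adjusted p-values to a screening table and flags the hits
#' retained at the given false-discovery-rate cutoff (`p_adj <= cutoff`,
#' inclusive). Input order is preserved.
#'
#' @param hits Data frame with a `p_raw` column.
#' @param cutoff FDR cutoff; the screening default is 0.25.
#' @param keep_all Return all rows with a `retained` flag (default), or
#'   only the retained rows (`keep_all = FALSE`).
#' @return The input tibble with `p_adj` and `retained` columns.
#' @export
filter_fdr <- function(hits, cutoff = 0.25, keep_all = TRUE) {
  stopifnot(is.data.frame(hits), "p_raw" %in% names(hits))
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) {
    hits$p_adj <- numeric(0)
    hits$retained <- logical(0)
    return(hits)
  }
  if (!"p_adj" %in% names(hits)) hits$p_adj <- bh_adjust(hits$p_raw)
  hits$retained <- hits$p_adj <= cutoff
  if (!keep_all) hits <- hits[hits$retained, , drop = FALSE]
  hits
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pocket consistency across peptides bound to one structure
#'
#' Tests whether different peptides predicted to bind one protein
#' structure target the same pocket. Pockets (residue sets) are clustered
#' greedily in input order: each hit joins the first existing cluster
#' whose representative (its first member) it matches at Jaccard
#' similarity >= `jaccard_min`, otherwise it starts a new cluster. Hits
#' in the largest cluster count as binding the "same" pocket; on a size
#' tie the earliest cluster wins.
#'
#' @param hits Data frame with a `pocket` list-column of residue-token
#'   character vectors (as from [read_screening_tsv()]); all rows must
#'   concern one structure.
#' @param jaccard_min Minimum Jaccard similarity to call two pockets the
#'   same (default 0.5).
#' @return A one-row tibble with `n_hits`, `n_same_pocket`,
#'   `n_different_pocket`, `frac_same_pocket`.
#' @export
pocket_consistency <- function(hits, jaccard_min = 0.5) {
  stopifnot(is.data.frame(hits), "pocket" %in% names(hits))
  pockets <- hits$pocket
  if (length(pockets) < 2) {
    stop("need at least 2 hits on the structure", call. = FALSE)
  }
  if ("structure_id" %in% names(hits) &&
      length(unique(hits$structure_id)) > 1) {
    stop("all hits must share one structure_id", call. = FALSE)
  }
  reps <- list()
  assignment <- integer(length(pockets))
  for (i in seq_along(pockets)) {
    matched <- 0L
    for (j in seq_along(reps)) {
      if (jaccard(pockets[[i]], reps[[j]]) >= jaccard_min) {
        matched <- j
        break
      }
    }
    if (matched == 0L) {
      reps[[length(reps) + 1L]] <- pockets[[i]]
      matched <- length(reps)
    }
    assignment[i] <- matched
  }
  sizes <- tabulate(assignment)
  n_same <- max(sizes)
  tibble::tibble(
    n_hits             = length(pockets),
    n_same_pocket      = n_same,
    n_different_pocket = length(pockets) - n_same,
    frac_same_pocket   = n_same / length(pockets)
  )
}
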