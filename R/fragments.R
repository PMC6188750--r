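#' Read stress-induced peptide (SIP) sequences from FASTA
#'
#' Reads a multi-record amino-acid FASTA file into a tidy table. Every
#' sequence is validated against the 20 standard one-letter codes; records
#' carrying ambiguity codes or other non-standard letters abort with an
#' error naming the offending position.
#'
#' @param path Path to a FASTA file of peptide sequences.
#' @return A tibble with columns `id` (FASTA header up to first
#'   whitespace) and `sequence`.
#' @export
read_sip_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- unname(as.character(aa))
  for (i in seq_along(seqs)) {
    tryCatch(
      check_aa_sequence(seqs[i]),
      error = function(e) {
        stop(sprintf("record '%s': %s", ids[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  tibble::tibble(id = ids, sequence = toupper(seqs))
}

#' Sliding-window k-mer fragment library
#'
#' Enumerates every contiguous fragment of each parent peptide for lengths
#' `kmin` to `kmax` at step 1, the way short binding-site screens fragment
#' a peptide catalogue before docking. For a parent of length L and a
#' given k this yields `max(0, L - k + 1)` fragments; fragments are
#' ordered by parent, then k, then start. Duplicate fragment sequences are
#' retained by default because each carries distinct provenance
#' (parent and offset); set `dedup = TRUE` to collapse the library to
#' unique sequences (first occurrence kept).
#'
#' @param sips A data frame with columns `id` and `sequence`
#'   (as from [read_sip_fasta()]), or a single character sequence.
#' @param kmin,kmax Integer fragment length range (inclusive); the
#'   screening default is 4 to 10 residues.
#' @param dedup Collapse to unique fragment sequences (default `FALSE`).
#' @return A tibble with columns `parent_id`, `start` (0-based offset),
#'   `k`, `sequence`.
#' @examples
#' generate_fragments("LAEDTFGEIS")            # 28 fragments, k = 4..10
#' @export
generate_fragments <- function(sips, kmin = 4L, kmax = 10L, dedup = FALSE) {
  if (is.character(sips)) {
    sips <- tibble::tibble(
      id = if (!is.null(names(sips))) names(sips) else paste0("seq", seq_along(sips)),
      sequence = sips
    )
  }
  stopifnot(is.data.frame(sips), all(c("id", "sequence") %in% names(sips)))
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  if (!(kmin >= 1 && kmin <= kmax)) {
    stop("need 1 <= kmin <= kmax", call. = FALSE)
  }
  frags <- purrr::pmap(list(sips$id, sips$sequence), function(id, seq) {
    seq <- check_aa_sequence(seq)
    L <- nchar(seq)
    ks <- seq.int(kmin, kmax)
    ks <- ks[ks <= L]
    if (length(ks) == 0) return(NULL)
    purrr::map(ks, function(k) {
      starts <- 0:(L - k)
      tibble::tibble(
        parent_id = id,
        start     = starts,
        k         = k,
        sequence  = substring(seq, starts + 1, starts + k)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (isTRUE(dedup) && nrow(frags) > 0) {
    frags <- dplyr::distinct(frags, .data$sequence, .keep_all = TRUE)
  }
  frags
}

#' Descriptor table for a fragment library
#'
#' Joins per-fragment hydropathy descriptors onto a fragment table.
#'
#' @param fragments A tibble from [generate_fragments()].
#' @return The input with `gravy`, `klass`, `n_charged`, `n_aromatic`
#'   columns appended.
#' @export
fragment_descriptors <- function(fragments) {
  stopifnot(is.data.frame(fragments), "sequence" %in% names(fragments))
  desc <- gravy(fragments$sequence)
  dplyr::bind_cols(fragments, desc[, c("gravy", "klass", "n_charged", "n_aromatic")])
}

#' Hydropathy and composition summary of a fragment library
#'
#' Reports the fraction of hydrophilic and hydrophobic fragments (by
#' GRAVY class) and the residue-level fractions of charged and aromatic
#' amino acids pooled over all fragments.
#'
#' @param fragments A tibble with a `sequence` column
#'   (descriptors are computed if absent).
#' @return A one-row tibble with columns `n_fragments`,
#'   `frac_hydrophilic`, `frac_hydrophobic`, `frac_charged_residues`,
#'   `frac_aromatic_residues`.
#' @export
library_summary <- function(fragments) {
  stopifnot(is.data.frame(fragments))
  if (nrow(fragments) == 0) stop("empty fragment collection", call. = FALSE)
  if (!all(c("gravy", "klass", "n_charged", "n_aromatic") %in% names(fragments))) {
    fragments <- fragment_descriptors(fragments)
  }
  n_res <- sum(nchar(fragments$sequence))
  tibble::tibble(
    n_fragments            = nrow(fragments),
    frac_hydrophilic       = mean(fragments$klass == "hydrophilic"),
    frac_hydrophobic       = mean(fragments$klass == "hydrophobic"),
    frac_charged_residues  = sum(fragments$n_charged) / n_res,
    frac_aromatic_residues = sum(fragments$n_aromatic) / n_res
  )
}

#' Write a fragment descriptor table as TSV
#'
#' @param fragments Fragment tibble (descriptors added if missing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragment_tsv <- function(fragments, path) {
  if (!all(c("gravy", "klass") %in% names(fragments))) {
    fragments <- fragment_descriptors(fragments)
  }
  readr::write_tsv(fragments, path)
  invisible(path)
}
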