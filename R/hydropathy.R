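#' Kyte-Doolittle hydropathy scale
#'
#' The published 20-residue hydropathy scale of Kyte & Doolittle (1982),
#' J Mol Biol 157:105-132. Values are dimensionless; positive means
#' hydrophobic. Ranges from -4.5 (Arg) to +4.5 (Ile).
#'
#' @format Named numeric vector of length 20, names are one-letter
#'   amino-acid codes.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# residue-class sets used throughout; His is deliberately in both
CHARGED_AA  <- c("R", "K", "H", "D", "E")
AROMATIC_AA <- c("H", "F", "Y", "W")

#' Validate an amino-acid sequence
#'
#' Checks that a sequence uses only the 20 standard one-letter codes.
#' Ambiguity codes (B, Z, X), selenocysteine (U) and stop characters are
#' rejected rather than silently remapped.
#'
#' @param sequence Character scalar, one-letter amino-acid codes.
#' @param allow_empty Allow the empty string (default `FALSE`).
#' @return The validated sequence (uppercased), invisibly usable.
#' @keywords internal
check_aa_sequence <- function(sequence, allow_empty = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop("`sequence` must be a single non-NA character string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (!allow_empty && !nzchar(sequence)) {
    stop("`sequence` must be non-empty", call. = FALSE)
  }
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!letters %in% names(kyte_doolittle))
  if (length(bad) > 0) {
    stop(
      sprintf(
        "non-standard residue letter '%s' at position %d",
        letters[bad[1]], bad[1]
      ),
      call. = FALSE
    )
  }
  sequence
}

#' Grand average of hydropathy (GRAVY)
#'
#' Computes the mean Kyte-Doolittle hydropathy over each sequence, a
#' hydrophobicity class, and counts of charged (Arg, Lys, His, Asp, Glu)
#' and aromatic (His, Phe, Tyr, Trp) residues. Sequences with GRAVY
#' strictly above zero are classed hydrophobic; zero or below is
#' hydrophilic.
#'
#' @param sequence Character vector of amino-acid sequences (standard
#'   one-letter codes only).
#' @return A tibble with one row per sequence and columns `sequence`,
#'   `gravy`, `klass` (`"hydrophobic"` or `"hydrophilic"`), `n_charged`,
#'   `n_aromatic`.
#' @examples
#' gravy("LAEDTFGEIS")
#' @export
gravy <- function(sequence) {
  if (length(sequence) == 0) stop("`sequence` must be non-empty", call. = FALSE)
  rows <- purrr::map(sequence, function(s) {
    s <- check_aa_sequence(s)
    letters <- strsplit(s, "")[[1]]
    g <- mean(kyte_doolittle[letters])
    tibble::tibble(
      sequence   = s,
      gravy      = g,
      klass      = if (g > 0) "hydrophobic" else "hydrophilic",
      n_charged  = sum(letters %in% CHARGED_AA),
      n_aromatic = sum(letters %in% AROMATIC_AA)
    )
  })
  dplyr::bind_rows(rows)
}
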