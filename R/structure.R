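# atom names classed as backbone; OXT and amide/N-terminal hydrogens included
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3")

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "SPC")
ION_RESIDUES   <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "FE2",
                    "CU", "NI", "CO", "CD", "BR", "IOD", "CS", "LI", "SR")

#' Euclidean distance between points
#'
#' Distance D(A,B) = sqrt((x1-x2)^2 + (y1-y2)^2 + (z1-z2)^2) between 3-D
#' coordinates in Angstrom, the primitive under every interface criterion
#' in the package.
#'
#' @param a,b Numeric 3-vectors, or matrices with 3 columns (row-wise
#'   distances are returned).
#' @return Numeric distance(s) in Angstrom.
#' @examples
#' euclid(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclid <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3, byrow = TRUE)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  d <- a - b
  sqrt(rowSums(d * d))
}

element_from_name <- function(name) {
  core <- sub("^[0-9]+", "", name)
  first <- substr(core, 1, 1)
  ifelse(first == "H" | grepl("^[0-9]*H", name), "H", first)
}

resolve_altloc <- function(atoms) {
  if (all(is.na(atoms$altloc) | atoms$altloc %in% c("", " "))) return(atoms)
  atoms |>
    dplyr::group_by(.data$chain, .data$resnum, .data$ins, .data$residue,
                    .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial)
}

check_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (nchar(ln) < 54 || anyNA(coords)) {
      stop(sprintf("malformed ATOM/HETATM record at line %d", i),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Assign receptor/peptide roles on an atom table
#'
#' Labels each atom `"peptide"` if it belongs to the designated peptide
#' chain and `"receptor"` otherwise. Both roles must be non-empty and the
#' peptide chain must not double as a receptor chain.
#'
#' @param atoms Atom tibble (as from [read_complex()]).
#' @param peptide_chain Single chain identifier of the docked peptide.
#' @return The atom tibble with a `role` column.
#' @export
set_roles <- function(atoms, peptide_chain) {
  stopifnot(is.data.frame(atoms), "chain" %in% names(atoms))
  chains <- unique(atoms$chain)
  if (!peptide_chain %in% chains) {
    stop(sprintf("peptide chain '%s' not found; available chains: %s",
                 peptide_chain, paste(sort(chains), collapse = ", ")),
         call. = FALSE)
  }
  if (length(chains) < 2) {
    stop("complex must contain at least one receptor chain besides the peptide",
         call. = FALSE)
  }
  atoms$role <- ifelse(atoms$chain == peptide_chain, "peptide", "receptor")
  atoms
}

#' Read a docked protein-peptide complex from PDB
#'
#' Parses ATOM/HETATM records of the first model into a tidy atom table
#' and labels receptor versus peptide atoms. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken
#' alphabetically); waters and monoatomic ions are always dropped; other
#' HETATM groups are dropped unless `keep_het = TRUE`.
#'
#' @param path PDB file path.
#' @param peptide_chain Chain identifier of the docked peptide.
#' @param keep_het Retain non-water, non-ion HETATM groups
#'   (default `FALSE`).
#' @return A tibble with one row per atom: `serial`, `name`, `element`,
#'   `residue`, `chain`, `resnum`, `ins`, `x`, `y`, `z`, `occupancy`,
#'   `is_backbone`, `is_hydrogen`, `is_het`, `role`.
#' @export
read_complex <- function(path, peptide_chain, keep_het = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  check_pdb_lines(lines)
  # keep only the first MODEL of multi-model files
  if (any(grepl("^ENDMDL", lines))) {
    lines <- lines[seq_len(which(grepl("^ENDMDL", lines))[1])]
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(lines, tmp)
    path <- tmp
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  atoms <- tibble::tibble(
    serial    = at$eleno,
    name      = at$elety,
    altloc    = at$alt,
    residue   = at$resid,
    chain     = ifelse(is.na(at$chain), " ", at$chain),
    resnum    = at$resno,
    ins       = ifelse(is.na(at$insert), "", at$insert),
    x         = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element   = ifelse(is.na(at$elesy) | at$elesy %in% c("", " "),
                       element_from_name(at$elety), toupper(at$elesy)),
    is_het    = at$type == "HETATM"
  )
  atoms <- resolve_altloc(atoms)
  atoms <- atoms[!(atoms$residue %in% WATER_RESIDUES), , drop = FALSE]
  atoms <- atoms[!(atoms$is_het & atoms$residue %in% ION_RESIDUES), , drop = FALSE]
  if (!keep_het) atoms <- atoms[!atoms$is_het, , drop = FALSE]
  atoms$altloc <- NULL
  atoms$is_hydrogen <- atoms$element == "H"
  atoms$is_backbone <- atoms$name %in% BACKBONE_ATOMS
  set_roles(atoms, peptide_chain)
}

#' Write an atom table as fixed-column PDB
#'
#' @param atoms Atom tibble (as from [read_complex()] or
#'   [build_peptide()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "residue", "chain", "resnum", "x", "y", "z")
                %in% names(atoms)))
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = if ("is_het" %in% names(atoms))
      ifelse(atoms$is_het, "HETATM", "ATOM") else rep("ATOM", nrow(atoms)),
    resno = atoms$resnum,
    resid = atoms$residue,
    eleno = if ("serial" %in% names(atoms)) atoms$serial else seq_len(nrow(atoms)),
    elety = atoms$name,
    chain = atoms$chain,
    insert = if ("ins" %in% names(atoms))
      ifelse(atoms$ins == "", NA, atoms$ins) else rep(NA, nrow(atoms)),
    o = if ("occupancy" %in% names(atoms)) atoms$occupancy else rep(1, nrow(atoms)),
    b = rep(0, nrow(atoms)),
    elesy = if ("element" %in% names(atoms)) atoms$element else
      element_from_name(atoms$name)
  )
  invisible(path)
}

#' Side-chain versus backbone atom bookkeeping
#'
#' Counts side-chain and backbone atoms per role, both over all resolved
#' atoms and over heavy atoms only, and reports the side-chain:backbone
#' ratio for each. Which atom census applies to a docked model depends on
#' whether it was protonated, so both are always returned.
#'
#' @param atoms Atom tibble with `role`, `is_backbone`, `is_hydrogen`.
#' @return A tibble with columns `role`, `atom_class`, `n_all`, `n_heavy`
#'   plus per-role ratio rows (`atom_class == "ratio_sc_bb"` carries the
#'   side-chain/backbone ratios in `n_all`/`n_heavy` as numeric ratios).
#' @export
classify_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("role", "is_backbone", "is_hydrogen") %in% names(atoms)))
  counts <- atoms |>
    dplyr::mutate(atom_class = ifelse(.data$is_backbone, "backbone", "side_chain")) |>
    dplyr::group_by(.data$role, .data$atom_class) |>
    dplyr::summarise(
      n_all   = dplyr::n(),
      n_heavy = sum(!.data$is_hydrogen),
      .groups = "drop"
    ) |>
    tidyr::complete(
      role = unique(atoms$role),
      atom_class = c("backbone", "side_chain"),
      fill = list(n_all = 0L, n_heavy = 0L)
    )
  ratios <- counts |>
    tidyr::pivot_wider(names_from = "atom_class",
                       values_from = c("n_all", "n_heavy")) |>
    dplyr::transmute(
      role = .data$role,
      atom_class = "ratio_sc_bb",
      n_all   = .data$n_all_side_chain / .data$n_all_backbone,
      n_heavy = .data$n_heavy_side_chain / .data$n_heavy_backbone
    )
  dplyr::bind_rows(
    dplyr::mutate(counts, n_all = as.numeric(.data$n_all),
                  n_heavy = as.numeric(.data$n_heavy)),
    ratios
  ) |> dplyr::arrange(.data$role, .data$atom_class)
}
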