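# ideal backbone geometry (Engh-Huber-style): bond lengths in Angstrom,
# angles in degrees
IDEAL_GEOMETRY <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.0, ang_ca_c_n = 117.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, ang_n_ca_cb = 110.4
)

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-10) return(NULL)
  v / n
}

# natural-extension-reference-frame placement: position D given A, B, C,
# the bond length |C-D|, the angle B-C-D and the torsion A-B-C-D
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  theta <- deg2rad(angle_deg)
  chi <- deg2rad(torsion_deg)
  d2 <- c(-bond * cos(theta),
          bond * cos(chi) * sin(theta),
          bond * sin(chi) * sin(theta))
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  if (is.null(bc) || is.null(n)) {
    stop("degenerate reference frame for atom placement", call. = FALSE)
  }
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(c + m %*% d2)
}

#' Torsion angle of four points
#'
#' Signed dihedral (IUPAC convention) in degrees for the atom path
#' A-B-C-D. Returns `NA` for degenerate (collinear) geometry.
#'
#' @param a,b,c,d Numeric 3-vectors.
#' @return Angle in degrees in (-180, 180], or `NA`.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-8 || sqrt(sum(n2^2)) < 1e-8) return(NA_real_)
  u2 <- unit3(b2)
  rad2deg(atan2(sum(cross3(n1, n2) * u2), sum(n1 * n2)))
}

angle3 <- function(a, b, c) {
  u <- unit3(a - b); v <- unit3(c - b)
  rad2deg(acos(pmin(1, pmax(-1, sum(u * v)))))
}

#' Idealized backbone conformer specifications
#'
#' The three canonical backbone dihedral sets used to seed peptide
#' docking: alpha-helical (phi = -57, psi = -47), extended
#' (phi = -139, psi = -135) and polyproline (phi = -78, psi = 149),
#' all with trans peptide bonds (omega = 180).
#'
#' @param name One of `"alpha"`, `"extended"`, `"polyproline"`, or
#'   `"custom"` with explicit angles.
#' @param phi,psi,omega Backbone dihedrals in degrees (required for
#'   `"custom"`, otherwise the canonical defaults are used).
#' @return A list with elements `name`, `phi`, `psi`, `omega`.
#' @export
conformer_spec <- function(name = c("alpha", "extended", "polyproline", "custom"),
                           phi = NULL, psi = NULL, omega = 180) {
  name <- match.arg(name)
  defaults <- list(
    alpha       = c(phi = -57, psi = -47),
    extended    = c(phi = -139, psi = -135),
    polyproline = c(phi = -78, psi = 149)
  )
  if (name == "custom") {
    if (is.null(phi) || is.null(psi)) {
      stop("custom conformer needs explicit `phi` and `psi`", call. = FALSE)
    }
  } else {
    if (is.null(phi)) phi <- defaults[[name]][["phi"]]
    if (is.null(psi)) psi <- defaults[[name]][["psi"]]
  }
  list(name = name, phi = phi, psi = psi, omega = omega)
}

#' Build an idealized peptide model
#'
#' Constructs a single-chain peptide with backbone atoms N, CA, C, O at
#' ideal bond lengths and angles and uniform backbone dihedrals, plus a
#' CB atom at ideal tetrahedral geometry for every residue except
#' glycine. Side chains beyond CB are not built; docking engines
#' rebuild them. The chain id is `"P"` and residues are numbered from 1.
#'
#' @param sequence Amino-acid sequence (2 to 50 residues, standard
#'   one-letter codes).
#' @param conformer A conformer name understood by [conformer_spec()] or
#'   a spec list returned by it.
#' @return An atom tibble compatible with [write_pdb()] and the
#'   interaction detectors (role column set to `"peptide"`).
#' @examples
#' pep <- build_peptide("LAEDTFGEIS", "alpha")
#' measure_dihedrals(pep)
#' @export
build_peptide <- function(sequence, conformer = "alpha") {
  sequence <- check_aa_sequence(sequence)
  n <- nchar(sequence)
  if (n < 2) stop("peptide must have at least 2 residues", call. = FALSE)
  if (n > 50) stop("peptide length is capped at 50 residues", call. = FALSE)
  spec <- if (is.character(conformer)) conformer_spec(conformer) else conformer
  g <- IDEAL_GEOMETRY
  letters <- strsplit(sequence, "")[[1]]

  N <- CA <- CC <- vector("list", n)
  # first residue seeded in the xy-plane
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  CC[[1]] <- CA[[1]] + g$ca_c * c(cos(deg2rad(180 - g$ang_n_ca_c)),
                                  sin(deg2rad(180 - g$ang_n_ca_c)), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], CC[[i - 1]],
                         g$c_n, g$ang_ca_c_n, spec$psi)
    CA[[i]] <- place_atom(CA[[i - 1]], CC[[i - 1]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, spec$omega)
    CC[[i]] <- place_atom(CC[[i - 1]], N[[i]], CA[[i]],
                          g$ca_c, g$ang_n_ca_c, spec$phi)
  }

  rows <- list()
  serial <- 0L
  add <- function(rows, name, element, resnum, residue, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      serial = serial, name = name, element = element, residue = residue,
      chain = "P", resnum = resnum, ins = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, is_het = FALSE
    )
    rows
  }
  for (i in seq_len(n)) {
    res3 <- AA3[[letters[i]]]
    rows <- add(rows, "N", "N", i, res3, N[[i]])
    rows <- add(rows, "CA", "C", i, res3, CA[[i]])
    rows <- add(rows, "C", "C", i, res3, CC[[i]])
    # carbonyl O opposite the next amide nitrogen along the psi torsion
    O <- place_atom(N[[i]], CA[[i]], CC[[i]], g$c_o, g$ang_ca_c_o,
                    spec$psi + 180)
    rows <- add(rows, "O", "O", i, res3, O)
    if (letters[i] != "G") {
      # CB on the bisector frame of N-CA-C, out of plane for L-chirality
      u <- unit3(N[[i]] - CA[[i]]); v <- unit3(CC[[i]] - CA[[i]])
      bis <- unit3(u + v); nrm <- unit3(cross3(v, u))
      a <- -cos(deg2rad(g$ang_n_ca_cb)) / sum(bis * u)
      b <- sqrt(max(0, 1 - a^2))
      CB <- CA[[i]] + g$ca_cb * (-a * bis + b * nrm)
      rows <- add(rows, "CB", "C", i, res3, CB)
    }
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$is_hydrogen <- atoms$element == "H"
  atoms$is_backbone <- atoms$name %in% BACKBONE_ATOMS
  atoms$role <- "peptide"
  atoms
}

#' Measure backbone dihedrals of a model
#'
#' Computes phi, psi and omega per residue for a chain with N, CA, C
#' backbone atoms, using the standard IUPAC sign convention. The first
#' residue has undefined phi, the last has undefined psi and omega;
#' residues with missing backbone atoms (or degenerate, collinear
#' geometry) yield `NA` rather than failing.
#'
#' @param atoms Atom tibble; if more than one chain is present, pass
#'   `chain` to select one.
#' @param chain Chain identifier (defaults to the only chain present).
#' @return A tibble with columns `chain`, `resnum`, `residue`, `phi`,
#'   `psi`, `omega` in degrees.
#' @export
measure_dihedrals <- function(atoms, chain = NULL) {
  stopifnot(is.data.frame(atoms))
  if (is.null(chain)) {
    chains <- unique(atoms$chain)
    if (length(chains) > 1) {
      stop("multiple chains present; pass `chain`", call. = FALSE)
    }
    chain <- chains
  }
  at <- atoms[atoms$chain == chain, , drop = FALSE]
  resnums <- unique(at$resnum)
  get_atom <- function(resnum, name) {
    row <- at[at$resnum == resnum & at$name == name, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  n <- length(resnums)
  out <- purrr::map(seq_len(n), function(i) {
    r <- resnums[i]
    Np <- get_atom(r, "N"); CAp <- get_atom(r, "CA"); Cp <- get_atom(r, "C")
    resname <- at$residue[at$resnum == r][1]
    phi <- psi <- omega <- NA_real_
    if (!is.null(Np) && !is.null(CAp) && !is.null(Cp)) {
      if (i > 1) {
        Cprev <- get_atom(resnums[i - 1], "C")
        if (!is.null(Cprev)) phi <- dihedral(Cprev, Np, CAp, Cp)
      }
      if (i < n) {
        Nnext <- get_atom(resnums[i + 1], "N")
        CAnext <- get_atom(resnums[i + 1], "CA")
        if (!is.null(Nnext)) psi <- dihedral(Np, CAp, Cp, Nnext)
        if (!is.null(Nnext) && !is.null(CAnext)) {
          omega <- dihedral(CAp, Cp, Nnext, CAnext)
        }
      }
    }
    tibble::tibble(chain = chain, resnum = r, residue = resname,
                   phi = phi, psi = psi, omega = omega)
  })
  dplyr::bind_rows(out)
}

#' Mean axial rise per residue of a helical model
#'
#' Estimates the per-residue translation along the helix axis from the
#' screw transformation that maps each residue's backbone onto the next:
#' the N/CA/C atoms of residues 1..(n-1) are superposed onto residues
#' 2..n (Kabsch), and the rise is the component of the residual
#' translation along the rotation axis. Unlike a principal-component fit
#' of the CA cloud, this is unbiased for short helices. A canonical
#' alpha-helix rises about 1.5 Angstrom per residue.
#'
#' @param atoms Atom tibble of a single-chain model.
#' @return Mean rise per residue in Angstrom.
#' @export
helix_rise <- function(atoms) {
  bb <- atoms[atoms$name %in% c("N", "CA", "C"), , drop = FALSE]
  resnums <- unique(bb$resnum)
  if (length(resnums) < 3) stop("need at least 3 residues", call. = FALSE)
  a <- as.matrix(bb[bb$resnum %in% resnums[-length(resnums)], c("x", "y", "z")])
  b <- as.matrix(bb[bb$resnum %in% resnums[-1], c("x", "y", "z")])
  ca <- colMeans(a); cb <- colMeans(b)
  s <- svd(t(sweep(a, 2, ca)) %*% sweep(b, 2, cb))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  ev <- eigen(rot)
  axis <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
  trans <- cb - as.numeric(rot %*% ca)
  abs(sum(trans * axis))
}
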