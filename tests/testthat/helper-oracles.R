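# Independent oracles and fixture builders. These deliberately avoid the
# package's grid/step-up code paths: contacts by an all-pairs distance
# scan, BH by an explicit step-up loop, interfaces by an all-pairs CA
# scan.

oracle_pairs <- function(A, B, cutoff, strict = FALSE) {
  d2 <- outer(A[, 1], B[, 1], "-")^2 +
    outer(A[, 2], B[, 2], "-")^2 +
    outer(A[, 3], B[, 3], "-")^2
  hit <- if (strict) d2 < cutoff^2 else d2 <= cutoff^2 + 1e-9
  idx <- which(hit, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    q[i] <- min(prev, sorted[i] * m / i, 1)
    prev <- q[i]
  }
  adj <- numeric(m)
  adj[o] <- q
  adj
}

# interface-residue key set from an oracle pair index matrix
# (paste() would recycle a scalar against zero-length input, so guard)
iface_keys <- function(idx) {
  if (nrow(idx) == 0) return(character(0))
  union(paste("A", idx[, 1]), paste("B", idx[, 2]))
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3")

# minimal atom-table builder for hand-made fixtures
mk_atoms <- function(name, element, chain, resnum, x, y, z,
                     residue = "GLY", peptide_chain = "P") {
  atoms <- tibble::tibble(
    serial = seq_along(name), name = name, element = element,
    residue = rep_len(residue, length(name)), chain = chain,
    resnum = resnum, ins = "", x = x, y = y, z = z, occupancy = 1,
    is_het = FALSE,
    is_hydrogen = element == "H",
    is_backbone = name %in% BACKBONE_NAMES
  )
  atoms$role <- ifelse(atoms$chain == peptide_chain, "peptide", "receptor")
  atoms
}

# a single cross-role atom pair at distance d (plus two distant padding
# atoms so both roles stay non-trivial)
mk_pair <- function(d, name_a = "CA", elem_a = "C",
                    name_b = "CA", elem_b = "C") {
  mk_atoms(
    name = c(name_a, "O", name_b, "O"),
    element = c(elem_a, "O", elem_b, "O"),
    chain = c("A", "A", "P", "P"),
    resnum = c(1L, 2L, 1L, 2L),
    x = c(0, -30, d, d + 30), y = 0, z = 0
  )
}

random_atom_cloud <- function(n_rec, n_pep, box = 15) {
  mk_atoms(
    name = rep("CA", n_rec + n_pep),
    element = sample(c("C", "N", "O"), n_rec + n_pep, replace = TRUE),
    chain = rep(c("A", "P"), c(n_rec, n_pep)),
    resnum = seq_len(n_rec + n_pep),
    x = runif(n_rec + n_pep, 0, box),
    y = runif(n_rec + n_pep, 0, box),
    z = runif(n_rec + n_pep, 0, box)
  )
}

angdiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
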