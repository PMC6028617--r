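# Shared fixture builders: tiny hand-written PDB records, rigid transforms,
# a uniform toy rate model, and brute-force oracles kept deliberately
# independent of the implementation they check.

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = "", icode = "", elem = "C",
                          record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, icode,
          x, y, z, occ, 0, elem)
}

write_pdb_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# three-atom single-residue fixture
ala_fixture <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0,    0, 0, elem = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.0,  1.3, 0)))
}

rigid_transform <- function(M, angle = 0.7, axis = c(0, 0, 1),
                            shift = c(3, -7, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(as.matrix(M) %*% t(R), 2, shift, "+")
}

transform_structure <- function(st, ...) {
  st$atoms[, c("x", "y", "z")] <-
    rigid_transform(st$atoms[, c("x", "y", "z")], ...)
  st
}

# single-atom carbon structure at the origin
carbon_structure <- function(xyz = rbind(c(0, 0, 0)), elem = "C") {
  n <- nrow(xyz)
  atoms <- data.frame(
    chain = "A", resno = seq_len(n), insert = "", resid = "ALA",
    elety = "CA", element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, radius = unname(vdw_radii()[elem]), sidechain = FALSE,
    stringsAsFactors = FALSE)
  structure(list(id = "toy", atoms = atoms, metadata = list()),
            class = "halo_structure")
}

# exchangeability-uniform model (all rates equal, uniform frequencies):
# posterior ties become exact, handy for tie-break tests
uniform_model <- function() {
  S <- matrix(1, 20, 20)
  rate_model(S, rep(1 / 20, 20), name = "uniform")
}

# Brute-force global alignment score: enumerates every monotone alignment
# path and charges each gap run open + len * ext (checked against the same
# convention the aligner uses). Exponential; only for length <= 5.
brute_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, state) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, sc + mat[a[i], b[j]], "m")
    if (i <= length(a))
      rec(i + 1, j, sc - (if (state == "da") ext else open + ext), "da")
    if (j <= length(b))
      rec(i, j + 1, sc - (if (state == "db") ext else open + ext), "db")
  }
  rec(1, 1, 0, "m")
  best
}
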