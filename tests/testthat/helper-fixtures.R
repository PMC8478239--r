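# In-code PDB fixtures: fixed-column ATOM/HETATM records built with sprintf.

pdb_line <- function(type, eleno, elety, resid, chain, resno, x, y, z,
                     o = 1.00, b = 20.00, elesy = "C", alt = "") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, elety, alt, resid, chain, resno, x, y, z, o, b, elesy)
}

write_pdb_fixture <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

# three ALA residues with CA atoms at known positions/B-factors, a glycerol
# het group (6 heavy atoms: C1-C3 one per residue's z-plane, oxygens far),
# and a water. Nearest ligand distances: res1 4.9 (CA-C1), res2 5.1
# (CA-C2), res3 exactly 5.0 (CA-C3).
fixture_basic <- function() {
  lines <- c(
    pdb_line("ATOM", 1, "N",  "ALA", "A", 1, 4.9, 0.8, 0),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 4.9, 0.0, 0, b = 20.5),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 5.9, 0.0, 0),
    pdb_line("ATOM", 4, "CA", "ALA", "A", 2, 5.1, 0.0, 30, b = 10.0),
    pdb_line("ATOM", 5, "CA", "ALA", "A", 3, 0.0, 5.0, 60, b = 30.0),
    pdb_line("HETATM", 6, "C1", "GOL", "A", 101, 0, 0, 0, b = 25),
    pdb_line("HETATM", 7, "C2", "GOL", "A", 101, 0, 0, 30, b = 25),
    pdb_line("HETATM", 8, "C3", "GOL", "A", 101, 0, 0, 60, b = 25),
    pdb_line("HETATM", 9, "O1", "GOL", "A", 101, 50, 2, 0, b = 25,
             elesy = "O"),
    pdb_line("HETATM", 10, "O2", "GOL", "A", 101, 50, 3, 0, b = 25,
             elesy = "O"),
    pdb_line("HETATM", 11, "O3", "GOL", "A", 101, 50, 4, 0, b = 25,
             elesy = "O"),
    pdb_line("HETATM", 12, "O", "HOH", "A", 201, 2, 0, 0, b = 30,
             elesy = "O"))
  write_pdb_fixture(lines)
}

# residue 2 distance ladder to GOL C1 at origin, plus altloc pair on res 1:
# altloc A occupancy 0.4 at x=1, altloc B occupancy 0.6 at x=2.
fixture_altloc <- function(occ_a = 0.4, occ_b = 0.6) {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 1, 0, 0, o = occ_a, b = 11,
             alt = "A"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 2, 0, 0, o = occ_b, b = 22,
             alt = "B"),
    pdb_line("ATOM", 3, "CA", "ALA", "A", 2, 9, 0, 0))
  write_pdb_fixture(lines)
}

# two chains, same residue numbering
fixture_two_chains <- function() {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, b = 1),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 4, 0, 0, b = 2),
    pdb_line("ATOM", 3, "CA", "LEU", "B", 1, 0, 9, 0, b = 3),
    pdb_line("ATOM", 4, "CA", "LEU", "B", 2, 4, 9, 0, b = 4))
  write_pdb_fixture(lines)
}

# two residues, five atoms each, placed so that exactly `n_close` atom pairs
# lie within 4.5 A: paired atoms are dy apart (dy = 4.4 by default, so only
# same-index pairs qualify: sqrt(1 + 4.4^2) = 4.51 > 4.5); resno gap
# controls the sequence-separation filter.
fixture_pair_contact <- function(n_close = 5, resno2 = 3, dy = 4.4) {
  mk <- function(eleno, resno, xs, y) {
    nm <- c("CA", "CB", "CG", "CD", "CE")
    vapply(seq_along(xs), function(k)
      pdb_line("ATOM", eleno + k - 1, nm[k], "ALA", "A", resno,
               xs[k], y, 0), "")
  }
  xs1 <- c(0, 1, 2, 3, 4)
  xs2 <- c(0, 1, 2, 3, 4)
  if (n_close < 5) xs2[(n_close + 1):5] <- 100 + xs2[(n_close + 1):5]
  write_pdb_fixture(c(mk(1, 1, xs1, 0), mk(6, resno2, xs2, dy)))
}

# synthetic PSI-BLAST ASCII PSSM with the two-matrix layout and a trailing
# statistics block; scores are pos * 100 + column index.
fixture_pssm <- function(n_pos = 3, truncate_row = NA) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  hdr <- paste0("            ",
                paste(sprintf("%3s", c(aa, aa)), collapse = " "))
  rows <- vapply(seq_len(n_pos), function(p) {
    sc <- p * 100 + 1:20
    pct <- rep(5, 20)
    paste0(sprintf("%5d %s  ", p, aa[p]),
           paste(sprintf("%4d", c(sc, pct)), collapse = " "),
           "  0.36 0.12")
  }, "")
  if (!is.na(truncate_row))
    rows[truncate_row] <- substr(rows[truncate_row], 1, 40)
  lines <- c("", "Last position-specific scoring matrix computed",
             hdr, rows, "", "                      K         Lambda",
             "Standard Ungapped    0.1337     0.3113")
  tf <- tempfile(fileext = ".pssm")
  writeLines(lines, tf)
  tf
}

# local-topology oracle: aggregate a brute-force relation table into the
# per-residue counts, independently of localTopology()
oracle_local_topology <- function(cmap, relations, residue) {
  ct <- contactTable(cmap)
  own <- ct$i == residue | ct$j == residue
  zero <- c(series = 0L, parallel = 0L, inverse_parallel = 0L, cross = 0L)
  if (!any(own) || nrow(relations) == 0) return(zero)
  own_key <- paste(ct$i[own], ct$j[own])
  rel <- relations[paste(relations$b_i, relations$b_j) %in% own_key &
                   !(paste(relations$a_i, relations$a_j) %in% own_key), ]
  cnt <- function(lab) length(unique(paste(rel$a_i, rel$a_j)[rel$relation == lab]))
  c(series = cnt("S"), parallel = cnt("P"),
    inverse_parallel = cnt("Pinv"), cross = cnt("X"))
}

structure_from_synthetic <- function(syn) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(syn$pdb_text, tf)
  readPDB(tf)
}
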