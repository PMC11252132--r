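# Fixtures built in code: small peptide structures with known geometry and
# an independent dihedral oracle.

# independent signed-dihedral oracle (projection/atan2 formulation kept
# deliberately different from the package's normal-vector implementation;
# IUPAC convention)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  b2n <- b2 / sqrt(sum(b2^2))
  v <- b0 - sum(b0 * b2n) * b2n
  w <- b3 - sum(b3 * b2n) * b2n
  x <- sum(v * w)
  y <- sum(pracma::cross(b2n, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# minimal pdb-like object from an atom table
as_pdb <- function(atom) {
  atom$type <- "ATOM"
  atom$alt <- atom$alt %||% ""
  atom$o <- atom$o %||% 1
  atom$insert <- ""
  atom$segid <- ""
  atom$charge <- ""
  list(atom = atom)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# extended-chain tripeptide (GLY-ALA-GLY) with backbone N/CA/C/O and B-factors;
# residue 2 can be made a proline
make_peptide <- function(pro2 = FALSE, bfactors = c(10, 30, 50)) {
  res <- function(i, x0, resid, b) {
    data.frame(
      elety = c("N", "CA", "C", "O"),
      resid = resid, chain = "A", resno = i,
      x = x0 + c(0.0, 1.46, 2.0, 1.9),
      y = c(0.0, 0.2, 1.5, 2.6),
      z = c(0.0, 1.2, 1.4, 1.5),
      b = b, elesy = c("N", "C", "C", "O"),
      stringsAsFactors = FALSE)
  }
  atom <- rbind(res(1, 0, "GLY", bfactors[1]),
                res(2, 3.6, if (pro2) "PRO" else "ALA", bfactors[2]),
                res(3, 7.2, "GLY", bfactors[3]))
  as_pdb(atom)
}

# TRP residue with a CD1 placed at a chosen chi2 (and the chi1 atoms fixed)
make_trp <- function(chi2 = 80, resno = 580) {
  N <- c(0, 0, 0); CA <- c(1.46, 0, 0); CB <- c(2.0, 1.0, 1.0)
  CG <- spindyn:::place_atom(N, CA, CB, 1.5, 114, -60)
  CD1 <- spindyn:::place_atom(CA, CB, CG, 1.4, 127, chi2)
  as_pdb(data.frame(
    elety = c("N", "CA", "CB", "CG", "CD1"),
    resid = "TRP", chain = "A", resno = resno,
    x = c(N[1], CA[1], CB[1], CG[1], CD1[1]),
    y = c(N[2], CA[2], CB[2], CG[2], CD1[2]),
    z = c(N[3], CA[3], CB[3], CG[3], CD1[3]),
    b = 20, elesy = "C", stringsAsFactors = FALSE))
}

# write a small PDB text file (for load_structure tests)
write_pdb_text <- function(pdb, path, altloc = NULL, occ = NULL) {
  a <- pdb$atom
  alt <- altloc %||% rep(" ", nrow(a))
  o <- occ %||% rep(1, nrow(a))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(a)),
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
    alt, a$resid, a$chain, a$resno, a$x, a$y, a$z, o, a$b)
  writeLines(c(lines, "END"), path)
  path
}

# ratios data.frame from a synthetic dataset's rate table
ratios_from_table <- function(tab, floor_sigma = 1e-4) {
  r <- tab$r2 / tab$r1
  s <- r * sqrt((tab$r1_sigma / tab$r1)^2 + (tab$r2_sigma / tab$r2)^2)
  data.frame(residue = tab$residue, ratio = r,
             sigma = pmax(s, floor_sigma))
}
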