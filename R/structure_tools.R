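# Geometry extraction from coordinate files (NH vectors, B-factors,
# dihedrals, methyl contacts) and structure-based tumbling predictors.
# PDB parsing and writing go through bio3d; everything downstream works on
# plain data.frames of atoms.

#' Load a structure from a PDB file
#'
#' Single-model files yield a `StructureModel` (a bio3d `pdb` object with
#' altloc filtering applied: for each atom the highest-occupancy conformer
#' is kept). Multi-model files should be read with [load_ensemble()].
#'
#' @param path PDB file.
#' @return a bio3d `pdb` object.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE)
  if (nrow(pdb$atom) == 0) stop("no atoms in ", path)
  pdb <- filter_altloc(pdb)
  if (!any(pdb$atom$resid %in% bio3d::aa.table$aa3))
    stop("no protein atoms in ", path)
  pdb
}

# keep, per (chain, resno, insert, elety), the highest-occupancy altloc
filter_altloc <- function(pdb) {
  a <- pdb$atom
  if (all(is.na(a$alt) | a$alt == "")) return(pdb)
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  occ <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(key, -occ)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  pdb$atom <- a[keep, , drop = FALSE]
  pdb$xyz <- as.vector(t(as.matrix(pdb$atom[, c("x", "y", "z")])))
  pdb$xyz <- bio3d::as.xyz(matrix(pdb$xyz, nrow = 1))
  pdb
}

#' Place amide hydrogens geometrically
#'
#' For every non-proline residue with backbone N, CA and a preceding-residue
#' C, an amide H is placed in the C(i-1)-N-CA plane along the external
#' bisector of the two bonds at N-H = 1.02 Angstrom. Prolines and chain
#' N-termini are skipped. A purely geometric rule; deviations from
#' heuristic proton builders are a few degrees and are absorbed by the
#' tensor-fit errors.
#'
#' @param pdb a `pdb` object from [load_structure()].
#' @param rNH N-H bond length (Angstrom).
#' @return the `pdb` with `H` atom rows appended (element H, B-factor of N).
#' @export
place_amide_hydrogens <- function(pdb, rNH = 1.02) {
  a <- pdb$atom
  newrows <- list()
  for (ch in unique(a$chain)) {
    ca <- a[a$chain %in% ch, ]
    resnos <- sort(unique(ca$resno))
    for (i in seq_along(resnos)[-1]) {
      rn <- resnos[i]
      res <- ca[ca$resno == rn, ]
      if (res$resid[1] == "PRO") next
      if (any(res$elety == "H")) next
      prev <- ca[ca$resno == resnos[i - 1], ]
      N <- res[res$elety == "N", c("x", "y", "z")]
      CA <- res[res$elety == "CA", c("x", "y", "z")]
      C <- prev[prev$elety == "C", c("x", "y", "z")]
      if (nrow(N) != 1 || nrow(CA) != 1 || nrow(C) != 1) next
      N <- as.numeric(N); CA <- as.numeric(CA); C <- as.numeric(C)
      u1 <- (N - C) / sqrt(sum((N - C)^2))
      u2 <- (N - CA) / sqrt(sum((N - CA)^2))
      bis <- u1 + u2
      bis <- bis / sqrt(sum(bis^2))
      H <- N + rNH * bis
      row <- res[res$elety == "N", , drop = FALSE]
      row$elety <- "H"; row$elesy <- "H"
      row$x <- H[1]; row$y <- H[2]; row$z <- H[3]
      newrows[[length(newrows) + 1]] <- row
    }
  }
  if (length(newrows) > 0) {
    add <- do.call(rbind, newrows)
    a <- rbind(a, add)
    a <- a[order(match(a$chain, unique(a$chain)), a$resno), ]
    rownames(a) <- NULL
    pdb$atom <- a
    pdb$xyz <- bio3d::as.xyz(matrix(
      as.vector(t(as.matrix(a[, c("x", "y", "z")]))), nrow = 1))
  }
  pdb
}

#' Per-residue N-H unit vectors and backbone-N B-factors
#'
#' @param pdb a `pdb` with amide hydrogens present (see
#'   [place_amide_hydrogens()]).
#' @return data.frame (`SpinGeometry`): `residue`, `chain`, `ux`,`uy`,`uz`
#'   (unit vector N to H, NA when no H), `bfactor` (backbone N), `flag`
#'   (`"ok"`, `"proline"` or `"missing"`).
#' @export
nh_vectors <- function(pdb) {
  a <- pdb$atom
  ns <- a[a$elety == "N", ]
  out <- data.frame(residue = ns$resno, chain = ns$chain,
                    ux = NA_real_, uy = NA_real_, uz = NA_real_,
                    bfactor = ns$b, flag = "missing",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ns))) {
    sel <- a$chain == ns$chain[i] & a$resno == ns$resno[i]
    if (a$resid[sel][1] == "PRO") { out$flag[i] <- "proline"; next }
    h <- a[sel & a$elety == "H", ]
    if (nrow(h) != 1) next
    v <- c(h$x - ns$x[i], h$y - ns$y[i], h$z - ns$z[i])
    v <- v / sqrt(sum(v^2))
    out[i, c("ux", "uy", "uz")] <- v
    out$flag[i] <- "ok"
  }
  out
}

#' Backbone nitrogen B-factor statistics
#'
#' @param pdb a `pdb` object.
#' @return list with `count`, `mean` and `median` over backbone N atoms.
#' @export
backbone_bfactor_stats <- function(pdb) {
  b <- pdb$atom$b[pdb$atom$elety == "N"]
  if (length(b) == 0) stop("no backbone N atoms")
  list(count = length(b), mean = mean(b), median = stats::median(b))
}

# side-chain atom names defining chi1 / chi2 per the IUPAC convention
.chi_defs <- list(
  `1` = list(c("N"), c("CA"), c("CB"),
             c("CG", "CG1", "OG", "OG1", "SG")),
  `2` = list(c("CA"), c("CB"), c("CG", "CG1"),
             c("CD", "CD1", "OD1", "ND1", "SD"))
)

#' Side-chain dihedral angle
#'
#' Signed chi1 (N-CA-CB-CG) or chi2 (CA-CB-CG-CD1) dihedral in degrees,
#' in (-180, 180].
#'
#' @param pdb a `pdb` object (or one model of an ensemble).
#' @param residue residue number (author numbering).
#' @param index 1 or 2 for chi1/chi2.
#' @param chain optional chain id.
#' @return angle in degrees.
#' @export
chi_angle <- function(pdb, residue, index = 2, chain = NULL) {
  def <- .chi_defs[[as.character(index)]]
  if (is.null(def)) stop("'index' must be 1 or 2")
  a <- pdb$atom
  sel <- a$resno == residue
  if (!is.null(chain)) sel <- sel & a$chain == chain
  res <- a[sel, ]
  pts <- lapply(def, function(names) {
    hit <- res[res$elety %in% names, , drop = FALSE]
    if (nrow(hit) == 0)
      stop("residue ", residue, " lacks atom(s) ",
           paste(names, collapse = "/"))
    as.numeric(hit[1, c("x", "y", "z")])
  })
  dihedral4(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Distance between two C-alpha atoms
#'
#' @param pdb a `pdb` object.
#' @param res_a,res_b residue numbers.
#' @return Euclidean distance in Angstrom.
#' @export
ca_distance <- function(pdb, res_a, res_b) {
  a <- pdb$atom
  pa <- a[a$resno == res_a & a$elety == "CA", c("x", "y", "z")]
  pb <- a[a$resno == res_b & a$elety == "CA", c("x", "y", "z")]
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("missing CA atom")
  sqrt(sum((as.numeric(pa[1, ]) - as.numeric(pb[1, ]))^2))
}

# methyl carbons of Ile/Leu/Val
.methyl_atoms <- list(ILE = c("CD1", "CG2"), LEU = c("CD1", "CD2"),
                      VAL = c("CG1", "CG2"))

#' Methyl-methyl contact map for ILV residues
#'
#' All pairs of Ile/Leu/Val methyl carbons (Ile CD1/CG2, Leu CD1/CD2,
#' Val CG1/CG2) of distinct residues within a distance cutoff, labelled
#' intra- or inter-domain relative to a domain boundary residue.
#'
#' @param pdb a `pdb` object.
#' @param cutoff carbon-carbon distance cutoff (Angstrom).
#' @param boundary last residue of the first domain (default 574).
#' @return data.frame: residues, atom names, `distance`, `label`
#'   (`"intra"`/`"inter"`).
#' @export
methyl_contact_map <- function(pdb, cutoff = 7, boundary = 574) {
  a <- pdb$atom
  keep <- mapply(function(resid, elety)
    resid %in% names(.methyl_atoms) && elety %in% .methyl_atoms[[resid]],
    a$resid, a$elety)
  m <- a[keep, , drop = FALSE]
  out <- list()
  if (nrow(m) >= 2) {
    xyz <- as.matrix(m[, c("x", "y", "z")])
    dmat <- as.matrix(stats::dist(xyz))
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      if (m$resno[i] == m$resno[j]) next
      if (dmat[i, j] > cutoff) next
      lab <- if ((m$resno[i] <= boundary) == (m$resno[j] <= boundary))
        "intra" else "inter"
      out[[length(out) + 1]] <- data.frame(
        res_a = m$resno[i], atom_a = m$elety[i],
        res_b = m$resno[j], atom_b = m$elety[j],
        distance = dmat[i, j], label = lab, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(res_a = integer(), atom_a = character(),
                      res_b = integer(), atom_b = character(),
                      distance = numeric(), label = character()))
  do.call(rbind, out)
}

#' Bead-model rotational diffusion tensor
#'
#' Rigid-body hydrodynamics of identical spherical beads placed at the
#' C-alpha positions, with pairwise hydrodynamic interaction at the
#' Rotne-Prager-Yamakawa level and the standard rotational volume
#' correction. The 3N x 3N mobility matrix is inverted to a friction
#' matrix, assembled into the 6 x 6 rigid-body resistance, and the
#' rotational diffusion block is obtained from its Schur complement
#' (origin-independent). The tensor is symmetrized and axially reduced:
#' the eigenvalue most separated from the other two defines the symmetry
#' axis. Only the anisotropy and axis orientation are shape-determined;
#' the absolute scale depends on the bead radius and solvent viscosity.
#'
#' @param pdb a `pdb` object (C-alpha atoms are used), or an n x 3 matrix
#'   of bead coordinates (Angstrom).
#' @param bead_radius bead radius (Angstrom, default 5).
#' @param viscosity solvent viscosity (Pa s, default water at 298 K).
#' @param temperature temperature (K).
#' @return a [diffusion_tensor()] with an extra field `eigenvalues`
#'   (full 3-eigenvalue set, s^-1).
#' @export
bead_model_tensor <- function(pdb, bead_radius = 5,
                              viscosity = 8.9e-4, temperature = 298) {
  xyz <- if (is.matrix(pdb)) pdb else {
    a <- pdb$atom
    as.matrix(a[a$elety == "CA", c("x", "y", "z")])
  }
  n <- nrow(xyz)
  if (n < 3) stop("need at least 3 beads")
  xyz <- sweep(xyz, 2, colMeans(xyz)) * 1e-10       # metres, centred
  a0 <- bead_radius * 1e-10
  eta <- viscosity
  # span check
  if (min(svd(xyz)$d) < 1e-16 && n == 3) stop("degenerate (collinear) geometry")
  M <- matrix(0, 3 * n, 3 * n)
  I3 <- diag(3)
  self <- I3 / (6 * pi * eta * a0)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    M[ii, ii] <- self
    if (i < n) for (j in (i + 1):n) {
      jj <- (3 * j - 2):(3 * j)
      rij <- xyz[j, ] - xyz[i, ]
      r <- sqrt(sum(rij^2))
      rh <- rij / r
      P <- outer(rh, rh)
      blk <- if (r >= 2 * a0) {
        (1 / (8 * pi * eta * r)) *
          ((I3 + P) + (2 * a0^2 / r^2) * (I3 / 3 - P))
      } else {
        (1 / (6 * pi * eta * a0)) *
          ((1 - 9 * r / (32 * a0)) * I3 + (3 * r / (32 * a0)) * P)
      }
      M[ii, jj] <- blk
      M[jj, ii] <- blk
    }
  }
  zeta <- solve(M)
  skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1],
                               v[2], -v[1], 0), 3, 3)
  Xtt <- matrix(0, 3, 3); Xtr <- matrix(0, 3, 3); Xrr <- matrix(0, 3, 3)
  A <- lapply(seq_len(n), function(i) skew(xyz[i, ]))
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    for (j in seq_len(n)) {
      jj <- (3 * j - 2):(3 * j)
      zij <- zeta[ii, jj]
      Xtt <- Xtt + zij
      Xtr <- Xtr - zij %*% A[[j]]
      Xrr <- Xrr - A[[i]] %*% zij %*% A[[j]]
    }
  }
  # rotational volume correction (total bead volume)
  Xrr <- Xrr + diag(3) * 8 * pi * eta * a0^3 * n
  kB <- 1.380649e-23
  Drr <- kB * temperature * solve(Xrr - t(Xtr) %*% solve(Xtt) %*% Xtr)
  Drr <- (Drr + t(Drr)) / 2
  e <- eigen(Drr, symmetric = TRUE)
  d <- e$values                      # decreasing
  gap_top <- d[1] - d[2]; gap_bot <- d[2] - d[3]
  if (gap_top >= gap_bot) {
    Dpar <- d[1]; Dperp <- (d[2] + d[3]) / 2; ax <- e$vectors[, 1]
  } else {
    Dpar <- d[3]; Dperp <- (d[1] + d[2]) / 2; ax <- e$vectors[, 3]
  }
  if (ax[3] < 0) ax <- -ax
  beta <- acos(max(-1, min(1, ax[3]))) * 180 / pi
  alpha <- (atan2(ax[2], ax[1]) * 180 / pi) %% 360
  tens <- diffusion_tensor(Dperp, Dpar, alpha, beta)
  tens$eigenvalues <- d
  tens
}

#' Empirical correlation-time prediction from molecular weight
#'
#' Linear-in-mass rule `tauC = coefficient * MW * (eta_w(T)/eta_w(298)) *
#' (298/T)` with the temperature dependence of water viscosity. The default
#' coefficient (0.61 ns/kDa at 298 K) is an explicit calibration constant
#' for H6-tagged two-domain constructs in dilute aqueous buffer.
#'
#' @param molecular_weight kDa (> 0).
#' @param temperature K (physically sensible range 273-373).
#' @param coefficient ns per kDa at 298 K.
#' @return predicted tauC in ns.
#' @export
empirical_tauc <- function(molecular_weight, temperature = 298,
                           coefficient = 0.61) {
  if (any(molecular_weight < 0)) stop("molecular weight must be >= 0")
  if (temperature < 273 || temperature > 373)
    stop("non-physical temperature for aqueous buffer")
  visc <- function(T) 2.414e-5 * 10^(247.8 / (T - 140))
  coefficient * molecular_weight * (visc(temperature) / visc(298)) *
    (298 / temperature)
}
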