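# Stage 3: Cartesian PCA of conformational ensembles with domain-core
# superposition, extreme-structure reconstruction, rotamer-state clustering
# and per-residue confidence summaries.

#' Construct a conformational ensemble
#'
#' @param xyz M x 3N coordinate matrix (models in rows, Angstrom).
#' @param atom atom table shared by all models (data.frame with `elety`,
#'   `resid`, `resno`, `chain`, bio3d column conventions).
#' @param plddt optional M x n_residue matrix of per-residue confidence
#'   values in \[0, 100\] (columns named by residue number).
#' @param ptm optional per-model global score in \[0, 1\].
#' @return object of class `Ensemble`.
#' @export
new_ensemble <- function(xyz, atom, plddt = NULL, ptm = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2) stop("an ensemble needs at least 2 models")
  if (ncol(xyz) != 3 * nrow(atom))
    stop("coordinate width does not match the atom inventory")
  if (!is.null(plddt)) {
    if (any(plddt < 0 | plddt > 100, na.rm = TRUE))
      stop("confidence values must lie in [0, 100]")
    if (nrow(plddt) != nrow(xyz)) stop("plddt must have one row per model")
  }
  structure(list(xyz = xyz, atom = atom, plddt = plddt, ptm = ptm),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d models, %d atoms, %d residues%s\n",
              nrow(x$xyz), nrow(x$atom), length(unique(x$atom$resno)),
              if (is.null(x$plddt)) "" else ", with per-residue confidence"))
  invisible(x)
}

# one model as a minimal pdb-like object usable by chi_angle()/ca_distance()
ensemble_model <- function(ens, i) {
  a <- ens$atom
  co <- matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
  a$x <- co[, 1]; a$y <- co[, 2]; a$z <- co[, 3]
  list(atom = a)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Coordinates and the atom inventory are read with bio3d; when
#' `plddt_from_b = TRUE` the per-model B-factor column is additionally
#' parsed per residue (the structure-prediction convention of storing
#' pLDDT there), which bio3d's single atom table cannot carry.
#'
#' @param path multi-model PDB file.
#' @param plddt_from_b interpret B-factors as per-residue pLDDT.
#' @return an [new_ensemble()] object.
#' @export
load_ensemble <- function(path, plddt_from_b = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- unclass(pdb$xyz)
  if (nrow(xyz) < 2) stop(path, " does not contain a multi-model ensemble")
  plddt <- NULL
  if (plddt_from_b) {
    lines <- readLines(path)
    model_starts <- grep("^MODEL", lines)
    resnos <- unique(pdb$atom$resno)
    plddt <- matrix(NA_real_, nrow(xyz), length(resnos),
                    dimnames = list(NULL, resnos))
    bounds <- c(model_starts, length(lines) + 1L)
    for (m in seq_along(model_starts)) {
      blk <- lines[bounds[m]:(bounds[m + 1] - 1L)]
      at <- blk[grepl("^ATOM|^HETATM", blk)]
      rn <- as.integer(substr(at, 23, 26))
      bb <- as.numeric(substr(at, 61, 66))
      agg <- tapply(bb, rn, mean)
      plddt[m, match(names(agg), colnames(plddt))] <- agg
    }
  }
  new_ensemble(xyz, pdb$atom, plddt = plddt)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens an `Ensemble`; per-residue confidence, when present, is
#'   written into the B-factor column of each model.
#' @param path output file.
#' @export
write_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- ens$atom
  for (m in seq_len(nrow(ens$xyz))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    co <- matrix(ens$xyz[m, ], ncol = 3, byrow = TRUE)
    b <- if (!is.null(ens$plddt))
      ens$plddt[m, match(a$resno, colnames(ens$plddt))] else
        rep(0, nrow(a))
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)),
      ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
      a$resid, a$chain, a$resno, co[, 1], co[, 2], co[, 3], 1, b)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' PCA configuration
#'
#' @param align_ranges list of residue ranges (2-vectors) whose C-alpha
#'   atoms define the superposition core; defaults to the rigid
#'   paracaspase-core stretches 344-467, 484-500 and 510-562.
#' @param analysis_ranges residue ranges analysed. Combined with
#'   `analysis_atoms`: `"backbone"` keeps N, CA, C, O; `"heavy"` keeps all
#'   non-hydrogen atoms; `"calpha"` keeps CA only.
#' @param analysis_atoms see above.
#' @param sidechain_residues residues whose side-chain heavy atoms are
#'   added to a backbone selection (the multi-rotamer side chains).
#' @param ncomp number of principal components retained.
#' @return list of class `PCAConfig`.
#' @export
pca_config <- function(align_ranges = list(c(344, 467), c(484, 500),
                                           c(510, 562)),
                       analysis_ranges = list(c(344, 717)),
                       analysis_atoms = c("backbone", "heavy", "calpha"),
                       sidechain_residues = integer(0),
                       ncomp = 2) {
  structure(list(align_ranges = align_ranges,
                 analysis_ranges = analysis_ranges,
                 analysis_atoms = match.arg(analysis_atoms),
                 sidechain_residues = sidechain_residues,
                 ncomp = ncomp),
            class = "PCAConfig")
}

in_ranges <- function(resno, ranges) {
  hit <- rep(FALSE, length(resno))
  for (r in ranges) hit <- hit | (resno >= r[1] & resno <= r[2])
  hit
}

# atom-row indices of the analysis selection
analysis_indices <- function(atom, cfg) {
  sel <- in_ranges(atom$resno, cfg$analysis_ranges)
  sel <- sel & switch(cfg$analysis_atoms,
    backbone = atom$elety %in% c("N", "CA", "C", "O"),
    calpha = atom$elety == "CA",
    heavy = !grepl("^H", atom$elety))
  if (length(cfg$sidechain_residues) > 0)
    sel <- sel | (atom$resno %in% cfg$sidechain_residues &
                    !atom$elety %in% c("N", "CA", "C", "O") &
                    !grepl("^H", atom$elety))
  which(sel)
}

#' Superpose an ensemble onto its iteratively refined mean
#'
#' Least-squares rigid-body superposition of every model onto the mean
#' structure over the alignment C-alpha set, iterated to a fixed point
#' (at least two mean refinements), so the result is deterministic,
#' model-order independent and idempotent.
#'
#' @param ens an `Ensemble`.
#' @param cfg a [pca_config()]; only `align_ranges` is used.
#' @param tol convergence tolerance on the mean (Angstrom).
#' @return the aligned `Ensemble`.
#' @export
align_ensemble <- function(ens, cfg = pca_config(), tol = 1e-12) {
  a <- ens$atom
  core <- which(a$elety == "CA" & in_ranges(a$resno, cfg$align_ranges))
  if (length(core) < 3) stop("alignment selection has fewer than 3 CA atoms")
  M <- nrow(ens$xyz)
  coords <- lapply(seq_len(M), function(m)
    matrix(ens$xyz[m, ], ncol = 3, byrow = TRUE))
  ref <- coords[[1]][core, , drop = FALSE]
  for (it in 1:50) {
    coords <- lapply(coords, function(co)
      kabsch_apply(co[core, , drop = FALSE], ref, co))
    newref <- Reduce(`+`, lapply(coords, function(co) co[core, ])) / M
    delta <- max(abs(newref - ref))
    ref <- newref
    if (it >= 2 && delta < tol) break
  }
  # the fixed point is defined only up to a global rigid transform; put the
  # mean core into a canonical frame (centroid at origin, principal axes on
  # x/y/z with a deterministic sign convention) so the result is exactly
  # reproducible and idempotent
  cen <- colMeans(ref)
  ec <- eigen(stats::cov(sweep(ref, 2, cen)), symmetric = TRUE)
  R <- t(ec$vectors)
  for (i in 1:3) if (R[i, which.max(abs(R[i, ]))] < 0) R[i, ] <- -R[i, ]
  if (det(R) < 0) R[3, ] <- -R[3, ]
  coords <- lapply(coords, function(co) sweep(co, 2, cen) %*% t(R))
  ens$xyz <- do.call(rbind, lapply(coords, function(co) as.vector(t(co))))
  ens
}

#' Cartesian principal component analysis of an aligned ensemble
#'
#' Mean-centred covariance PCA (no mass weighting, no variance scaling) on
#' the flattened coordinates of the analysis selection.
#'
#' @param ens an aligned `Ensemble` (see [align_ensemble()]).
#' @param cfg a [pca_config()].
#' @return list of class `PCAResult`: `loadings` (3K x ncomp, orthonormal),
#'   `scores` (M x ncomp), `variance_fraction` (per retained component,
#'   relative to the total variance), `mean` (flattened mean coordinates),
#'   `atom_indices` (rows of the atom table analysed).
#' @export
run_pca <- function(ens, cfg = pca_config()) {
  idx <- analysis_indices(ens$atom, cfg)
  if (length(idx) == 0) stop("empty analysis selection")
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  X <- ens$xyz[, cols, drop = FALSE]
  M <- nrow(X)
  if (cfg$ncomp > M - 1)
    stop("fewer models than requested components")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(M - 1, ncol(Xc)))
  ev <- sv$d^2 / (M - 1)
  total <- sum(ev)
  k <- seq_len(cfg$ncomp)
  loadings <- sv$v[, k, drop = FALSE]
  structure(list(loadings = loadings,
                 scores = Xc %*% loadings,
                 variance_fraction = if (total > 0) ev[k] / total
                                     else rep(0, cfg$ncomp),
                 eigenvalues = ev,
                 mean = mu,
                 atom_indices = idx),
            class = "PCAResult")
}

#' Extreme structures along a principal component
#'
#' Inverse-transforms the minimal and maximal observed score on one
#' component back to Cartesian coordinates: `mean + score * loading`.
#'
#' @param result a [run_pca()] result.
#' @param component component index.
#' @return list with `low` and `high` (K x 3 coordinate matrices over the
#'   analysed atoms) and the two scores.
#' @export
pc_extreme_structures <- function(result, component = 1) {
  if (component < 1 || component > ncol(result$loadings))
    stop("invalid component index")
  s <- result$scores[, component]
  build <- function(sc) {
    v <- result$mean + sc * result$loadings[, component]
    matrix(v, ncol = 3, byrow = TRUE)
  }
  list(low = build(min(s)), high = build(max(s)),
       score_low = min(s), score_high = max(s))
}

# per-model side-chain dihedral across an ensemble
ensemble_chi <- function(ens, residue, index) {
  vapply(seq_len(nrow(ens$xyz)), function(m)
    chi_angle(ensemble_model(ens, m), residue, index), numeric(1))
}

# nearest-anchor classification on the circle (boundaries at circular
# midpoints of the two anchors)
classify_circular <- function(angles, anchor1, anchor2) {
  d1 <- abs(ang_diff(angles, anchor1))
  d2 <- abs(ang_diff(angles, anchor2))
  ifelse(d1 <= d2, 1L, 2L)
}

#' Assign rotamer states from two side-chain dihedrals
#'
#' Classifies every model by the circular proximity of two probe dihedrals
#' to fixed rotamer anchors, yielding four states:
#' I = (A at `anchors_a[1]`, B at `anchors_b[1]`),
#' II = (A1, B2), III = (A2, B1), IV = (A2, B2).
#' The defaults are the tryptophan chi2 outward/inward anchors (+80 /
#' -100 degrees) and the tyrosine chi1 anchors (-93 / +57 degrees); state
#' boundaries are the circular midpoints between anchors (fixed thresholds,
#' not data-driven clustering, for reproducibility).
#'
#' @param ens an `Ensemble`.
#' @param residue_a,chi_a probe A residue number and chi index (default
#'   chi2).
#' @param residue_b,chi_b probe B residue number and chi index (default
#'   chi1).
#' @param anchors_a,anchors_b two anchor angles (degrees) per probe.
#' @return list of class `StateAssignment`: `labels` (factor I-IV per
#'   model), `chi` (M x 2 matrix of angles), `populations` (named fractions
#'   summing to 1).
#' @export
assign_states <- function(ens, residue_a, chi_a = 2, residue_b, chi_b = 1,
                          anchors_a = c(80, -100),
                          anchors_b = c(-93, 57)) {
  xa <- ensemble_chi(ens, residue_a, chi_a)
  xb <- ensemble_chi(ens, residue_b, chi_b)
  ca <- classify_circular(xa, anchors_a[1], anchors_a[2])
  cb <- classify_circular(xb, anchors_b[1], anchors_b[2])
  lab <- factor(c("I", "II", "III", "IV")[2 * (ca - 1) + cb],
                levels = c("I", "II", "III", "IV"))
  pop <- table(lab) / length(lab)
  structure(list(labels = lab,
                 chi = cbind(chi_a = xa, chi_b = xb),
                 populations = c(pop)),
            class = "StateAssignment")
}

#' Per-residue confidence summaries
#'
#' @param ens an `Ensemble` carrying per-residue confidence values.
#' @param residues residue numbers (default: all with confidence values).
#' @return list with `summary` (data.frame residue, min, max, mean) and
#'   `per_model` (M x length(residues) matrix).
#' @export
plddt_summary <- function(ens, residues = NULL) {
  if (is.null(ens$plddt)) stop("ensemble carries no confidence values")
  all_res <- as.integer(colnames(ens$plddt))
  residues <- residues %||% all_res
  idx <- match(residues, all_res)
  if (anyNA(idx)) stop("no confidence values for residue(s) ",
                       paste(residues[is.na(idx)], collapse = ", "))
  vals <- ens$plddt[, idx, drop = FALSE]
  list(summary = data.frame(residue = residues,
                            min = apply(vals, 2, min),
                            max = apply(vals, 2, max),
                            mean = colMeans(vals)),
       per_model = vals)
}

#' Detect side chains with multi-modal chi2 distributions
#'
#' Helper for choosing the side-chain residues added to a backbone PCA
#' selection: a residue qualifies when its chi2 angles split into two
#' circular clusters each holding at least `min_fraction` of the models
#' and separated by more than `min_separation` degrees.
#'
#' @param ens an `Ensemble`.
#' @param residues candidate residues (must carry chi2 atoms in all models).
#' @param min_fraction minimal minor-cluster fraction.
#' @param min_separation minimal circular separation of cluster means
#'   (degrees).
#' @return residues flagged as multi-rotamer.
#' @export
detect_multirotamer <- function(ens, residues, min_fraction = 0.05,
                                min_separation = 60) {
  keep <- logical(length(residues))
  for (i in seq_along(residues)) {
    x <- tryCatch(ensemble_chi(ens, residues[i], 2), error = function(e) NULL)
    if (is.null(x)) next
    # 2-means on the circle via best split over candidate boundaries
    med <- atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
    dev <- ang_diff(x, med)
    cl <- dev > 0
    if (sum(cl) == 0 || sum(!cl) == 0) next
    m1 <- mean(dev[cl]); m2 <- mean(dev[!cl])
    frac <- min(mean(cl), 1 - mean(cl))
    keep[i] <- frac >= min_fraction && abs(m1 - m2) >= min_separation
  }
  residues[keep]
}
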