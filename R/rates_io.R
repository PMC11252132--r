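# Stage 1: turn measured peak-volume tables into per-residue rates with
# uncertainties, plus chemical-shift-perturbation mapping and table I/O.

#' Fit a mono-exponential decay
#'
#' Nonlinear least-squares fit of `A exp(-R t)` to a peak-volume decay
#' series; the rate uncertainty is taken from the covariance matrix of the
#' fit. Duplicate delays are legitimate and weighted as independent points.
#'
#' @param series data.frame with columns `delay_s`, `volume` and optionally
#'   `sigma` (> 0); at least 3 distinct delays.
#' @param weighted if TRUE, weight points by 1/sigma^2; default unit weights.
#' @return list with `rate`, `sigma` (s^-1) and `amplitude`.
#' @export
fit_monoexponential <- function(series, weighted = FALSE) {
  stopifnot(is.data.frame(series))
  if (!all(c("delay_s", "volume") %in% names(series)))
    stop("series needs columns 'delay_s' and 'volume'")
  t <- series$delay_s; v <- series$volume
  if (length(unique(t)) < 3) stop("need at least 3 distinct delays")
  if (any(!is.finite(v))) stop("volumes must be finite")
  w <- rep(1, length(v))
  if (weighted) {
    if (is.null(series$sigma) || any(series$sigma <= 0))
      stop("weighted fit requires positive 'sigma' column")
    w <- 1 / series$sigma^2
  }
  # log-linear start; guard against non-positive volumes in the seed only
  vv <- pmax(v, max(v) * 1e-6)
  cf <- stats::lm(log(vv) ~ t, weights = w)$coefficients
  start <- list(A = exp(unname(cf[1])), R = max(1e-6, -unname(cf[2])))
  fit <- tryCatch(
    stats::nls(v ~ A * exp(-R * t), start = start, weights = w,
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            minFactor = 1e-12)),
    error = function(e)
      minpack.lm::nlsLM(v ~ A * exp(-R * t), start = start, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)))
  est <- summary(fit)$coefficients
  list(rate = est["R", "Estimate"], sigma = est["R", "Std. Error"],
       amplitude = est["A", "Estimate"])
}

#' Steady-state heteronuclear NOE from a saturated/reference intensity pair
#'
#' `NOE = Isat/Iref`, with the uncertainty propagated in quadrature from
#' the base-plane noise of the two spectra.
#'
#' @param Isat,Iref peak intensities (Iref nonzero).
#' @param sigma_sat,sigma_ref base-plane noise estimates (> 0).
#' @return list with `NOE` and `sigma`.
#' @export
compute_noe <- function(Isat, Iref, sigma_sat, sigma_ref) {
  if (any(Iref == 0)) stop("Iref must be nonzero")
  if (any(sigma_sat <= 0) || any(sigma_ref <= 0))
    stop("noise estimates must be positive")
  noe <- Isat / Iref
  list(NOE = noe,
       sigma = abs(noe) * sqrt((sigma_sat / Isat)^2 + (sigma_ref / Iref)^2))
}

#' Cross-correlated relaxation rate from TROSY/anti-TROSY intensities
#'
#' `eta_xy = -ln(Ibeta/Ialpha) / (2 Delta)` from the pair measured at
#' relaxation delay `Delta`; the initial uncertainty is propagated from the
#' alpha/beta intensity discrepancy of the zero-delay pair, which would be
#' identical in the absence of noise.
#'
#' @param Ialpha,Ibeta TROSY and anti-TROSY intensities at delay `Delta` (> 0).
#' @param Delta relaxation delay (s), > 0.
#' @param Ialpha0,Ibeta0 the corresponding zero-delay intensities.
#' @return list with `eta_xy` and `sigma` (s^-1).
#' @export
compute_etaxy <- function(Ialpha, Ibeta, Delta, Ialpha0, Ibeta0) {
  if (any(c(Ialpha, Ibeta, Ialpha0, Ibeta0) <= 0))
    stop("intensities must be positive")
  if (any(Delta <= 0)) stop("'Delta' must be positive (s)")
  eta <- -log(Ibeta / Ialpha) / (2 * Delta)
  # relative intensity error from the zero-delay alpha/beta discrepancy
  rel <- abs(Ibeta0 - Ialpha0) / ((Ibeta0 + Ialpha0) / 2)
  rel <- pmax(rel, 1e-12)
  sig <- sqrt(2) * rel / (2 * Delta)   # two log-intensities in quadrature
  list(eta_xy = eta, sigma = sig)
}

#' Regularize CCR uncertainties across two datasets
#'
#' Per shared residue the uncertainty is replaced by the mean of the two
#' datasets' sigmas, then floored at `floor * |eta_xy|` (default 5 percent
#' relative). The operation is idempotent.
#'
#' @param table_a,table_b data.frames with columns `residue`, `eta_xy`,
#'   `eta_xy_sigma`.
#' @param floor minimal relative error (fraction of |eta_xy|).
#' @return `table_a` restricted to the shared residues with regularized
#'   sigmas.
#' @export
regularize_ccr_errors <- function(table_a, table_b, floor = 0.05) {
  shared <- intersect(table_a$residue, table_b$residue)
  if (length(shared) == 0) stop("no shared residues between datasets")
  a <- table_a[match(shared, table_a$residue), , drop = FALSE]
  b <- table_b[match(shared, table_b$residue), , drop = FALSE]
  sig <- (a$eta_xy_sigma + b$eta_xy_sigma) / 2
  a$eta_xy_sigma <- pmax(sig, floor * abs(a$eta_xy))
  rownames(a) <- NULL
  a
}

#' Combined amide chemical shift perturbation
#'
#' `dd_eff = sqrt(ddH^2 + (0.16 ddN)^2)` per residue shared between two
#' variants; the 0.16 factor scales the larger 15N shift range onto the 1H
#' scale.
#'
#' @param shifts_a,shifts_b data.frames with columns `residue`, `dH_ppm`,
#'   `dN_ppm` for the two protein variants.
#' @return data.frame with `residue`, `dH`, `dN`, `ddEff` (ppm).
#' @export
compute_csp <- function(shifts_a, shifts_b) {
  shared <- intersect(shifts_a$residue, shifts_b$residue)
  if (length(shared) == 0) stop("no shared residues")
  a <- shifts_a[match(shared, shifts_a$residue), ]
  b <- shifts_b[match(shared, shifts_b$residue), ]
  dH <- a$dH_ppm - b$dH_ppm
  dN <- a$dN_ppm - b$dN_ppm
  data.frame(residue = shared, dH = dH, dN = dN,
             ddEff = sqrt(dH^2 + (0.16 * dN)^2))
}

#' Read and write per-residue relaxation-rate tables
#'
#' Plain TSV with a header; lines starting with `#` are comments (metadata
#' such as the field label is stored as `# key: value` lines and restored
#' on read). Columns: `residue` plus any of `r1`, `r2`, `noe`, `eta_xy`
#' each with a matching `<name>_sigma` column.
#'
#' @param path file path.
#' @return data.frame with attribute `metadata` (named list).
#' @export
read_rate_table <- function(path) {
  lines <- readLines(path)
  meta <- list()
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!"residue" %in% cols) stop("missing 'residue' column in ", path)
  vals <- lapply(c("r1", "r2", "noe", "eta_xy"), function(v) v %in% cols)
  present <- c("r1", "r2", "noe", "eta_xy")[unlist(vals)]
  missing_sig <- present[!paste0(present, "_sigma") %in% cols]
  if (length(missing_sig) > 0)
    stop("column(s) ", paste(missing_sig, collapse = ", "),
         " lack a matching _sigma column in ", path)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(cols))
  if (length(bad) > 0)
    stop("malformed row(s) at data line(s) ", paste(bad, collapse = ", "),
         " of ", path)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  for (cn in setdiff(cols, "residue")) df[[cn]] <- as.numeric(df[[cn]])
  df$residue <- as.integer(df$residue)
  if (anyDuplicated(df$residue)) stop("duplicated residue ids in ", path)
  attr(df, "metadata") <- meta
  df
}

#' @rdname read_rate_table
#' @param table data.frame as produced by the rate estimators; an optional
#'   `metadata` attribute (named list) is serialized to `#` header lines.
#' @export
write_rate_table <- function(table, path) {
  meta <- attr(table, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  writeLines(paste(names(table), collapse = "\t"), con)
  fmt <- vapply(seq_len(nrow(table)), function(i)
    paste(vapply(table[i, ], function(x)
      if (is.numeric(x)) format(x, digits = 17) else as.character(x),
      character(1)), collapse = "\t"), character(1))
  writeLines(fmt, con)
  invisible(path)
}

#' Read a decay-series table
#'
#' TSV with columns `residue`, `delay_s`, `volume`, `sigma`; `#` comments
#' ignored. Returns a list of per-residue data.frames.
#'
#' @param path file path.
#' @return named list of data.frames keyed by residue id.
#' @export
read_decay_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue", "delay_s", "volume", "sigma")
  if (!all(need %in% names(df)))
    stop("decay table needs columns: ", paste(need, collapse = ", "))
  split(df[c("delay_s", "volume", "sigma")], df$residue)
}
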