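# Stage 2: residue selection, axially symmetric diffusion-tensor fitting
# from R2/R1 ratios (and CCR-derived pseudo-ratios), delete-d resampling
# uncertainties, S2 calibration, Rex profiling and domain comparison.

#' Selection configuration for tensor fitting
#'
#' @param max_relative_ratio_error named fractions per dataset kind;
#'   defaults: 0.10 for `r2r1_900`, 0.15 for `r2r1_800`, 0.25 for `ccr`.
#' @param max_N_bfactor backbone-N B-factor ceiling (Angstrom^2).
#' @param overlap_exclusions residues excluded for spectral peak overlap
#'   (dataset-specific; must be supplied by the user, empty for synthetic
#'   pipelines).
#' @param sd_trim named SD multiples for the single-pass ratio trim;
#'   defaults 2.0 for R2/R1 data, 1.7 for CCR.
#' @return list of class `SelectionConfig`.
#' @export
selection_config <- function(max_relative_ratio_error =
                               c(r2r1_900 = 0.10, r2r1_800 = 0.15,
                                 ccr = 0.25),
                             max_N_bfactor = 35,
                             overlap_exclusions = integer(0),
                             sd_trim = c(r2r1_900 = 2.0, r2r1_800 = 2.0,
                                         ccr = 1.7)) {
  if (any(max_relative_ratio_error <= 0) || max_N_bfactor <= 0 ||
      any(sd_trim <= 0))
    stop("selection thresholds must be positive")
  structure(list(max_relative_ratio_error = max_relative_ratio_error,
                 max_N_bfactor = max_N_bfactor,
                 overlap_exclusions = overlap_exclusions,
                 sd_trim = sd_trim),
            class = "SelectionConfig")
}

#' Resampling configuration
#'
#' @param deletion_fraction fraction d of residues omitted per refit,
#'   0 < d < 0.5 (above 0.5 tensor fits degrade and the scheme is unusable).
#' @param repeats number of resampled refits.
#' @param seed RNG seed.
#' @return list of class `ResamplingConfig`.
#' @export
resampling_config <- function(deletion_fraction = 0.20, repeats = 100,
                              seed = 1) {
  if (deletion_fraction <= 0 || deletion_fraction >= 0.5)
    stop("'deletion_fraction' must be in (0, 0.5)")
  if (repeats < 2) stop("'repeats' must be >= 2")
  structure(list(deletion_fraction = deletion_fraction,
                 repeats = repeats, seed = seed),
            class = "ResamplingConfig")
}

#' Select residues for diffusion-tensor fitting
#'
#' Applies, in order: (i) relative ratio-error threshold for the dataset
#' kind; (ii) backbone-N B-factor ceiling; (iii) overlap exclusion list;
#' (iv) a single-pass trim of ratios beyond `sd_trim` SD from the mean of
#' the residues surviving (i)-(iii).
#'
#' @param ratios data.frame with `residue`, `ratio`, `sigma`.
#' @param geometry `SpinGeometry` data.frame from [nh_vectors()] (provides
#'   B-factors); residues absent from it are dropped.
#' @param cfg a [selection_config()].
#' @param kind dataset kind: `"r2r1_900"`, `"r2r1_800"` or `"ccr"`.
#' @return list with `selected` (residue ids) and `audit` (data.frame of
#'   residue, criterion that removed it).
#' @export
select_residues <- function(ratios, geometry, cfg = selection_config(),
                            kind = "r2r1_900") {
  if (!kind %in% names(cfg$max_relative_ratio_error))
    stop("unknown dataset kind: ", kind)
  audit <- data.frame(residue = integer(), criterion = character(),
                      stringsAsFactors = FALSE)
  drop <- function(res, why) {
    if (length(res) > 0)
      audit <<- rbind(audit, data.frame(residue = res, criterion = why,
                                        stringsAsFactors = FALSE))
  }
  cur <- ratios
  miss <- setdiff(cur$residue, geometry$residue)
  drop(miss, "no_geometry")
  cur <- cur[cur$residue %in% geometry$residue, ]
  # (i) relative error
  rel <- abs(cur$sigma / cur$ratio)
  bad <- cur$residue[rel > cfg$max_relative_ratio_error[[kind]]]
  drop(bad, "relative_error")
  cur <- cur[!cur$residue %in% bad, ]
  # (ii) B-factor
  bf <- geometry$bfactor[match(cur$residue, geometry$residue)]
  bad <- cur$residue[!is.na(bf) & bf > cfg$max_N_bfactor]
  drop(bad, "bfactor")
  cur <- cur[!cur$residue %in% bad, ]
  # (iii) overlap
  bad <- intersect(cur$residue, cfg$overlap_exclusions)
  drop(bad, "overlap")
  cur <- cur[!cur$residue %in% bad, ]
  # (iv) single-pass SD trim
  if (nrow(cur) > 2) {
    m <- mean(cur$ratio); s <- stats::sd(cur$ratio)
    bad <- cur$residue[abs(cur$ratio - m) > cfg$sd_trim[[kind]] * s]
    drop(bad, "sd_trim")
    cur <- cur[!cur$residue %in% bad, ]
  }
  if (nrow(cur) == 0) stop("no residues survive selection")
  list(selected = cur$residue, audit = audit)
}

# predicted R2/R1 ratios for all residues; cphi = cos(angle NH vs axis)
predict_ratios_axial <- function(Dperp, Dpar, axis, vectors, field) {
  cphi <- as.vector(vectors %*% axis)
  J <- jw_axial_all(Dperp, Dpar, cphi, field$omegaH, field$omegaN)
  r <- rates_from_J(J$J0, J$JN, J$JmHN, J$JH, J$JpHN, field)
  r$R2 / r$R1
}

# weighted least-squares objective on experimental ratios
ratio_objective <- function(par, vectors, ratio, w, field) {
  Dperp <- exp(par[1]); Dpar <- exp(par[2])
  ax <- axis_vector(par[3] * 180 / pi, par[4] * 180 / pi)
  pred <- predict_ratios_axial(Dperp, Dpar, ax, vectors, field)
  sum(w * (ratio - pred)^2)
}

#' Fit an axially symmetric rotational diffusion tensor from R2/R1 ratios
#'
#' Minimizes `sum_i [(ratio_i - ratio_pred_i(Dperp, Dpar, alpha, beta)) /
#' sigma_i]^2`, the predicted ratios coming from the full relaxation-rate
#' expressions with the three-term Woessner spectral density. A 12 x 12
#' orientation grid seeded from the isotropic solution provides multiple
#' starts; the best starts are refined by Nelder-Mead and a quasi-Newton
#' polish. Angles are canonicalized (`beta` in \[0, 90\]).
#'
#' @param ratios data.frame with `residue`, `ratio`, `sigma`.
#' @param geometry `SpinGeometry` data.frame with NH unit vectors.
#' @param field a [make_field_context()] object.
#' @param grid orientation grid size per angle.
#' @param n_refine number of best grid starts refined.
#' @return list of class `TensorFitResult`: `tensor`, `residues`, `value`
#'   (target function), `n` and (after [resample_tensor()]) uncertainty
#'   fields.
#' @export
fit_axial_tensor <- function(ratios, geometry, field, grid = 12,
                             n_refine = 4) {
  idx <- match(ratios$residue, geometry$residue)
  if (anyNA(idx)) stop("ratios contain residues without geometry")
  V <- as.matrix(geometry[idx, c("ux", "uy", "uz")])
  if (anyNA(V)) stop("missing NH vectors for some residues")
  if (nrow(V) < 8) stop("need at least 8 residues for a tensor fit")
  ratio <- ratios$ratio
  w <- 1 / ratios$sigma^2
  # isotropic seed
  tau_iso <- tauc_from_r2r1(max(mean(ratio), 7 / 6 + 1e-6), field) * 1e-9
  D_iso <- 1 / (6 * tau_iso)
  alphas <- seq(0, 180, length.out = grid + 1)[-(grid + 1)]
  betas <- seq(5, 90, length.out = grid)
  starts <- expand.grid(alpha = alphas, beta = betas)
  vals <- vapply(seq_len(nrow(starts)), function(i) {
    ratio_objective(c(log(0.9 * D_iso), log(1.3 * D_iso),
                      starts$alpha[i] * pi / 180, starts$beta[i] * pi / 180),
                    V, ratio, w, field)
  }, numeric(1))
  best <- order(vals)[seq_len(n_refine)]
  fits <- lapply(best, function(i) {
    p0 <- c(log(0.9 * D_iso), log(1.3 * D_iso),
            starts$alpha[i] * pi / 180, starts$beta[i] * pi / 180)
    f1 <- stats::optim(p0, ratio_objective, vectors = V, ratio = ratio,
                       w = w, field = field, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 2000))
    for (k in 1:2)
      f1 <- stats::optim(f1$par, ratio_objective, vectors = V, ratio = ratio,
                         w = w, field = field, method = "BFGS",
                         control = list(reltol = 1e-14, maxit = 500,
                                        ndeps = rep(1e-7, 4)))
    f1
  })
  fb <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- fb$par
  tens <- diffusion_tensor(exp(p[1]), exp(p[2]),
                           p[3] * 180 / pi, p[4] * 180 / pi)
  # an axial tensor fitted with Dpar < Dperp is the same tensor with the
  # roles swapped and the axis in the perpendicular plane is ill-defined;
  # report as-is but warn near isotropy
  res <- structure(list(tensor = tens, residues = ratios$residue,
                        value = fb$value, n = nrow(V),
                        field = field),
                   class = "TensorFitResult")
  if (abs(tens$zeta - 1) < 0.02) {
    res$orientation_defined <- FALSE
    warning("fitted tensor is nearly isotropic; axis orientation is undefined")
  } else res$orientation_defined <- TRUE
  res
}

#' Convert CCR rates to pseudo R2/R1 ratios
#'
#' Per residue, the correlation time is obtained from eta_xy via the
#' J(0)-truncated inversion with the calibrated order parameter, then
#' converted to the R2/R1 ratio of the target field through the
#' low-frequency relation. Uncertainties are propagated through both steps
#' (ratio - 7/6 scales as eta_xy^2). Tensors fitted from this pathway are
#' flagged for qualitative use: the CCR route rests on the truncated eta_xy
#' expression and a global S2.
#'
#' @param table data.frame with `residue`, `eta_xy`, `eta_xy_sigma`.
#' @param S2 order parameter (default 0.88).
#' @param field a [make_field_context()] object for the target field.
#' @return data.frame `residue`, `ratio`, `sigma`, `tauC` (ns).
#' @export
ccr_to_pseudo_ratios <- function(table, S2 = 0.88, field) {
  if (any(table$eta_xy <= 0)) stop("eta_xy values must be positive")
  tau <- tauc_from_etaxy(table$eta_xy, S2 = S2, field = field)
  ratio <- r2r1_from_tauc(tau, field)
  relerr <- table$eta_xy_sigma / table$eta_xy
  sigma <- 2 * (ratio - 7 / 6) * relerr   # d(ratio)/ratio' via tau ~ eta
  data.frame(residue = table$residue, ratio = ratio, sigma = sigma,
             tauC = tau)
}

#' Calibrate the CCR order parameter against R2/R1 correlation times
#'
#' The unique S2 making the mean CCR-derived correlation time equal the
#' mean R2/R1-derived one (tauC is proportional to 1/S2):
#' `S2_new = S2_old * mean(tauC_ccr(S2_old)) / mean(tauC_r2r1)`.
#'
#' @param ccr_taucs per-residue tauC (ns) from the CCR pathway computed at
#'   `current_S2`.
#' @param r2r1_taucs per-residue tauC (ns) from R2/R1 ratios.
#' @param current_S2 the S2 used for `ccr_taucs`.
#' @return calibrated S2.
#' @export
calibrate_s2 <- function(ccr_taucs, r2r1_taucs, current_S2 = 0.88) {
  if (length(ccr_taucs) == 0 || length(r2r1_taucs) == 0)
    stop("both tauC lists must be non-empty")
  m_ccr <- mean(ccr_taucs); m_ref <- mean(r2r1_taucs)
  if (m_ccr == 0 || m_ref == 0) stop("zero mean correlation time")
  current_S2 * m_ccr / m_ref
}

#' Delete-d resampling uncertainties for a tensor fit
#'
#' Refits the tensor on `repeats` random subsets with a fraction d of
#' residues deleted (without replacement), warm-started from the full-data
#' solution. Parameter uncertainties are `sqrt(n/d_count) * SD` over the
#' resampled values, the delete-d jackknife scaling (sqrt(5) for d = 20
#' percent).
#'
#' @param ratios,geometry,field as in [fit_axial_tensor()].
#' @param cfg a [resampling_config()].
#' @return `TensorFitResult` with `resamples` (data.frame of per-repeat
#'   Dperp, Dpar, alpha, beta, tauC) and `uncertainty` (scaled SDs, plus
#'   `tauC`), and `scale_factor = sqrt(n/d_count)`.
#' @export
resample_tensor <- function(ratios, geometry, field,
                            cfg = resampling_config()) {
  full <- fit_axial_tensor(ratios, geometry, field)
  n <- nrow(ratios)
  d_count <- max(1L, round(cfg$deletion_fraction * n))
  keep_n <- n - d_count
  if (keep_n < 8) stop("resampled subsets too small to fit")
  p_full <- c(log(full$tensor$Dperp), log(full$tensor$Dpar),
              full$tensor$alpha * pi / 180, full$tensor$beta * pi / 180)
  idx_geom <- match(ratios$residue, geometry$residue)
  V <- as.matrix(geometry[idx_geom, c("ux", "uy", "uz")])
  draws <- with_seed(cfg$seed, lapply(seq_len(cfg$repeats), function(i)
    sample.int(n, keep_n)))
  res <- lapply(draws, function(keep) {
    w <- 1 / ratios$sigma[keep]^2
    f1 <- stats::optim(p_full, ratio_objective, vectors = V[keep, ],
                       ratio = ratios$ratio[keep], w = w, field = field,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 1500))
    p <- stats::optim(f1$par, ratio_objective, vectors = V[keep, ],
                      ratio = ratios$ratio[keep], w = w, field = field,
                      method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 300,
                                     ndeps = rep(1e-7, 4)))$par
    tt <- diffusion_tensor(exp(p[1]), exp(p[2]),
                           p[3] * 180 / pi, p[4] * 180 / pi)
    c(Dperp = tt$Dperp, Dpar = tt$Dpar, alpha = tt$alpha, beta = tt$beta,
      tauC = tt$tauC)
  })
  rs <- as.data.frame(do.call(rbind, res))
  scale <- sqrt(n / d_count)
  # circular SD for angles (alpha lives on a 360 deg circle mod axis flips)
  ang_sd <- function(x) {
    m <- atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
    sqrt(mean(ang_diff(x, m)^2))
  }
  full$resamples <- rs
  full$scale_factor <- scale
  full$uncertainty <- c(Dperp = scale * stats::sd(rs$Dperp),
                        Dpar = scale * stats::sd(rs$Dpar),
                        alpha = scale * ang_sd(rs$alpha),
                        beta = scale * ang_sd(rs$beta),
                        tauC = scale * stats::sd(rs$tauC))
  full$resampling <- cfg
  full
}

#' Per-residue conformational-exchange profile
#'
#' Applies the R2 versus eta_xy comparison residue by residue and flags
#' statistically significant exchange at `Rex/sigma_Rex > 5`. Residues
#' lacking either rate are skipped and recorded in the audit.
#'
#' @param table data.frame with columns `residue`, `r2`, `r2_sigma`,
#'   `eta_xy`, `eta_xy_sigma` (NA allowed, such rows are skipped).
#' @param field a [make_field_context()] object.
#' @param threshold significance threshold on Rex/sigma.
#' @return list with `profile` (residue, Rex, sigma, significant) and
#'   `skipped` (residue ids lacking a complete pair).
#' @export
rex_profile <- function(table, field, threshold = 5) {
  need <- c("residue", "r2", "r2_sigma", "eta_xy", "eta_xy_sigma")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  ok <- stats::complete.cases(table[, need])
  skipped <- table$residue[!ok]
  t2 <- table[ok, ]
  r <- rex_from_r2_etaxy(t2$r2, t2$eta_xy, field,
                         sigma_R2 = t2$r2_sigma, sigma_eta = t2$eta_xy_sigma)
  list(profile = data.frame(residue = t2$residue, Rex = r$Rex,
                            sigma = r$sigma,
                            significant = r$Rex / r$sigma > threshold),
       skipped = skipped)
}

#' Compare two resampled tensor fits
#'
#' Z-like scores per parameter using the combined scaled uncertainties;
#' verdict `"distinct"` when both Dperp and Dpar differ by more than 2
#' combined SD, otherwise `"indistinguishable"`. Symmetric in its
#' arguments.
#'
#' @param fit_a,fit_b `TensorFitResult`s carrying resample distributions.
#' @return list with `scores` (named absolute z scores) and `verdict`.
#' @export
compare_domain_tensors <- function(fit_a, fit_b) {
  if (is.null(fit_a$uncertainty) || is.null(fit_b$uncertainty))
    stop("both fits must carry resampling uncertainties")
  zs <- function(name) {
    num <- abs(fit_a$tensor[[name]] - fit_b$tensor[[name]])
    den <- sqrt(fit_a$uncertainty[[name]]^2 + fit_b$uncertainty[[name]]^2)
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
  }
  scores <- c(Dperp = zs("Dperp"), Dpar = zs("Dpar"), tauC = zs("tauC"))
  verdict <- if (scores["Dperp"] > 2 && scores["Dpar"] > 2)
    "distinct" else "indistinguishable"
  list(scores = scores, verdict = verdict)
}
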