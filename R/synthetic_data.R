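# Ground-truth generators for every pipeline input: relaxation datasets
# from a known axially symmetric diffusion tensor, decay curves,
# TROSY/anti-TROSY pairs, and toy two-domain ensembles with a hinge mode
# coupled to a two-state side-chain flip. All generators are pure functions
# of (spec, seed).

#' Deterministic or seeded unit vectors on the sphere
#'
#' @param n number of vectors.
#' @param scheme `"fibonacci"` (deterministic quasi-uniform lattice) or
#'   `"uniform"` (seeded isotropic random directions).
#' @param seed RNG seed for the uniform scheme.
#' @return n x 3 matrix of unit vectors.
#' @export
simulate_vectors <- function(n, scheme = c("fibonacci", "uniform"),
                             seed = 1) {
  if (n < 1) stop("'n' must be >= 1")
  scheme <- match.arg(scheme)
  if (scheme == "fibonacci") {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    phi <- pi * (1 + sqrt(5)) * i
    r <- sqrt(1 - z^2)
    cbind(r * cos(phi), r * sin(phi), z)
  } else {
    with_seed(seed, {
      v <- matrix(stats::rnorm(3 * n), n, 3)
      v / sqrt(rowSums(v^2))
    })
  }
}

#' Specification of a synthetic relaxation dataset
#'
#' @param tensor truth [diffusion_tensor()].
#' @param S2 order parameter scaling all spectral densities (fast-libration
#'   correction; cancels in R2/R1 but enters eta_xy).
#' @param fields spectrometer 1H frequencies (MHz); eta_xy is generated for
#'   the first field.
#' @param vectors n x 3 NH unit-vector matrix, or an integer count (then a
#'   Fibonacci set is used).
#' @param noise named fractions per observable (`r1`, `r2`, `noe`,
#'   `eta_xy`, `volume`, `intensity`).
#' @param rex named numeric vector: residue id -> injected Rex (s^-1).
#' @param seed RNG seed.
#' @return list of class `RelaxationSimSpec`.
#' @export
relaxation_sim_spec <- function(tensor = diffusion_tensor(0.56e7, 0.77e7,
                                                          alpha = 11,
                                                          beta = 59),
                                S2 = 0.88,
                                fields = c(900, 800),
                                vectors = 120,
                                noise = c(r1 = 0, r2 = 0, noe = 0,
                                          eta_xy = 0, volume = 0,
                                          intensity = 0),
                                rex = numeric(0),
                                seed = 1) {
  if (any(noise < 0)) stop("noise fractions must be >= 0")
  if (is.numeric(vectors) && length(vectors) == 1)
    vectors <- simulate_vectors(vectors)
  structure(list(tensor = tensor, S2 = S2, fields = fields,
                 vectors = vectors, noise = noise, rex = rex, seed = seed),
            class = "RelaxationSimSpec")
}

# default relaxation-delay schedules (s)
.default_delays <- list(
  r1 = c(0.08, 0.16, 0.32, 0.48, 0.72, 0.88, 1.12, 1.36, 1.76, 2.24, 2.4),
  r2 = c(0.0058, 0.0115, 0.0173, 0.0230, 0.0288, 0.0346, 0.0403)
)

#' Simulate a decay series
#'
#' `A exp(-R t)` with seeded Gaussian noise (fraction of the amplitude).
#'
#' @param rate decay rate (s^-1), > 0.
#' @param delays delays (s); duplicates allowed.
#' @param noise noise SD as a fraction of the amplitude.
#' @param seed RNG seed.
#' @param amplitude signal amplitude.
#' @return data.frame `delay_s`, `volume`, `sigma`.
#' @export
simulate_decay <- function(rate, delays = .default_delays$r2, noise = 0.01,
                           seed = 1, amplitude = 100) {
  if (rate <= 0) stop("'rate' must be positive")
  v <- amplitude * exp(-rate * delays)
  sig <- max(noise, 1e-6) * amplitude
  if (noise > 0)
    v <- v + with_seed(seed, stats::rnorm(length(delays), 0, sig))
  data.frame(delay_s = delays, volume = v, sigma = sig)
}

#' Simulate a complete relaxation dataset from a known tensor
#'
#' Noiseless per-residue R1, R2, NOE and eta_xy are computed from the
#' forward model (full rate expressions with the three-term Woessner
#' spectral density, scaled by S2); injected exchange is added to R2;
#' Gaussian noise is applied last. Decay curves and TROSY/anti-TROSY
#' intensity pairs reproducing those rates are generated alongside.
#'
#' @param spec a [relaxation_sim_spec()].
#' @return list with `tables` (per-field rate data.frames; eta columns on
#'   the first field only), `decays` (per-field list of R1/R2 decay series
#'   by residue), `pairs` (TROSY/anti-TROSY intensities at Delta = 0 and
#'   0.010 s), `geometry` (SpinGeometry data.frame), `truth` (spec).
#' @export
simulate_relaxation_dataset <- function(spec = relaxation_sim_spec()) {
  V <- spec$vectors
  n <- nrow(V)
  resid <- seq_len(n)
  ax <- axis_vector(spec$tensor$alpha, spec$tensor$beta)
  cphi <- as.vector(V %*% ax)
  geometry <- data.frame(residue = resid, chain = "A",
                         ux = V[, 1], uy = V[, 2], uz = V[, 3],
                         bfactor = 20, flag = "ok",
                         stringsAsFactors = FALSE)
  rex <- rep(0, n)
  if (length(spec$rex) > 0)
    rex[as.integer(names(spec$rex))] <- spec$rex
  noise <- spec$noise
  nz <- function(key) if (key %in% names(noise)) noise[[key]] else 0
  tables <- list(); decays <- list(); pairs <- NULL
  for (fi in seq_along(spec$fields)) {
    fmhz <- spec$fields[fi]
    field <- make_field_context(fmhz)
    J <- jw_axial_all(spec$tensor$Dperp, spec$tensor$Dpar, cphi,
                      field$omegaH, field$omegaN, S2 = spec$S2)
    r <- rates_from_J(J$J0, J$JN, J$JmHN, J$JH, J$JpHN, field)
    r$R2 <- r$R2 + rex
    tab <- with_seed(spec$seed + fi, {
      jitter <- function(x, f) if (f > 0)
        x + stats::rnorm(n, 0, f * abs(x)) else x
      sig <- function(x, f) pmax(f, 1e-4) * abs(x)
      data.frame(residue = resid,
                 r1 = jitter(r$R1, nz("r1")), r1_sigma = sig(r$R1, nz("r1")),
                 r2 = jitter(r$R2, nz("r2")), r2_sigma = sig(r$R2, nz("r2")),
                 noe = jitter(r$NOE, nz("noe")),
                 noe_sigma = sig(r$NOE, nz("noe")))
    })
    if (fi == 1L) {
      tab$eta_xy <- with_seed(spec$seed + 101, {
        if (nz("eta_xy") > 0)
          r$eta_xy + stats::rnorm(n, 0, nz("eta_xy") * abs(r$eta_xy))
        else r$eta_xy
      })
      tab$eta_xy_sigma <- pmax(nz("eta_xy"), 1e-4) * abs(r$eta_xy)
      Delta <- 0.010
      pairs <- with_seed(spec$seed + 202, {
        i0 <- 100
        jit <- function(x) if (nz("intensity") > 0)
          x * (1 + stats::rnorm(n, 0, nz("intensity"))) else x
        data.frame(residue = resid,
                   Ialpha0 = jit(rep(i0, n)), Ibeta0 = jit(rep(i0, n)),
                   Ialpha = jit(i0 * exp(-(r$R2 - r$eta_xy) * Delta)),
                   Ibeta = jit(i0 * exp(-(r$R2 + r$eta_xy) * Delta)),
                   Delta = Delta)
      })
    }
    attr(tab, "metadata") <- list(field_mhz = as.character(fmhz),
                                  provenance = "synthetic")
    tables[[as.character(fmhz)]] <- tab
    decays[[as.character(fmhz)]] <- list(
      r1 = lapply(resid, function(i)
        simulate_decay(r$R1[i], .default_delays$r1, nz("volume"),
                       seed = spec$seed + 1000 * fi + i)),
      r2 = lapply(resid, function(i)
        simulate_decay(r$R2[i], .default_delays$r2, nz("volume"),
                       seed = spec$seed + 5000 * fi + i)))
  }
  list(tables = tables, decays = decays, pairs = pairs,
       geometry = geometry, truth = spec)
}

#' Specification of a synthetic two-domain ensemble
#'
#' @param M model count.
#' @param fractions four state fractions (sum 1): I, II, III, IV with
#'   states defined as in [assign_states()]. Defaults mirror the
#'   populations of a two-domain paracaspase ensemble (0.555, 0.083,
#'   0.350, 0.011).
#' @param hinge_amplitude hinge rotation of domain B (degrees) for the two
#'   hinge clusters (+/-).
#' @param hinge_sd per-model SD of the hinge angle (degrees).
#' @param coupling probability in \[0, 1\] that the hinge cluster follows
#'   the probe-A rotamer state (1 = deterministic coupling, 0 =
#'   independent).
#' @param chi_sd SD of the probe dihedrals about their anchors (degrees).
#' @param coord_noise Gaussian coordinate noise SD (Angstrom).
#' @param plddt_means per-state mean confidence of the probe residues.
#' @param seed RNG seed.
#' @return list of class `EnsembleSimSpec`.
#' @export
ensemble_sim_spec <- function(M = 2000,
                              fractions = c(0.555, 0.083, 0.350, 0.011),
                              hinge_amplitude = 12, hinge_sd = 2,
                              coupling = 1, chi_sd = 8,
                              coord_noise = 0.05,
                              plddt_means = c(92, 90, 82, 78),
                              seed = 1) {
  if (M < 2) stop("'M' must be >= 2")
  if (abs(sum(fractions) - 1) > 0.01 || any(fractions < 0))
    stop("state fractions must be nonnegative and sum to 1")
  fractions <- fractions / sum(fractions)  # absorb rounding (e.g. printed
                                           # percentages summing to 99.9)
  if (coupling < 0 || coupling > 1) stop("'coupling' must be in [0, 1]")
  structure(list(M = M, fractions = fractions,
                 hinge_amplitude = hinge_amplitude, hinge_sd = hinge_sd,
                 coupling = coupling, chi_sd = chi_sd,
                 coord_noise = coord_noise, plddt_means = plddt_means,
                 seed = seed),
            class = "EnsembleSimSpec")
}

# template for the toy two-domain polymer:
# residues 1-20  : domain A, CA trace on a gentle helix (fixed)
# residues 21-40 : domain B, CA trace, rotated about the z axis through the
#                  hinge point at residue 20
# residue 41     : TRP-like probe (N, CA, CB, CG, CD1), chi2 set per model
# residue 42     : TYR-like probe (N, CA, CB, CG), chi1 set per model
toy_template <- function() {
  helix <- function(i, x0) cbind(x0 + 1.5 * i, 2.3 * cos(i), 2.3 * sin(i))
  caA <- helix(1:20, 0)
  caB <- helix(1:20, 40)
  atom <- data.frame(
    type = "ATOM",
    eleno = NA_integer_,
    elety = c(rep("CA", 40), c("N", "CA", "CB", "CG", "CD1"),
              c("N", "CA", "CB", "CG")),
    alt = "", resid = c(rep("GLY", 40), rep("TRP", 5), rep("TYR", 4)),
    chain = "A",
    resno = c(1:40, rep(41L, 5), rep(42L, 4)),
    insert = "", x = 0, y = 0, z = 0, o = 1, b = 0,
    segid = "", elesy = "C", charge = "",
    stringsAsFactors = FALSE)
  # probe scaffolds away from the chains
  trp_base <- rbind(c(0, 20, 0), c(1.46, 20, 0),
                    c(2.0, 20, 1.45), c(1.5, 21.2, 2.2))   # N CA CB CG
  tyr_base <- rbind(c(0, -20, 0), c(1.46, -20, 0), c(2.0, -20, 1.45))
  list(atom = atom, caA = caA, caB = caB,
       trp_base = trp_base, tyr_base = tyr_base,
       hinge = caA[20, ])
}

#' Simulate a toy two-domain conformational ensemble
#'
#' Generates a minimal two-domain C-alpha polymer whose second domain
#' rotates about a hinge, plus two dihedral probe residues whose rotamer
#' states are drawn from the spec fractions. The hinge cluster is coupled
#' to the probe-A state with the given coupling probability, mirroring a
#' hinge mode correlated with a side-chain flip. Per-residue confidence is
#' assigned state-dependently on the probe residues. The geometry is
#' deliberately minimal (no sterics): it reproduces the statistical
#' structure the PCA stage consumes, not molecular realism.
#'
#' @param spec an [ensemble_sim_spec()].
#' @return an `Ensemble` with attribute `truth` (per-model state labels,
#'   hinge angles, chi angles).
#' @export
simulate_ensemble <- function(spec = ensemble_sim_spec()) {
  tpl <- toy_template()
  M <- spec$M
  anchors_a <- c(80, -100)   # probe A (chi2): outward / inward
  anchors_b <- c(-93, 57)    # probe B (chi1)
  sim <- with_seed(spec$seed, {
    state <- sample.int(4, M, replace = TRUE, prob = spec$fractions)
    a_cls <- ifelse(state <= 2, 1L, 2L)        # probe A rotamer class
    b_cls <- ifelse(state %% 2 == 1L, 1L, 2L)  # probe B rotamer class
    follow <- stats::runif(M) < spec$coupling
    hinge_cls <- ifelse(follow, a_cls, sample.int(2, M, replace = TRUE))
    hinge <- ifelse(hinge_cls == 1L, spec$hinge_amplitude,
                    -spec$hinge_amplitude) + stats::rnorm(M, 0, spec$hinge_sd)
    chiA <- anchors_a[a_cls] + stats::rnorm(M, 0, spec$chi_sd)
    chiB <- anchors_b[b_cls] + stats::rnorm(M, 0, spec$chi_sd)
    plddt_probe <- spec$plddt_means[state] + stats::rnorm(M, 0, 1.5)
    noise <- if (spec$coord_noise > 0)
      array(stats::rnorm(M * nrow(tpl$atom) * 3, 0, spec$coord_noise),
            dim = c(M, nrow(tpl$atom), 3)) else NULL
    list(state = state, hinge = hinge, chiA = chiA, chiB = chiB,
         plddt_probe = plddt_probe, noise = noise)
  })
  natoms <- nrow(tpl$atom)
  xyz <- matrix(0, M, 3 * natoms)
  for (m in seq_len(M)) {
    th <- sim$hinge[m] * pi / 180
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                  3, 3)
    caB <- sweep(sweep(tpl$caB, 2, tpl$hinge) %*% t(rot), 2, tpl$hinge, "+")
    trp <- rbind(tpl$trp_base,
                 place_atom(tpl$trp_base[2, ], tpl$trp_base[3, ],
                            tpl$trp_base[4, ], 1.4, 114, sim$chiA[m]))
    tyr <- rbind(tpl$tyr_base,
                 place_atom(tpl$tyr_base[1, ], tpl$tyr_base[2, ],
                            tpl$tyr_base[3, ], 1.5, 114, sim$chiB[m]))
    co <- rbind(tpl$caA, caB, trp, tyr)
    if (!is.null(sim$noise)) co <- co + sim$noise[m, , ]
    xyz[m, ] <- as.vector(t(co))
  }
  plddt <- matrix(90, M, 42, dimnames = list(NULL, 1:42))
  plddt[, "41"] <- pmin(100, pmax(0, sim$plddt_probe))
  plddt[, "42"] <- pmin(100, pmax(0, sim$plddt_probe))
  ens <- new_ensemble(xyz, tpl$atom, plddt = plddt)
  attr(ens, "truth") <- list(state = sim$state, hinge = sim$hinge,
                             chiA = sim$chiA, chiB = sim$chiB,
                             spec = spec)
  ens
}
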