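# Closed-form 15N relaxation equations, spectral densities, and the scalar
# relations linking R2/R1, eta_xy and the rotational correlation time.
#
# All internal quantities are SI (rad/s, s, T); API boundaries use ns for
# correlation times, ppm for the CSA, MHz for spectrometer frequencies.

#' Physical constants for the amide 15N-1H spin pair
#'
#' Returns the constant set entering the dipolar and CSA interaction
#' strengths: vacuum permeability, Planck constant, gyromagnetic ratios,
#' N-H bond length, 15N chemical shielding anisotropy and the angle between
#' the N-H bond and the unique axis of the 15N shift tensor.
#'
#' @param gammaN 15N gyromagnetic ratio (rad s^-1 T^-1, negative).
#' @param gammaH 1H gyromagnetic ratio (rad s^-1 T^-1).
#' @param rNH N-H bond length (Angstrom).
#' @param deltaSigma 15N CSA (ppm).
#' @param theta angle between the N-H vector and the CSA unique axis (degrees).
#' @return object of class `PhysicalConstants`.
#' @export
physical_constants <- function(gammaN = -27.116e6,
                               gammaH = 267.522e6,
                               rNH = 1.02,
                               deltaSigma = 172,
                               theta = 17) {
  vals <- list(mu0 = 4 * pi * 1e-7, h = 6.62607e-34,
               gammaN = gammaN, gammaH = gammaH, rNH = rNH,
               deltaSigma = deltaSigma, theta = theta)
  if (any(vapply(vals, function(x) x == 0, logical(1))))
    stop("all physical constants must be nonzero")
  structure(vals, class = "PhysicalConstants")
}

#' Field-dependent interaction constants
#'
#' Derives, for a given spectrometer 1H frequency, the Larmor angular
#' frequencies and the dipolar (d), CSA (c), dipolar cross-correlation (p)
#' and CSA cross-correlation (deltaN) constants used throughout the
#' relaxation equations. Gyromagnetic-ratio magnitudes are used for all
#' derived constants; the sign of gammaN enters only through the NOE.
#'
#' @param frequency spectrometer 1H frequency (MHz).
#' @param constants a [physical_constants()] object.
#' @return object of class `FieldContext` with fields `B0`, `omegaH`,
#'   `omegaN` (rad/s, magnitudes), `d`, `c`, `p`, `deltaN` (rad/s) and the
#'   constants used.
#' @export
make_field_context <- function(frequency, constants = physical_constants()) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("'frequency' must be a single positive number (MHz)")
  k <- constants
  B0 <- 2 * pi * frequency * 1e6 / k$gammaH
  omegaH <- k$gammaH * B0
  omegaN <- abs(k$gammaN) * B0
  r3 <- (k$rNH * 1e-10)^3
  d <- k$mu0 * k$h * abs(k$gammaN) * k$gammaH / (8 * pi^2) / r3
  dsig <- k$deltaSigma * 1e-6
  cc <- dsig * omegaN / sqrt(3)
  p <- k$mu0 * k$gammaH * abs(k$gammaN) * k$h / (16 * pi^2 * sqrt(2) * r3)
  deltaN <- abs(k$gammaN) * B0 * dsig / (3 * sqrt(2))
  structure(list(frequency = frequency, B0 = B0,
                 omegaH = omegaH, omegaN = omegaN,
                 d = d, c = cc, p = p, deltaN = deltaN,
                 constants = k),
            class = "FieldContext")
}

#' Axially symmetric rotational diffusion tensor
#'
#' @param Dperp,Dpar perpendicular and parallel principal components (s^-1).
#' @param alpha,beta orientation of the symmetry axis in the molecular frame
#'   (degrees); `gamma_angle` is carried for completeness but is immaterial
#'   for axial symmetry.
#' @param gamma_angle third Euler angle (degrees).
#' @return object of class `DiffusionTensor` with derived `tauC` (ns) and
#'   anisotropy `zeta = Dpar/Dperp`. Orientation is canonicalized to
#'   `beta` in \[0, 90\] (the axis is defined up to sign); `alpha` in
#'   \[0, 360) and reduced mod 180 when `beta = 90`.
#' @export
diffusion_tensor <- function(Dperp, Dpar, alpha = 0, beta = 0,
                             gamma_angle = 0) {
  if (Dperp <= 0 || Dpar <= 0) stop("principal components must be positive")
  can <- canonical_axis_angles(alpha, beta)
  structure(list(Dperp = Dperp, Dpar = Dpar,
                 alpha = can$alpha, beta = can$beta,
                 gamma_angle = gamma_angle,
                 zeta = Dpar / Dperp,
                 tauC = 1e9 / (2 * (Dpar + 2 * Dperp))),
            class = "DiffusionTensor")
}

# canonical (alpha, beta) for an axis defined up to sign
canonical_axis_angles <- function(alpha, beta) {
  u <- axis_vector(alpha, beta)
  if (u[3] < 0) u <- -u
  b <- acos(max(-1, min(1, u[3]))) * 180 / pi
  a <- atan2(u[2], u[1]) * 180 / pi
  a <- a %% 360
  if (abs(b - 90) < 1e-9) a <- a %% 180
  if (b < 1e-9) a <- 0  # axis orientation about z undefined
  list(alpha = a, beta = b)
}

# unit vector of the symmetry axis from polar angles (degrees)
axis_vector <- function(alpha, beta) {
  a <- alpha * pi / 180; b <- beta * pi / 180
  c(sin(b) * cos(a), sin(b) * sin(a), cos(b))
}

#' Effective rotational correlation time of a diffusion tensor
#'
#' `tauC = 1/(2 tr(D)) = 1/(2 (Dpar + 2 Dperp))`. Note the reciprocal of
#' the trace: the frequently quoted form "tauC = 1/2 tr(D)" is dimensionally
#' inconsistent and does not reproduce published component/tauC pairs.
#'
#' @param tensor a [diffusion_tensor()] object.
#' @return tauC in ns.
#' @export
tauc_from_tensor <- function(tensor) {
  1e9 / (2 * (tensor$Dpar + 2 * tensor$Dperp))
}

#' Isotropic spectral density
#'
#' `J(w) = (2/5) tauC / (1 + (w tauC)^2)`.
#'
#' @param omega angular frequency (rad/s); vectorized.
#' @param tauC correlation time (s).
#' @return spectral density (s).
#' @export
jw_isotropic <- function(omega, tauC) {
  if (tauC <= 0) stop("'tauC' must be positive (seconds)")
  (2 / 5) * tauC / (1 + (omega * tauC)^2)
}

#' Woessner expansion for an axially symmetric tensor
#'
#' Reduces the five-term anisotropic spectral density to three Lorentzians.
#' With phi the angle between the N-H vector and the symmetry axis the
#' weights are `A0 = (3 cos^2 phi - 1)^2 / 4`, `A1 = 3 sin^2 phi cos^2 phi`,
#' `A2 = (3/4) sin^4 phi`, and `1/tau_k = 6 Dperp + k^2 (Dpar - Dperp)`.
#'
#' @param tensor a [diffusion_tensor()] object.
#' @param nh_unit_vector unit 3-vector (molecular frame).
#' @param S2 optional order-parameter scaling applied in [jw_aniso()].
#' @return object of class `SpectralDensityExpansion` with `weights`
#'   (summing to 1) and `times` (s).
#' @export
expand_axial <- function(tensor, nh_unit_vector, S2 = NULL) {
  v <- nh_unit_vector
  nrm <- sqrt(sum(v^2))
  if (abs(nrm - 1) > 1e-6) stop("'nh_unit_vector' must have unit norm")
  u <- axis_vector(tensor$alpha, tensor$beta)
  cphi <- sum(v * u) / nrm
  w <- woessner_weights(cphi)
  k <- 0:2
  times <- 1 / (6 * tensor$Dperp + k^2 * (tensor$Dpar - tensor$Dperp))
  structure(list(weights = w, times = times, S2 = S2),
            class = "SpectralDensityExpansion")
}

# weights from cos(phi); vectorized over cphi, returns length(cphi) x 3
woessner_weights <- function(cphi) {
  c2 <- cphi^2
  s2 <- 1 - c2
  cbind((3 * c2 - 1)^2 / 4, 3 * s2 * c2, 0.75 * s2^2)
}

#' Anisotropic spectral density from a Woessner expansion
#'
#' `J(w) = (2/5) sum_k A_k tau_k / (1 + (w tau_k)^2)`, multiplied by `S2`
#' when the expansion carries one.
#'
#' @param expansion an [expand_axial()] object.
#' @param omega angular frequency (rad/s); vectorized.
#' @return spectral density (s).
#' @export
jw_aniso <- function(expansion, omega) {
  tau <- expansion$times
  A <- as.vector(expansion$weights)
  j <- vapply(omega, function(w)
    (2 / 5) * sum(A * tau / (1 + (w * tau)^2)), numeric(1))
  if (!is.null(expansion$S2)) j <- j * expansion$S2
  j
}

# J at the five relaxation frequencies for many residues at once.
# cphi: vector of cos(angle to symmetry axis); returns list of J vectors.
jw_axial_all <- function(Dperp, Dpar, cphi, omegaH, omegaN, S2 = 1) {
  A <- woessner_weights(cphi)                      # n x 3
  k <- 0:2
  tau <- 1 / (6 * Dperp + k^2 * (Dpar - Dperp))    # 3
  om <- c(0, omegaN, omegaH - omegaN, omegaH, omegaH + omegaN)
  f <- outer(tau, om, function(t, w) t / (1 + (w * t)^2))  # 3 x 5
  J <- (2 / 5) * S2 * (A %*% f)                    # n x 5
  list(J0 = J[, 1], JN = J[, 2], JmHN = J[, 3], JH = J[, 4], JpHN = J[, 5])
}

#' Predict relaxation rates from a spectral-density model
#'
#' Evaluates the rigid-tumbling predictions
#' \deqn{R1 = d^2/4 [J(wH-wN) + 3 J(wN) + 6 J(wH+wN)] + c^2 J(wN)}
#' \deqn{R2 = d^2/8 [4J(0) + J(wH-wN) + 3J(wN) + 6J(wH) + 6J(wH+wN)]
#'       + c^2/6 [4J(0) + 3J(wN)]}
#' \deqn{NOE = 1 + d^2/(4 R1) (gH/gN) [6J(wH+wN) - J(wH-wN)]}
#' \deqn{eta_xy = p deltaN [4J(0) + 3J(wN)] (3 cos^2 theta - 1)}
#' The R2 prediction excludes exchange (Rex = 0); eta_xy is the
#' J(0)/J(wN)-truncated form.
#'
#' @param jfun spectral density function of one argument omega (rad/s), e.g.
#'   `function(w) jw_isotropic(w, tauC)` or a closure over [jw_aniso()].
#' @param field a [make_field_context()] object.
#' @return list with `R1`, `R2`, `NOE`, `eta_xy`.
#' @export
predict_rates <- function(jfun, field) {
  f <- field
  J0 <- jfun(0); JN <- jfun(f$omegaN)
  JmHN <- jfun(f$omegaH - f$omegaN); JH <- jfun(f$omegaH)
  JpHN <- jfun(f$omegaH + f$omegaN)
  rates_from_J(J0, JN, JmHN, JH, JpHN, f)
}

# core rate expressions given the five spectral-density values (vectorized)
rates_from_J <- function(J0, JN, JmHN, JH, JpHN, field) {
  f <- field
  k <- f$constants
  R1 <- (f$d^2 / 4) * (JmHN + 3 * JN + 6 * JpHN) + f$c^2 * JN
  R2 <- (f$d^2 / 8) * (4 * J0 + JmHN + 3 * JN + 6 * JH + 6 * JpHN) +
    (f$c^2 / 6) * (4 * J0 + 3 * JN)
  NOE <- 1 + (f$d^2 / (4 * R1)) * (k$gammaH / k$gammaN) * (6 * JpHN - JmHN)
  th <- k$theta * pi / 180
  eta_xy <- f$p * f$deltaN * (4 * J0 + 3 * JN) * (3 * cos(th)^2 - 1)
  list(R1 = R1, R2 = R2, NOE = NOE, eta_xy = eta_xy)
}

#' R2/R1 ratio from the correlation time, and its inverse
#'
#' Low-frequency approximation `R2/R1 = (2/3)(wN tauC)^2 + 7/6`, exact to
#' better than 1 percent for slow tumbling because the J(0)/J(wN) prefactors
#' of R2 and R1 share the factor (3 d^2 + 4 c^2)/24 vs /4.
#'
#' @param tauC correlation time (ns).
#' @param field a [make_field_context()] object.
#' @return dimensionless ratio.
#' @export
r2r1_from_tauc <- function(tauC, field) {
  if (any(tauC <= 0)) stop("'tauC' must be positive (ns)")
  (2 / 3) * (field$omegaN * tauC * 1e-9)^2 + 7 / 6
}

#' @rdname r2r1_from_tauc
#' @param ratio R2/R1 ratio, must exceed 7/6.
#' @return tauC in ns.
#' @export
tauc_from_r2r1 <- function(ratio, field) {
  if (any(ratio <= 7 / 6)) stop("ratio must exceed 7/6")
  sqrt((ratio - 7 / 6) * 3 / 2) / field$omegaN * 1e9
}

#' Correlation time from the cross-correlated relaxation rate
#'
#' `tauC = 5 eta_xy / (8 S^2 p deltaN (3 cos^2 theta - 1))`, the
#' J(0)-truncated inversion of the eta_xy expression; S^2 corrects for fast
#' N-H librations (default 0.88, the calibrated value for structured
#' backbone).
#'
#' @param eta_xy cross-correlated transverse relaxation rate (s^-1).
#' @param S2 order parameter in (0, 1].
#' @param field a [make_field_context()] object.
#' @return tauC in ns.
#' @export
tauc_from_etaxy <- function(eta_xy, S2 = 0.88, field) {
  if (any(eta_xy <= 0)) stop("'eta_xy' must be positive")
  if (S2 <= 0 || S2 > 1) stop("'S2' must be in (0, 1]")
  th <- field$constants$theta * pi / 180
  geo <- 3 * cos(th)^2 - 1
  if (abs(geo) < 1e-12) stop("theta at the magic angle: eta_xy carries no tauC information")
  5 * eta_xy / (8 * S2 * field$p * field$deltaN * geo) * 1e9
}

#' Conformational exchange from paired R2 and eta_xy
#'
#' `Rex = R2 - [(3 d^2 + 4 c^2) / (2 sqrt(3) c d (3 cos^2 theta - 1))] eta_xy`
#' with the uncertainty propagated in quadrature. The bracket converts
#' eta_xy into the exchange-free part of R2 (both share the 4J(0)+3J(wN)
#' combination); the high-frequency dipolar terms of R2 are neglected.
#'
#' @param R2 transverse rate (s^-1); vectorized.
#' @param eta_xy CCR rate (s^-1).
#' @param field a [make_field_context()] object.
#' @param sigma_R2,sigma_eta one-SD uncertainties (s^-1).
#' @return list with `Rex` and `sigma` (s^-1).
#' @export
rex_from_r2_etaxy <- function(R2, eta_xy, field, sigma_R2, sigma_eta) {
  if (any(sigma_R2 <= 0) || any(sigma_eta <= 0))
    stop("uncertainties must be positive")
  th <- field$constants$theta * pi / 180
  geo <- 3 * cos(th)^2 - 1
  fac <- (3 * field$d^2 + 4 * field$c^2) /
    (2 * sqrt(3) * field$c * field$d * geo)
  list(Rex = R2 - fac * eta_xy,
       sigma = sqrt(sigma_R2^2 + (fac * sigma_eta)^2))
}

#' @export
print.DiffusionTensor <- function(x, ...) {
  cat(sprintf(
    "Axially symmetric diffusion tensor\n  Dperp = %.3e s^-1, Dpar = %.3e s^-1 (zeta = %.3f)\n  tauC = %.2f ns, axis alpha = %.1f deg, beta = %.1f deg\n",
    x$Dperp, x$Dpar, x$zeta, x$tauC, x$alpha, x$beta))
  invisible(x)
}
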