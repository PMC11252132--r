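---
title: "Models and methods behind spindyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spindyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spindyn` turns backbone amide ¹⁵N relaxation measurements and coordinate
models into a quantitative picture of how a multi-domain protein moves in
solution: how fast and how anisotropically it tumbles, whether its domains
diffuse semi-independently, where µs–ms conformational exchange occurs,
and how its conformational ensemble partitions into discrete side-chain
rotamer states. This vignette describes the models, the tunable
parameters, the synthetic-data generators the tests rest on, and the
numerical and design choices, in that order.

## The relaxation model

For an amide ¹⁵N–¹H spin pair, the longitudinal rate R1, transverse rate
R2, steady-state ¹⁵N-{¹H} NOE and the CSA/dipole transverse
cross-correlated relaxation rate η_xy are linear combinations of the
spectral density J(ω) evaluated at 0, ω_N, ω_H−ω_N, ω_H and ω_H+ω_N
(frequency magnitudes; the sign of the ¹⁵N gyromagnetic ratio enters only
through the NOE, which is why the NOE sits below 1 for slow tumbling).
The interaction constants are assembled in `make_field_context()` from
`physical_constants()`:

* γ_N = −27.116×10⁶ rad s⁻¹ T⁻¹, γ_H = 267.522×10⁶ rad s⁻¹ T⁻¹;
* r_NH = 1.02 Å, giving the dipolar constant d = μ₀hγ_Nγ_H/(8π²r³);
* Δσ = 172 ppm and θ = 17° (angle between the N–H bond and the unique CSA
  axis), giving c = Δσ·ω_N/√3 and the cross-correlation constants
  p = d/(2√2) and δ_N = c/√6.

Two of the printed cross-term definitions deserve a note. The dipolar
cross-correlation constant is implemented as p ∝ γ_H·γ_N (magnitudes): a
γ_H·γ_H version would break the algebraic identity p·δ_N = c·d/(4√3) on
which the exchange-free consistency of R2, η_xy and the Rex equation
rests, and that identity is unit-tested. Likewise the effective
correlation time of a diffusion tensor is τ_C = 1/(2·tr **D**): the
reciprocal is required dimensionally and is what reproduces a 26.5 ns
τ_C from components (D⊥, D∥) = (0.56, 0.77)×10⁷ s⁻¹.

### Anisotropic tumbling

For an axially symmetric rotational diffusion tensor the spectral density
is the three-term Woessner expansion implemented in `expand_axial()` /
`jw_aniso()`: weights A₀ = (3cos²φ−1)²/4, A₁ = 3sin²φcos²φ,
A₂ = (3/4)sin⁴φ and correlation times 1/τ_k = 6D⊥ + k²(D∥−D⊥), with φ the
angle between the N–H vector and the symmetry axis. These closed forms are
not taken on faith: the test suite propagates anisotropic rotational
Brownian motion step by step in the body frame and checks that the
simulated P2 orientational correlation function matches Σ A_k e^(−t/τ_k)
(Monte-Carlo oracle), in addition to the exact isotropic-limit and
weight-normalization properties.

### Scalar shortcuts and their accuracy

Two scalar relations connect observables to τ_C without a tensor fit:

* R2/R1 = (2/3)(ω_N τ_C)² + 7/6. On rates truncated to their J(0) and
  J(ω_N) terms this is exact — the prefactor (3d²+4c²)/24 over
  (3d²+4c²)/4 is exactly 1/6 — and the package asserts that identity to
  machine precision. Against the full expressions the relation is good to
  about 1.2 % (1.14 % at 900 MHz, 1.28 % at 800 MHz, nearly independent of
  τ_C in the slow-tumbling regime), the residual being R1's
  high-frequency dipolar fraction (d²/4)[J(ω_H−ω_N)+6J(ω_H+ω_N)]/R1.
  We quote <2 % as the honest bound; a sub-1 % claim would require
  dropping the high-frequency terms from both sides.
* τ_C = 5η_xy/(8S²pδ_N(3cos²θ−1)), the J(0)-only inversion of η_xy. The
  neglected 3J(ω_N) term contributes 100·3J(ω_N)/(4J(0)) ≈ 0.3 % at
  τ_C ≈ 28 ns and 900 MHz, below 1 % for τ_C ≥ 20 ns, which the tests pin.

Because the two shortcuts carry opposite-signed biases (+0.3 % on the CCR
route, −0.9 % on the ratio route), tensors fitted from CCR-derived
pseudo-ratios sit systematically ≈1.2 % above tensors fitted from the
same molecule's R2/R1 data even on noiseless synthetic input. This is an
intrinsic property of the truncations, not noise; CCR-pathway fits are
therefore flagged for qualitative use, and the cross-pathway agreement is
asserted at 2 %.

## Stage 1: rates from peak tables

`fit_monoexponential()` fits A·e^(−Rt) by nonlinear least squares
(`stats::nls`, Levenberg–Marquardt fallback) with the rate uncertainty
taken from the covariance matrix; duplicate relaxation delays are ordinary
repeated observations. Unit weights are the default — covariance-based
errors already assume homoscedastic residuals — with 1/σ² weighting
available. The NOE is the saturated/reference intensity ratio with
base-plane noise propagated in quadrature; σ inputs are user-supplied
because base-plane noise estimation happens upstream in peak-integration
software. η_xy = −ln(I^β/I^α)/(2Δ) from TROSY/anti-TROSY pairs, its error
seeded from the zero-delay α/β discrepancy; because two repeats make a
crude estimator, `regularize_ccr_errors()` averages the σ of two datasets
and floors the result at 5 % relative — an idempotent operation. Chemical
shift perturbations combine ¹H and ¹⁵N differences as
√(Δδ_H² + (0.16Δδ_N)²).

## Stage 2: residue selection, tensor fit, uncertainties

Selection applies four screens in a fixed order (relative ratio error by
dataset kind: 10 %/15 %/25 % for 900 MHz, 800 MHz and CCR; backbone-N
B-factor ≤ 35 Å²; a user-supplied spectral-overlap exclusion list, empty
for synthetic data; and a single-pass trim of ratios beyond 2 SD — 1.7 SD
for CCR — of the survivors' mean). The trim statistics are computed after
the first three screens, matching the listed order; the trim is not
iterated. Every removal is written to an audit table with the criterion
that fired.

The fit minimizes Σ[(ρ_i − ρ_pred,i)/σ_i]² with ρ_pred from the full
R2/R1 expressions under the Woessner density — the ratios are compared
directly rather than through a linearized transformation, which is
equivalent in the nanosecond-τ_C regime and easier to verify. The
optimizer is a 12×12 (α, β) grid seeded from the isotropic solution
(D from the mean ratio), Nelder–Mead refinement of the best four starts
(relative tolerance 10⁻¹⁰), and two BFGS polish passes with 10⁻⁷
finite-difference steps; D⊥ and D∥ are optimized in log space to stay
positive. Noiseless synthetic data are recovered to ~10⁻¹⁴ relative.

An axial tensor's symmetry axis is only defined up to sign, so one can
always report β ∈ [0°, 90°], but α then genuinely spans [0°, 360°); the
package reduces α mod 180° only in the degenerate β = 90° case (and sets
α = 0 at β = 0, where the axis azimuth is meaningless). Near-isotropic
fits (|ζ−1| < 0.02) additionally warn that the orientation is undefined.

Parameter uncertainties use delete-d resampling: 100 refits on random
subsets with d = 20 % of residues removed, warm-started from the full
solution, and SDs scaled by √(n/d) = √5. Angular SDs are computed
circularly. The scaling was checked two ways: the raw resample spread
between d = 20 % and d = 5 % follows the subsampling prediction
√((d₁/m₁)/(d₂/m₂)) ≈ 2.18 within Monte-Carlo error, and the scaled
uncertainty brackets the true replicate-to-replicate SD conservatively
(the √(n/d) prescription slightly exceeds the asymptotic √((n−d)/d),
which errs on the safe side). Deletion fractions of 0.5 and above are
rejected: subsets that small no longer support a stable four-parameter
fit.

`compare_domain_tensors()` reports per-parameter z-like scores using the
combined scaled uncertainties and calls two fits "distinct" when both D⊥
and D∥ differ by more than 2 combined SD — deliberately simple machinery
for a deliberately qualitative verdict.

## Exchange mapping

Rex = R2 − [(3d²+4c²)/(2√3·c·d·(3cos²θ−1))]·η_xy with quadrature error
propagation; residues with Rex/σ > 5 are flagged. On algebraically
consistent (R2, η_xy) pairs the residual is not exactly zero but the
high-frequency dipolar part of R2, about 10⁻⁴ of R2 at 26.5 ns / 900 MHz;
the tests assert |Rex| < 10⁻³·R2 and exact additivity of injected
exchange.

## Stage 3: ensembles

Superposition (`align_ensemble()`) is an iterated-mean rigid-body fit on
the C-alpha atoms of configured core stretches (defaults 344–467, 484–500,
510–562 — a rigid, high-confidence domain core), run to a fixed point
(tolerance 10⁻¹² Å, minimum two mean refinements). Because that fixed
point is only defined up to a global rigid transform, the final frame is
canonicalized (mean-core centroid at the origin, principal axes on
x/y/z with a deterministic sign convention), which makes alignment
idempotent and model-order independent and the PCA scores invariant under
arbitrary rigid pre-transformations of the input models.

PCA (`run_pca()`) is mean-centred covariance PCA — no mass weighting, no
variance scaling — on the flattened Cartesian coordinates of the analysis
selection, computed by SVD. Backbone selections take N, CA, C, O within
the analysis ranges; side chains of configured residues can be added, and
`detect_multirotamer()` offers a circular-bimodality screen (minor-mode
fraction ≥ 5 %, circular separation ≥ 60° by default) for choosing them,
since "residues with multiple χ2 rotamers" is inherently data-dependent.
Extreme structures along a component are the observed score extrema
inverse-transformed through the loading.

State assignment uses two probe dihedrals (a tryptophan χ2 with
outward/inward anchors +80°/−100°, a tyrosine χ1 with anchors −93°/+57°)
and classifies each model to the circularly nearest anchor — equivalent
to fixed boundaries at the circular midpoints. Fixed thresholds were
chosen over k-means-style clustering for exact reproducibility; with
rotamer modes this far apart the two coincide in practice. States are
labelled I (out, χ1 at −93°), II (out, +57°), III (in, −93°),
IV (in, +57°), and populations are model fractions. Dihedrals follow the
IUPAC sign convention, verified against three independent formulations
(a projection construction, the normal-vector triple product, and
bio3d's torsion routine).

## Structure-based predictors

`place_amide_hydrogens()` positions H on the external bisector of the
C(i−1)–N and CA–N directions in their common plane at 1.02 Å — a
geometric rule rather than a re-implementation of any particular proton
builder's heuristics; the orientation difference for regular backbone is
a few degrees and is absorbed by the fit errors. Prolines and chain
N-termini are skipped, residues with missing backbone atoms are flagged
rather than fatal.

`bead_model_tensor()` computes rigid-body hydrodynamics for identical
beads at the C-alpha positions: a 3N×3N Rotne–Prager–Yamakawa mobility
matrix (with the overlapping-bead form below contact distance) is
inverted to a friction matrix, assembled into the 6×6 rigid-body
resistance, volume-corrected for rotation, and the rotational diffusion
block is taken from the origin-independent Schur complement. The
symmetrized tensor is axially reduced by treating the eigenvalue most
separated from the other two as D∥. Only the anisotropy and axis are
shape-determined; the default 5 Å bead radius is configurable, and for
compact shapes the anisotropy is radius-insensitive (tested at 2 % over
3–7 Å on a spherical shell) while elongated rods are genuinely
radius-sensitive, so no invariance is claimed there.

`empirical_tauc()` is the simple mass rule τ_C = k·MW·(η_w(T)/η_w(298 K))
·(298/T) with k = 0.61 ns/kDa — an explicit calibration constant for an
H6-tagged two-domain construct of ≈43.6 kDa in dilute aqueous buffer
(the underlying published mass→τ_C relation is not reproduced in print,
so the linear rule with a visible constant was adopted; both the constant
and the construct mass are arguments, not assumptions).

## The synthetic-data generators

`simulate_relaxation_dataset()` draws noiseless rates from the forward
model (full rate expressions, Woessner density, global S² = 0.88 scaling),
adds injected exchange to R2, then Gaussian noise as the last step, and
emits the decay curves and TROSY/anti-TROSY pairs that reproduce those
rates — so every estimator in stage 1 has an exact inverse relationship
with the generator at zero noise, and the full pipeline (decays → rates →
selection → tensor) closes on the generating tensor. Defaults mirror the
study conditions the package targets: (D⊥, D∥, α, β) =
(0.56×10⁷ s⁻¹, 0.77×10⁷ s⁻¹, 11°, 59°), 900 and 800 MHz fields, the
published relaxation-delay schedules, Δ = 0/10 ms CCR delays, S² = 0.88.
Sample-degradation drift is not modelled by default; noise is independent
Gaussian per observable.

`simulate_ensemble()` builds a deliberately minimal two-domain C-alpha
polymer: domain A fixed on a gentle helix, domain B rotated about a hinge
by per-model angles (±12° cluster centres, 2° SD), plus two four-atom
dihedral probes whose rotamer states are drawn from configurable
fractions — defaulting to 0.555/0.083/0.350/0.011, the published
four-state populations — with the hinge cluster following the probe-A
rotamer with probability `coupling`. Per-residue confidence values are
state-dependent on the probes. The geometry has no sterics and no
side-chain packing: it reproduces the *statistical* structure the PCA
stage consumes (two hinge clusters, a coupled binary rotamer, four joint
states, confidence/state correlation), not molecular realism. Passing
tests therefore demonstrate that the analysis machinery recovers known
ensemble structure, not that real predicted ensembles have that
structure.

## Problem sizes and tolerances used in the checks

The shipped tests and the acceptance script run at sizes chosen to make
the statistics meaningful on a single CPU in minutes: 100–120 amide
vectors per synthetic dataset, 50 seeded replicates at 3 % ratio noise
for the ±2 SD coverage study, 100–250 resampling repeats, 400 decay-fit
Monte-Carlo draws, and 2000-model ensembles for population recovery
(binomial 3 SD criterion). Statistical tolerances are set from the
corresponding sampling distributions (e.g. ±0.35 on an SD ratio estimated
from 250 repeats), not tuned to outcomes.

## Known limitations

* No per-residue model-free fitting (S², τ_e) and no relaxation-dispersion
  modelling; internal dynamics enter only through the global S² of the
  CCR pathway.
* Only the axially symmetric tensor is fitted; fully anisotropic
  three-component fitting is out of scope.
* The untruncated η_xy expression is not implemented; all CCR relations
  use the J(0) (and, where stated, J(ω_N)) truncation, with the ≈1.2 %
  systematic consequences described above.
* The bead model is C-alpha-level with identical radii; atomic-shell
  hydrodynamics would sharpen absolute D values, which the package
  deliberately does not interpret.
* Multi-model PDB is the only ensemble interchange format; per-residue
  confidence is read from the B-factor column by convention.
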