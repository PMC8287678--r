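---
title: "Methods: wall-shear metrics, spectrogram digitization and the case-control pipeline"
author: "wallshear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall-shear metrics, spectrogram digitization and the case-control pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, numerical choices and design
decisions behind the package, in the spirit of a methods section: what
is computed, under which assumptions, which knobs matter, and what the
synthetic generators do and do not emulate.

## 1. The haemodynamic model

Blood is treated as an incompressible Newtonian fluid (density
1056 kg/m³, dynamic viscosity 0.0035 Pa·s — `blood_properties()`), and
the vessel wall as rigid with no-slip flow. The package does not solve
the flow; it post-processes a time-resolved wall-shear vector field
`wss_i(t)` given per mesh vertex over one cardiac cycle of duration `T`.

Three per-vertex quantities are derived:

* **TAWSS** — `(1/T) ∫ |wss_i| dt` (Pa), the time-averaged magnitude.
* **OSI** — `½ (1 − |∫ wss_i dt| / ∫ |wss_i| dt)`, a dimensionless
  measure of directional fluctuation, 0 for unidirectional shear and
  0.5 for perfect reversal. Where the whole trajectory is zero the OSI
  is undefined and masked (`NA`), not zero-filled.
* **WSSG** — the tangential gradient of TAWSS, decomposed in the local
  `(p, q)` frame: `p` is the time-averaged WSS direction projected into
  the tangent plane, `q = n × p`. The magnitude is
  `sqrt((∂τ/∂p)² + (∂τ/∂q)²)` (Pa/mm). The *sign* is that of the
  `p`-component alone: positive where TAWSS grows along the flow
  direction (acceleration zone), negative where it decays (recovery
  zone). The `q`-component contributes magnitude but not sign, since
  "gradient in the same direction as the WSS vector" is naturally read
  as a positive projection on `p`.

Units are fixed: coordinates in mm, stresses in Pa, so gradients are
natively Pa/mm.

### Region definitions

Per subject, metrics are averaged over the *high-WSS region*: vertices
of a circular patch (default radius 5 mm) centred on the bifurcation
apex whose TAWSS reaches the patch's 98th percentile. Three conventions
deserve explicit statement because each had open alternatives:

* **Patch distance** defaults to geodesic (Dijkstra on the edge graph):
  a straight-line ball of 5 mm centred at the apex can capture the
  opposite branch wall through empty space, which a surface distance
  cannot. Euclidean distance remains available (`metric = "euclidean"`).
* **Percentile convention**: linear interpolation between order
  statistics (R's default type 7), with "in the 98th percentile" read
  as TAWSS ≥ P98. The percentile is computed over the patch (not the
  branch or the whole model); this is configurable because the source
  convention is ambiguous.
* **Averaging** is area-weighted, each vertex carrying one third of its
  incident triangle area. This makes region averages robust to
  irregular triangulation; plain vertex means are available as a
  sensitivity switch (`area_weighted = FALSE`).

Gradient measurements are restricted to the daughter branch whose patch
vertices attain the higher maximum TAWSS ("max within patch" was chosen
over the mean because a single impingement peak is what distinguishes
branches; ties break deterministically to branch1 with a warning).
Vertices with an undefined frame (zero mean shear) or undefined gradient
are excluded from region averages rather than imputed.

## 2. Discretization choices

* **Cycle integrals** use trapezoidal quadrature on the samples as
  provided, uniform or not. A solver's internal time step is metadata;
  only the exported samples matter. At the default 32 samples per cycle
  the trapezoid error on smooth pulsatile waveforms is well below other
  error sources; tests use up to 2001 samples where analytic limits are
  asserted tightly.
* **Surface gradients** use a one-ring least-squares fit: field
  differences over the neighbours are regressed on the neighbour
  offsets expressed in an orthonormal tangent basis at the vertex. The
  scheme is exact for fields affine in the tangent coordinates of a
  planar mesh (a property the tests assert to 1e-10) and degrades
  gracefully on curved, irregular rings. Vertices with fewer than two
  non-collinear neighbours (rank-deficient fit, singular-value ratio
  below 1e-8) are flagged undefined.
* **Degenerate triangles** below 1e-12 mm² are dropped (or rejected) at
  construction; repeated-vertex triangles are always rejected.
* **Orientation** of synthetic meshes is made globally consistent by a
  flood fill over shared edges, then flipped outward using the trunk's
  radial direction as reference.

## 3. The Womersley oracle

As an exact reference for the cycle integrals the package evaluates the
classical pulsatile-pipe-flow solution: for a steady pressure gradient
`G` the wall shear is the Poiseuille value `G·R/2`; each harmonic `n`
contributes a term built from complex-argument Bessel functions `J₀`,
`J₁` at the Womersley number `α = R·sqrt(nωρ/μ)`. The Bessel functions
are evaluated by their power series, which is accurate and stable for
the moderate `|z|` of arterial Womersley numbers (α ≈ 2–3 for the MCA);
tests pin the steady limit to 1e-12 and the α → 0 quasi-steady limit to
1%.

## 4. Spectrogram digitization

The digitizer converts a spectral-Doppler image into the maximal
velocity envelope: per image column, the topmost pixel above the
baseline whose intensity reaches a threshold (default 20% of the image
maximum), converted to cm/s by the user-supplied axis calibration.
Calibration is deliberately *not* auto-detected: on-screen axis layouts
are device-specific, whereas scale factors are trivially read off once
per device.

Robustness choices: an isolated bright pixel does not define the
envelope — the envelope pixel must head a vertical run of at least
`min_run = 3` super-threshold pixels (speckle rejection); the envelope
is median-smoothed over 5 columns; signal-free columns are linearly
interpolated from their neighbours. Only antegrade flow (above the
baseline) is digitized. These defaults are declared package choices —
the thresholds of the original acquisition tooling are unknown — and
the round-trip error budget under them is part of the test suite
(noiseless recovery within one velocity quantum; ≤ 2% of Vps under 5%
speckle).

Cycle cropping finds the period as the normalized-autocorrelation
maximum beyond the first negative dip (signals that never dip are
declared aperiodic), then starts the cycle at end-diastole (the minimum
within the first period). Indices follow clinical definitions: Vps is
the cycle maximum, Ved the velocity at the cycle end (end-diastolic by
definition; a global-minimum variant is available), Vm the trapezoidal
time average. Exported inlet profiles are two-column ASCII (s, m/s) at
fixed 9-decimal precision, and re-import reproduces the file
byte-identically.

## 5. Synthetic generators

The generators replace the two unavailable inputs — solver output and
patient data — with controlled objects whose ground truth is known.

**Bifurcation surface** (`make_bifurcation_mesh`): trunk cylinder,
junction collar closed by an explicit flow-divider ridge (the apex
vertex sits at its midpoint), and two cylindrical daughter branches;
every vertex is labelled trunk/branch1/branch2, with the junction
collar assigned to the trunk (it is the divider region, not a branch).
Defaults: 2.5 mm trunk, 2.0/1.8 mm branches, 90° between branches,
0.4 mm target edge length.

**Zonal wall-shear field** (`make_zonal_wss_field`): TAWSS as a
function of geodesic distance `s` from the apex — linear rise from
`tau_impingement` to `tau_peak` at `peak_distance`, then exponential
decay with scale `decay_length` — expressing the canonical
impingement/acceleration/recovery zones. The shear direction is the
tangent direction of increasing `s` (down-branch flow); the magnitude
is modulated by `1 + pulsatility·sin(2πt/T)` and reversed during the
final `reversal_fraction` of the cycle, which makes the OSI
approximately equal to that fraction. The `case_like` preset puts the
peak at 7 mm — beyond the 5 mm patch — so the high-WSS region falls in
the acceleration zone (positive dirWSSG); `control_like` uses a shallow
impingement dip (95 → 110 Pa) peaking at 1.5 mm, inside the junction
collar, so the branch's high-WSS region lies in the recovery zone
(negative dirWSSG). The control profile's shallow dip is deliberate: a
deep dip adjacent to a near-apex peak straddles the peak with the
sampled region and makes the discrete signed average an unstable
near-cancellation, which is a property of the *field design*, not of
the estimator.

What these fields do not emulate: secondary/swirling flow, inter-branch
asymmetry, wall compliance, measurement noise beyond optional
multiplicative speckle. Passing tests therefore demonstrate correct
*post-processing* of fields with known structure, not fidelity of any
flow solution.

**Cohort generator** (`make_cohort`): group-wise marginals calibrated
to the published 77-subject summaries. WSS and absWSSG are lognormal
(right-skewed stress metrics; median matched exactly, σ solved from the
IQR width in closed form). The signed WSSG is a two-component mixture:
a positive lognormal magnitude with probability `p` (23/38 cases,
14/39 controls) and a negative one otherwise; the component parameters
are solved in closed form so the *mixture's* quartiles match the
published q25/median/q75 exactly. OSI is a scaled beta on [0, 0.5]
fitted to the three quartiles with the median constrained exactly.

Two sampling-design decisions were made a priori for calibration
stability, and are worth stating because they change what the
generator's randomness means:

* direction counts are `round(p·n)` assigned by random permutation
  rather than i.i.d. Bernoulli draws — at the study sizes this
  reproduces the published 23/38 and 14/39 exactly;
* continuous draws use randomized stratified (Latin-hypercube-style)
  uniforms through the component quantile functions, making empirical
  quantiles O(1/n)-accurate instead of O(1/√n). Without this, the
  sample-median standard error of the heavy-tailed signed WSSG at
  n = 10,000 (≈ 0.29 Pa/mm) would be comparable to a 2% calibration
  check on a median of 11 Pa/mm, and a calibration test would mostly
  measure sampling noise.

Because WSSG and absWSSG marginals are calibrated independently (the
joint law is unpublished), individual rows may violate
`absWSSG ≥ |WSSG|`; the table validator reports this at warning level,
and `make_cohort` suppresses the check for its own output. Pipelines
that compute both quantities from one field always satisfy the bound.

## 6. The statistical pipeline

`casecontrol_analysis()` composes: Shapiro-Wilk-routed group
comparisons (Mann-Whitney U with exact small-sample p where tie-free,
normal approximation with tie correction otherwise; Student's t when
both groups pass normality at 0.05); Fisher's exact test
(probability-mass two-sided rule) with the Wald odds-ratio interval
`exp(log OR ± 1.96·SE)` (Haldane-Anscombe 0.5 correction on zero cells,
flagged); Spearman correlations with the t-approximation; univariate
logistic screens; the selection rule — keep univariate p < 0.1, then
among each significantly correlated pair (Spearman p < 0.05) keep the
smaller univariate p — which fully determines the final model, so no
iterative stepwise re-entry is implemented; the multivariate fit
(IRLS, tolerance 1e-8, max 100 iterations, separation flagged); and
ROC curves for the signed gradient and the fitted risk score, with the
Youden-J-optimal cutoff (ties toward higher sensitivity). "Uncorrelated"
is operationalized as Spearman p ≥ 0.05, a declared convention. AUC
equals the tie-corrected U statistic divided by `n₁·n₂`, an identity
the tests assert against an independent computation.

## 7. Problem sizes and verification scope

The test suite verifies: analytic cycle-integral limits at up to 2001
samples; gradient exactness on planar grids and convergence under
refinement; patch extraction against an independent Bellman-Ford
oracle; Fisher's exact test against full hypergeometric enumeration for
every 2×2 table with total ≤ 30; ROC-AUC against the U identity on 100
seeded datasets; logistic parameter recovery within 3 standard errors
at n = 5000; digitizer round trips on 20 seeded waveforms; generator
calibration at n = 10,000 per group (medians within 2%); and the
end-to-end pipeline at the study size (n = 38/39) across 50 seeds.
These sizes make the default suite complete in about a minute on one
core while keeping each check's statistical resolution well beyond the
tolerance it asserts.

## 8. Known limitations

* The gradient estimator is first-order on curved surfaces; magnitudes
  within ~1 edge length of the apex ridge mix the two branch walls.
* The zonal field is rotationally symmetric per branch; it cannot
  express azimuthal gradient structure (`∂τ/∂q` is essentially zero by
  construction, so absWSSG ≈ |WSSG| on synthetic subjects).
* The cohort generator matches marginals, not the joint dependence
  between metrics (beyond the sign/direction coupling); correlation
  screens on generated tables reflect that construction.
* Spectrogram digitization assumes a supplied calibration and antegrade
  flow above a horizontal baseline; aliased or retrograde content is
  ignored by design.
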