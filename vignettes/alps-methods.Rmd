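---
title: "Methods: the DTI-ALPS pipeline and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS pipeline and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsdti)
```

## The measurement model

Single-shell DWI is modelled per voxel by the single-tensor signal
equation \(S = S_0 \exp(-b\, g^\top D g)\), with \(D\) a symmetric
3×3 diffusion tensor (mm²/s), \(b\) the diffusion weighting (s/mm²) and
\(g\) a unit gradient direction. Taking logs makes the model linear in
\((\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz})\);
`design_matrix()` builds the corresponding encoding matrix and
`fit_tensor_volume()` solves the ordinary-least-squares problem for all
masked voxels at once by QR. OLS (rather than weighted LSQ or nonlinear
fitting) is this package's documented choice: it is deterministic,
admits an exact noiseless round trip (forward simulation followed by
fitting recovers any SPD tensor to machine precision, asserted at 1e-8
relative error in the tests), and can be cross-checked against an
independent least-squares route (`stats::lm()` on a formula-built
design) without sharing code with it.

The ALPS index uses the tensor **diagonal in the anatomical frame**, not
the eigenvalues:

\[
\mathrm{ALPS} \;=\;
\frac{\mathrm{mean}(D_{xx}^{proj},\, D_{xx}^{assoc})}
     {\mathrm{mean}(D_{yy}^{proj},\, D_{zz}^{assoc})}
\]

Both means are arithmetic; "mean" is unqualified in the method's
standard description, and the arithmetic reading keeps the index linear
in each input, which gives clean monotonicity properties (the tests
assert strict monotonicity in each argument and invariance under joint
rescaling). The axis convention is fixed: +x right, +y anterior,
+z superior (RAS-style); images are assumed already in this orientation
and no reorientation or gradient rotation is attempted. Measurements
follow the left-hemisphere convention — an ROI centred at positive x
triggers a warning rather than an error, since the geometry is still
well defined.

### Assumptions

* One tensor per voxel; no partial-volume or multi-compartment
  modelling. The perivascular contribution is treated as an additive
  component of \(D_{xx}\), which is exactly the quantity the ALPS ratio
  senses.
* The acquisition has at least one \(b=0\) volume and six non-collinear
  directions; rank of the encoding matrix is checked and a deficient
  direction set is reported with the offending directions.
* ROI placement is coordinate-based. Manual placement on a colour-FA map
  is how the index is produced clinically, but it is not reproducible in
  code; sphere centres in world millimetres are the package's interface,
  and the phantom generator emits the matching ROI config.

## Numerical choices

* **Signal clamping.** Log-linear fitting needs positive signals; values
  at or below zero (possible under Rician noise at high b) are clamped
  to `1e-6 * max(signal)` and the clamp count is reported. No eigenvalue
  clipping is applied to fitted tensors — the ALPS ratio consumes raw
  diagonals, and clipping would bias it; FA alone clips negative
  eigenvalues to zero before the normalised-variance formula and is then
  clamped to [0, 1].
* **Sphere membership.** A voxel belongs to an ROI iff its centre lies
  within `diameter/2` of the ROI centre, boundary inclusive (tolerance
  1e-9 mm to absorb float error). On the 2×2×2.5 mm grid a 5 mm sphere
  centred on a voxel centre selects exactly 7 voxels.
* **Dominance QC.** An ROI passes iff the principal eigenvector of its
  mean tensor has its largest absolute component on the expected axis.
  Two degenerate cases flag FALSE with a warning: a principal
  *eigenvalue* tie (relative gap below 1e-9, e.g. isotropic CSF, where
  the principal direction is undefined) and an exact component tie. Ties
  failing QC is the conservative choice; the index is still computed and
  reported with `qc_pass = FALSE`.
* **Degenerate statistics inputs.** Zero overall variance gives F = 0,
  p = 1 (explicitly, to avoid 0/0 float noise); constant covariates are
  dropped from the ANCOVA design, which then reduces exactly to one-way
  ANOVA (asserted in the tests); rows missing a variable are dropped
  from that test only, with a message.

## The phantom generator

`make_phantom()` lays out five compartments on a default 20×20×20 grid
of 2×2×2.5 mm voxels (the clinical ALPS acquisition grid): a z-dominant
projection block, a y-dominant association block, an x-dominant
subcortical block, an isotropic high-diffusivity CSF block
(3.0e-3 mm²/s) and an isotropic background (0.8e-3 mm²/s). Fibre
compartments use axial diffusivity 1.4e-3 and radial 0.4e-3 mm²/s,
typical white-matter values. All blocks sit in the left (negative x)
half; ROI spheres are emitted at the block centres.

The tunable parameters that matter:

* `perivascular_boost` (δ, mm²/s, default 0): added to \(D_{xx}\) in the
  projection *and* association blocks. The analytic index is then
  \((0.4\times10^{-3} + \delta)/0.4\times10^{-3}\), so ground truth
  stays closed-form for any δ; the end-to-end tests sweep
  δ ∈ {0, 0.2, 0.4, 0.6}·1e-3.
* `noise_sigma` (signal units, default 0): Rician noise, i.e. the
  magnitude of the complex signal with i.i.d. Gaussian noise of SD σ on
  each channel — the standard magnitude-MR model, which reduces to
  Gaussian at high SNR. With `s0 = 1000`, σ in the 10–40 range spans
  realistic clinical SNR.
* `nex` (default 3): number of independently noised excitations
  averaged, emulating repeated acquisitions rather than storing separate
  volumes.
* The direction set is a frozen 13-direction electrostatic-repulsion
  table plus one b = 0 volume at b = 1000 s/mm²; the acquisition
  literature for this method does not publish its direction set, so any
  well-spread non-collinear set is acceptable and a fixed one keeps runs
  reproducible.

The isotropic variant (`isotropic_phantom_spec()`) gives every
compartment the same tensor; its ALPS index is exactly 1, the
no-perivascular-component baseline, and this is the quantity
`scripts/acceptance.R` recomputes end to end.

## The cohort generator

`simulate_cohort()` draws subjects from a Gaussian copula: a latent
multivariate normal with unit variances, transformed margin by margin.
Only the pairwise rank correlations between the ALPS index and selected
variables are targeted (nuclear DNA −0.278, mitochondrial DNA −0.201,
MMSE 0.222, CASI 0.178, UPDRS II/III/total −0.238/−0.331/−0.307, the
values reported for this design); all other latent correlations are
zero, because no fuller joint dependence is published — the copula and
the zero fill-in are this package's documented assumptions. Latent
Pearson entries are set by \(r = 2\sin(\pi\rho_s/6)\), exact for the
Gaussian copula, and positive definiteness is checked at spec time.

Margins are Gaussian per group with the published means and SDs
(group sizes 47/25/25/38). Physically bounded variables (DNA ≥ 0, MMSE
in [0, 30], CASI/SE-ADL in [0, 100], HY in [0, 5]) use truncated-normal
quantile transforms whose *underlying* parameters are moment-matched so
the truncated distribution hits the target mean and SD (a plain
truncation of the published parameters would, for example, inflate the
control-group nuclear-DNA mean by ~14%). The transforms are monotone in
the latent normal, so the rank-correlation targets survive truncation
exactly; the tests assert recovery within ±0.03 at n = 10000. HY stages
are rounded to half steps afterwards; sex is Bernoulli per group ratio,
independent of the copula.

Two generator choices were genuinely open and are fixed here once:

* **ALPS group means** (NC 1.52, PDN 1.48, PD-MCI 1.42, PDD 1.38,
  SD 0.12): the source design reports group differences only as figures,
  not numbers. These values are in the range reported across the ALPS
  literature and reproduce the published significance pattern at the
  study's group sizes — NC vs PD-MCI and NC vs PDD Bonferroni
  significant, NC vs PDN not.
* **Domain z-score means** per group are set so that
  `classify_cognitive_status()` reproduces the generating label at the
  group mean: PD-MCI has two domains at −1.8 (impairment threshold
  z ≤ −1.5, boundary impaired) with MMSE ≈ 27; PDD has all domains well
  below threshold with MMSE = 20 (< 26, the dementia cut-off, with
  exactly 26 counting as not demented). UPDRS subscales and the total
  are drawn as separate margins, as they are reported; the additive
  identity total = I + II + III is *not* enforced.

The classifier itself follows the published wording literally: impaired
iff z ≤ −1.5; PDD iff more than one impaired domain *and* MMSE < 26;
else PD-MCI iff ≥ 2 impaired domains; else PDN. Note the literal rule
leaves single-domain impairment in PDN — single-domain MCI is excluded
by the wording, and the package implements (and documents) exactly that.

### What the synthetic data do and do not show

The phantom has rectangular compartments, no anatomy, no partial-volume
mixing, no eddy-current or motion artifacts, and a perivascular effect
that is additive by construction; passing the end-to-end oracle shows
the *estimator chain* is correct, not that the index is unbiased on real
anatomy. The cohort generator reproduces first and second marginal
moments and targeted pairwise rank correlations; it does not model
missingness patterns, site effects, or any dependence beyond those
pairs. Power and type-I results on these cohorts therefore validate the
statistical machinery under the published design, not clinical effect
sizes.

## The statistics battery

`run_group_analysis()` mirrors the standard analysis for this design:
one-way ANOVA for age; Pearson chi-square (no continuity correction) for
sex; ANCOVA `outcome ~ group + age + sex` for every clinical, cognitive,
DNA and ALPS outcome, with the group effect tested by the
extra-sum-of-squares F against the covariates-only model (Type II, no
interactions — the stated "covariates" model, and checkable by two
nested fits against a normal-equations oracle); Bonferroni post hocs
over the six pairwise adjusted-mean contrasts per outcome
(`p_adj = min(1, 6p)`; the family is the pairs within an outcome, not
across outcomes, matching how the correction is applied in this
literature); an additional ALPS ANCOVA over NC / early PD (HY ≤ 2,
boundary early) / late PD (HY > 2); and Spearman correlations (average
ranks; p from the t approximation with n − 2 df, with an exact
permutation mode for n ≤ 10 used as the oracle in tests). Adjusted means
are computed at the covariate means (proportional weighting over sex)
via emmeans. α defaults to 0.05.

Type-I calibration is asserted empirically: under simulated nulls, each
test's rejection rate at α = 0.05 lies within [3%, 7%] over 1000
replicates.

## Problem sizes

The default grids and replicate counts are chosen to keep every check
sharp at desk scale: 20×20×20 voxels for end-to-end phantom runs
(12×12×10 in unit tests), 100 random tensors for fit-recovery and
cross-route agreement, 1000 replicates for type-I calibration, 200
simulated cohorts at the study's group sizes for the power-style checks,
and n = 10000 per group for marginal and copula fidelity.

## Known limitations

* Single-shell, single-tensor only; no WLS/NLLS fit option.
* No image registration, eddy/motion correction, skull stripping or
  atlas-based ROI placement; inputs are assumed oriented and ROIs are
  coordinate-specified.
* Right-hemisphere and bilateral ALPS variants are out of scope.
* The cohort generator's unspecified joint dependencies are zero by
  assumption; real cohorts are more entangled (e.g. UPDRS subscales and
  their total).
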