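---
title: "Quantitative T2 relaxometry and myelin water fraction mapping with t2relax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T2 relaxometry and myelin water fraction mapping with t2relax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2relax)
```

## The measurement and the models

In a multi-echo T2-weighted acquisition the transverse magnetisation of a
voxel is sampled at a series of echo times TE. For a homogeneous voxel
the signal decays mono-exponentially,

$$S(TE) = S_0\, e^{-TE/T_2},$$

with the amplitude $S_0$ (proportional to proton density) and the tissue
time constant $T_2$ in milliseconds. Brain voxels are not homogeneous:
water trapped between myelin lamellae is tightly bound and relaxes very
fast (T2 around 20 ms), intra/extra-cellular water in white and gray
matter relaxes at roughly 80 ms, and free water (CSF) at seconds. A voxel
is therefore better described as a non-negative mixture of exponentials
on a small fixed basis,

$$S(TE) = S_0 \sum_i v_i\, e^{-TE/T_{2,i}}, \qquad
  v_i \ge 0,\; \textstyle\sum_i v_i = 1,$$

and the **myelin water fraction** (MWF) — the signal fraction $v$ at the
shortest basis T2 — is a widely used surrogate for myelin density. The
package fixes the basis at the literature values 20 / 80 / 2000 ms
(configurable via `compartmentBasis()`), and the default echo times are
the ten-echo protocol TE = 13, 16, 20, 25, 30, 40, 50, 85, 100, 150 ms.
All T2 and TE quantities are in milliseconds; amplitudes are unitless.

The forward models live in `predictMono()` and `predictMulti()` and are
deliberately noise-free: all stochasticity is confined to the synthetic
cohort generator, so the model layer is referentially transparent and
can be tested against closed-form oracles.

## Single-component fitting

`linearInit()` + `gaussNewtonFit()` implement the classical two-stage
estimator:

1. **Log-linear initialisation.** Taking logs turns the mono-exponential
   into a line, $\ln S = \ln S_0 - TE/T_2$, fitted by ordinary least
   squares. The log requires positive signals, so non-positive echoes
   are excluded *from the initialisation only*; with fewer than two
   usable echoes the fallback is $(S_0 = \max S,\ T_2 = 70\,\text{ms})$
   (70 ms is mid-range for adolescent white matter), and a non-negative
   slope — typical of CSF-like voxels, which are essentially flat over
   13–150 ms — initialises $T_2 = 2000$ ms.
2. **Gauss–Newton refinement** of the *original-space* sum of squared
   residuals, with Jacobian columns
   $\partial S/\partial S_0 = e^{-TE/T_2}$ and
   $\partial S/\partial T_2 = S_0 (TE/T_2^2) e^{-TE/T_2}$, iterating the
   normal-equations update until the residual change falls below `tol`
   or 500 iterations are reached. Log-space least squares and
   original-space least squares differ under noise; the second stage is
   the estimator, the first only its starting point.

Three numerical choices deserve a note, since the raw update is not
globally safe:

* **Step control.** A full update step can overshoot (increase the
  residual, or drive $T_2 \le 0$). Steps are backtracked by successive
  halving (up to 20 halvings, counted as a single iteration), so the
  residual norm is non-increasing along the iteration — a property the
  test suite asserts.
* **Damping.** When the 2×2 normal matrix has condition number above
  $10^{12}$, Levenberg damping $\lambda = 10^{-10}\,\mathrm{tr}(D^TD)$
  is added. This is the minimal departure from the plain update needed
  to survive degenerate voxels.
* **Normalisation.** An absolute residual-change tolerance is
  meaningless across arbitrary scanner intensity scales, so signals are
  normalised before fitting: a single curve by the magnitude of its
  first-echo signal, a volume by the mean first-echo magnitude over the
  mask (one shared scale, so the tolerance is comparable across the
  volume). `tol = 1e-6` applies on that normalised scale; reported
  amplitudes and residual norms are rescaled to original units.

`fitMonoVolume()` runs the identical engine vectorised across all masked
voxels (the per-curve and volume paths share one implementation and are
identity-tested against each other); unmasked voxels carry `NA`, and
downstream ROI statistics skip `NA` by contract.

## Multi-compartment fitting

With the basis fixed, the mixture model is linear in the compartment
amplitudes $a_i = S_0 v_i$, and the two simplex constraints plus a free
$S_0$ are simultaneously satisfiable in exactly one way: solve the
non-negative least-squares problem
$\min_a \lVert A a - S \rVert^2,\ a \ge 0$ with
$A_{ji} = e^{-TE_j/T_{2,i}}$, then set $S_0 = \sum_i a_i$ and
$v_i = a_i/S_0$. Non-negativity alone already yields sparse amplitude
vectors (unsupported compartments are driven exactly to zero), so no
additional regularisation is applied — none is warranted by the
three-point basis.

`nnlsFractions()` solves the NNLS problem by **exact support
enumeration**: for each of the $2^p-1$ column supports the unconstrained
least-squares solution is computed (vectorised across voxels in
`fitMultiVolume()`), infeasible supports are discarded, and the feasible
solution with minimal SSE is the global optimum. For a fixed 3-point
basis this is exact, deterministic and fast; iterative active-set
solvers can cycle on exactly representable curves (pure one-compartment
decays), which synthetic and masked real data produce routinely. The
test suite cross-checks the enumeration against an independent iterative
NNLS implementation on noisy curves and against a dense simplex-grid
search.

A voxel whose optimal amplitude vector is all-zero (flat-zero
background) is flagged *degenerate*: its fractions are `NA`, it is
excluded from ROI statistics, and `fitMultiVolume()` counts it in a QC
field.

`basisConditionReport()` quantifies why this inverse problem is
delicate: over a 13–150 ms echo range the 2000 ms column is nearly
constant and strongly correlated with the 80 ms column; the
column-normalised design has condition number ≈ 15. The long-T2 column
is retained because free-water signal must be absorbed by the longest
available decay time, but users changing the basis or echo times can
inspect the conditioning directly.

## ROI statistics

Tissue label images use the 3-class convention 0/1/2/3 =
background/CSF/GM/WM. `tissueVolumes()` converts voxel counts to liters
with the header voxel dimensions; intracranial volume is *defined* as
CSF + GM + WM, which in a 3-class segmentation is an identity (asserted,
not estimated). ROI summaries (`roiMapSummary()`) use the sample
standard deviation (n−1), matching the two-sample t machinery
downstream, skip `NA` voxels (unmasked or degenerate) and report the
valid count. `roiMeanCurve()` averages signals echo by echo — this is
the subject- or group-average white matter curve consumed by the
posterior analysis. Label transfer between grids
(`resampleLabelsNN()`) is nearest-neighbour only, so no label code can
be invented; registration estimation is out of scope (synthetic data
are generated co-registered).

## Posterior analysis of compartment fractions

`runChain()` samples the posterior of $(v, S_0)$ for a single
(ROI-averaged) curve with a Metropolis–Hastings scheme:

* **Proposal.** Fractions: $v' \sim \mathrm{Dirichlet}(\kappa v)$ with
  concentration scale $\kappa = 500$ by default; the asymmetric
  proposal density enters the Hastings ratio. Current fractions are
  floored at $10^{-4}$ (and renormalised) before scaling, keeping the
  proposal proper at the simplex boundary. The amplitude takes a
  log-normal random walk (1% step).
* **Prior.** Flat Dirichlet(1, 1, 1) on the fractions — no information
  is invented — and flat on $\log S_0$, so the amplitude walk needs no
  Jacobian correction.
* **Likelihood.** Gaussian in signal space with standard deviation
  $\sigma$ either supplied or estimated as the RMS residual of the NNLS
  fit to the same curve, held fixed during sampling (floored at
  $10^{-9} S_0$ so an exactly representable curve still yields a proper
  likelihood).
* **Schedule.** The chain is initialised at the NNLS point estimate,
  burn-in is discarded, and every $\lfloor n_\text{run}/n_\text{keep}
  \rfloor$-th state is retained. The default preset is the long
  protocol (100,000 burn-in, 100,000 iterations, 5000 kept);
  `chainConfig("test")` (2000 / 2000 / 500) runs in seconds and is the
  preset used throughout the tests and the default pipeline.

Two limiting behaviours validate the sampler: on an effectively
noiseless curve the posterior concentrates at the NNLS estimate (within
0.01 per compartment), and at very large $\sigma$ the retained samples
reproduce the flat Dirichlet prior (mean 1/3, marginal sd
$\sqrt{1/18}$). Identical seed, config and input give bitwise-identical
samples. Convergence diagnostics beyond the acceptance rate and the
retained trace are not claimed.

## Group statistics

`compareGroups()` performs two-sided two-sample Student's t-tests with
pooled variance ("standard Student's" is read as the pooled test; a
Welch flag exists). Significance is conventionally read at p < 0.05 and
no multiple-testing correction is applied by default; a Holm option is
available but clearly beyond the mirrored analysis.
`compareAdjusted()` fits `variable ~ group + covariate` and reports the
group coefficient: a group difference that is purely mediated by a
volume difference loses significance once the volume enters the model.
The default covariate is white matter volume; which volume measure to
adjust by is genuinely open, so it is a parameter, not a constant.

## The synthetic cohort generator

No public multi-echo cohort with the relevant demographics exists, so
the package ships a generator (`cohortSpec()`, `generateCohort()`) that
emulates a 63-subject study in four group × sex strata (16/27/10/10)
with stratum parameters recorded, value by value, in
`inst/extdata/cohort-defaults.yaml`:

* **Volumes.** Per-tissue volumes are drawn from truncated normals
  (truncation at zero). White matter means/SDs per stratum are the
  published values (0.38/0.35/0.43/0.37 l); GM and CSF means are not
  published numerically and are realistic choices documented in the
  config.
* **Composition.** Every white matter voxel of a subject decays as the
  subject's three-compartment mixture. The per-subject MWF is drawn
  from a truncated normal at the stratum mean; the free-water fraction
  is drawn around a stratum mean *calibrated* (`calibrateCsfFraction()`,
  a deterministic root-find over a quantile-quadrature expectation) so
  that the expected effective single-component T2 of the mixture equals
  the stratum target (69.5/68.7/67.8/66.8 ms). The effective T2 at zero
  free water has a floor — about 67.2 ms at MWF 0.25 on this basis and
  echo protocol — so per-subject T2 and MWF cannot be prescribed
  independently; the between-subject T2 spread is instead *emergent*
  from the compositional spread, and comes out at ≈ 3 ms, consistent
  with the published 2.6–3.6 ms. One consequence is documented
  honestly: the term-female target of 66.8 ms sits ~0.25 ms below the
  reachable floor, so that stratum generates at the floor (≈ 67.05 ms)
  and the term group mean sits ≈ 0.1 ms above its nominal target, well
  inside the across-seed spread.
* **Geometry.** Heads are schematic concentric shapes (CSF core, white
  matter interior, gray matter shell) built by ranking voxels by
  physical distance from the grid centre; per-tissue voxel counts match
  the drawn volumes exactly, so the label bookkeeping and
  `tissueVolumes()` agree to the voxel. ROI statistics depend only on
  label membership, not anatomy.
* **Grid and voxel scale.** The default grid is 24 × 24 × 12. A
  voxel-volume scale factor (default: automatic, the smallest factor
  fitting the largest plausible head into 85% of the grid) multiplies
  the nominal 2.5 × 2.5 × 3.0 mm voxel volume, and the emitted NIfTI
  pixdims are the nominal dimensions × scale^(1/3) — so voxel counting
  on the emitted labels returns true liters at every grid size. This
  keeps a full 63-subject cohort (≈ 4,700 head voxels per subject)
  generatable and fittable in seconds while preserving all volume
  semantics.
* **Noise.** Additive i.i.d. Gaussian noise, with σ set by the
  first-echo white matter SNR (default 150; the acquisition SNR is not
  published). The least-squares machinery is Gaussian-consistent;
  Rician magnitude noise is deliberately not modelled (see
  limitations).
* **Determinism.** Per-subject seeds derive from the spec seed; the
  same spec reproduces the cohort byte for byte. Group labels enter
  only through stratum parameters, never the noise or geometry code
  paths (asserted by a relabelling test).

`drawTruthTable()` exposes the distributional layer without rendering
images; the statistical calibration studies (null-cohort type-I error,
volume-mediated adjustment behaviour) run on it directly, since the
statistics under test consume the cohort table, not the images.

## What passing tests do and do not show

The generator reproduces the *summary statistics* of a real cohort
under the package's own forward model — the same model the estimators
fit. Recovery of the stratum values therefore validates the pipeline's
correctness (estimators, bookkeeping, statistics), not the biological
fidelity of three-pool relaxometry: real data add Rician noise,
partial-volume mixing at tissue boundaries, B1 inhomogeneity,
stimulated echoes and exchange between pools, none of which are
simulated. Conclusions about real cohorts rest on the published
literature for the model itself; the package's claim is that, given the
model, every computational step is right.

## Problem sizes and runtimes

Defaults were chosen so a laptop core handles everything comfortably:
the full default cohort (63 subjects, ≈ 300k voxel fits for each of the
two fitters) generates and fits in well under a minute; the test-preset
chain (2000/2000/500) samples in under a second; the test suite,
including a complete cohort recovery run and a 1000-replicate null
calibration, finishes in a couple of minutes. The long chain preset
(100k/100k/5000) remains the default `chainConfig()` for faithful
posterior work.
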