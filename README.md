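# t2relax

Quantitative T2 relaxometry for multi-echo brain MRI in R: voxelwise
single-component T2 mapping, three-compartment myelin water fraction
(MWF) estimation, ROI/volume statistics over tissue label images,
cohort-level group comparisons with covariate adjustment, and a
Metropolis–Hastings posterior analysis of compartment fractions — plus a
synthetic multi-echo cohort generator so the entire pipeline is testable
end to end without scanner data.

The intended users are neuroimaging researchers quantifying tissue
composition — in particular myelination — from multi-echo T2-weighted
acquisitions, e.g. when comparing preterm-born cohorts against term-born
controls.

## Models

A homogeneous voxel decays mono-exponentially,

```
S(TE) = S0 · exp(−TE / T2),
```

fitted per voxel by a log-linear initialisation followed by Gauss–Newton
refinement of the original-space least squares (backtracked steps,
residual-change stopping rule |Δr| < 1e−6, at most 500 iterations).
Heterogeneous voxels are modelled as a non-negative mixture of
exponential decays on a fixed T2 basis,

```
S(TE) = S0 · Σᵢ vᵢ · exp(−TE / T2ᵢ),   vᵢ ≥ 0,  Σᵢ vᵢ = 1,
```

with basis T2s of 20 / 80 / 2000 ms for myelin water, intra/extra-
cellular tissue water and free water (CSF). The amplitudes are solved by
exact non-negative least squares and normalised; the **myelin water
fraction is the fraction at 20 ms**. Group contrasts use pooled-variance
two-sample t-tests, optionally adjusted for a volume covariate via
`variable ~ group + covariate`; the posterior of the fractions for a
group-averaged white matter curve is sampled with Dirichlet proposals
and a flat Dirichlet prior. The methods vignette
(`vignettes/t2relax-methods.Rmd`) documents every model, parameter and
numerical choice.

## Worked example

Fit one noisy white-matter-like decay curve (ten echoes, true fractions
0.25 / 0.70 / 0.05, amplitude 1000, noise sd 5):

```r
library(t2relax)
te <- defaultEchoTimes()                 # 13, 16, ..., 150 ms
set.seed(7)
truth <- c(myelin = 0.25, tissue = 0.70, free = 0.05)
signal <- predictMulti(1000, truth, compartmentBasis(), te) + rnorm(10, 0, 5)
curve <- echoSeries(te, signal)

gaussNewtonFit(curve)      # single-component estimate
#> MonoFit: S0 = 889.511, T2 = 76.5129 ms (SSE 4360, 3 iter, converged)

nnlsFractions(curve)       # three-compartment decomposition
#> MultiFit: S0 = 1020, MWF = 0.2926
#>   fractions: myelin=0.2926, tissue=0.6412, free=0.0662

ps <- runChain(curve, config = chainConfig("test", seed = 1))
posteriorReport(ps)$table
#>   compartment t2_ms      mean          sd
#> 1      myelin    20 0.2938458 0.016554312
#> 2      tissue    80 0.6399689 0.020674013
#> 3        free  2000 0.0661853 0.005639218
```

The single-component fit collapses the mixture into one effective T2
(76.5 ms here — between the myelin and free-water basis values, as it
must be); the three-compartment fit recovers the simulated composition
within the noise (MWF 0.29 vs. a true 0.25 from a single curve at this
noise level), and the posterior mean agrees with the point estimate with
an honest uncertainty (± 0.017 on the myelin fraction).

A full synthetic study — 63 subjects in four group × sex strata, label +
multi-echo NIfTI pairs, voxelwise T2 and MWF maps, per-subject ROI
summaries, group statistics and the group-average posterior — runs with:

```r
res <- runPipeline(runConfig("myrun", cohortSpec(seed = 1), seed = 1))
res$summary$group_means$preterm$wm_t2_ms   # e.g. 69.29 ms
```

or from a shell via `inst/scripts/run-pipeline.R`.

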