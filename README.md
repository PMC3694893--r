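# cfsefit

Maximum-likelihood deconvolution of CFSE dye-dilution time courses into
single-cell proliferation parameters, with objective estimates of solution
sensitivity and redundancy.

## What it does, and for whom

CFSE-stained lymphocytes halve their fluorescence at every division, so a
flow-cytometry time course of a stimulated culture encodes the population's
division and death dynamics in a series of log-fluorescence histograms.
`cfsefit` is for immunologists and systems biologists who want to turn such
time courses into interpretable cellular parameters — what fraction of
cells responds, how long cells take to divide and die, and how many
divisions lineages undergo — without over-interpreting data that cannot
actually constrain those parameters.

The pipeline has three steps:

1. **Cell fluorescence model.** Log10 fluorescence of generation *g* is a
   Gaussian with mean `log10((i0 + s − b)·r^g + b)` (anchored undivided
   mean `i0`, shift `s`, background `b`, halving ratio `r ≈ 0.5`) and a
   generation-invariant width `σ = sqrt(ln(1 + cv²))/ln 10`. Peak weights
   (generational cell counts) are obtained analytically by non-negative
   least squares; `(cv, r, b, s)` are fitted per time point with
   constraints propagated along the course.
2. **fcyton population model.** Twelve parameters — founder count `N`,
   responding fraction `F0`, Gaussian division destiny `(Dμ, Dσ)`, and
   log-normal mean/SD pairs for times to divide and die of undivided and
   divided cells — drive a renewal simulation in which division and death
   fates are decoupled (responders are protected from death). Fitting is by
   seeded simulated annealing, either *sequentially* against extracted
   counts or *integrated*: model counts are rendered into histograms
   through the fitted fluorescence model (the adaptor) and scored directly
   against the data (objectives MAD, MRSD, MRSD+; quality metric NPAE, a
   cell-weighted total-variation distance in percent).
3. **Solution quality.** Repeated fits are filtered (within 0.1 NPAE points
   of the best), each parameter's ±1-NPAE-point sensitivity range is found
   by bisection, overlapping candidates are agglomeratively clustered into
   non-redundant maximum-likelihood parameter ranges, and clusters whose
   resampled median NPAE is poor are dropped.

A synthetic-data module generates realistic CFSE courses with known ground
truth (uniform parameter draws in realistic ranges, analytic or sampled
histograms, count/scale noise models) and the error metrics used in the
benchmarks. FCS 3.0/3.1 and CSV event input, viability gating, and a
histogram CSV interchange format are included.

## Worked example

Generate a realistic eight-point course from a known truth, fit both model
layers, and inspect the recovered parameters:

```r
library(cfsefit)

truth <- list(
  fcyton = fcyton_params(N = 1e4, F0 = 0.9, Dmu = 3.5, Dsigma = 1,
                         Ediv0 = 40, SDdiv0 = 10, Ediv1 = 10, SDdiv1 = 6,
                         Edie0 = 60, SDdie0 = 20, Edie1 = 80, SDdie1 = 30),
  fluor  = fluor_params(cv = 0.18, r = 0.5, b = 100, s = 0, i0 = 5e4))

cfg    <- generator_config(schedule = schedule_preset("eight-point"))
course <- generate_course(truth, cfg)

## step 1: fluorescence model per time point
fl <- fit_fluorescence_timecourse(course$timecourse, seed = 1)
fl$fits[[5]]$params
#> fluorescence model: cv=0.180 r=0.500 b=100.1 s=4.4 i0=50000.0 g_max=8

## extracted generational counts vs truth, percent of the course maximum
max(count_error_profile(course$counts, fl$counts))
#> [1] 0.0316771

## step 2: integrated fit of the population model (polished point estimate)
cands <- integrated_fit(course$timecourse, fl, n_restarts = 8, seed = 1,
                        schedule = anneal_schedule(cooling = 0.9,
                                                   steps_per_temp = 40,
                                                   t_min_ratio = 1/500),
                        polish = TRUE, dt = 0.5)
round(cands[[1]]$npae, 2)
#> [1] 1.16
round(unclass(cands[[1]]$params)[c("N", "F0", "Dmu", "Ediv0", "Ediv1")], 3)
#>         N        F0       Dmu     Ediv0     Ediv1
#> 11189.550     0.825     3.551    39.402    10.606
```

The fitted `cv`, `r`, `b` match the generating values; the extracted
counts are within 0.04% of truth; and the integrated fit recovers the
division destiny and division times of the generating parameter set from
the histograms alone with an NPAE of ~1%, while `N` and `F0` land on the
familiar trade-off ridge (more founders, fewer responders) that the
sensitivity-range step of `run_phenotyping()` is designed to expose.
`run_phenotyping()` wraps steps 1–3, adding candidate filtering,
sensitivity ranges, clustering, and the final resampling filter; the
`inst/scripts/cfsefit` script exposes the same stages as shell verbs
(`hist`, `fluor`, `simulate`, `fit`, `phenotype`, `chimera`).

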