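# turnoverAging

Protein lifetimes in brain tissue can be measured in vivo by pulse SILAC:
mice are fed a diet in which lysine carries a ¹³C₆ label, and after a pulse
of 14 or 21 days the heavy/light (H/L) intensity ratio of each protein
reports how much of it has been replaced. `turnoverAging` is an R package
for analyzing such experiments end to end, aimed at proteomics
bioinformaticians who want the full aged-versus-young comparison machinery
— and a synthetic cohort generator that makes every stage testable without
raw mass-spectrometry data.

## What it computes

**Reuse-corrected kinetics.** Degraded protein releases light lysine back
into the precursor pool, so the pool's heavy fraction rises
double-exponentially,

&nbsp;&nbsp;&nbsp;&nbsp;*F*(*t*) = 1 − *a* e^(−*b t*) − (1 − *a*) e^(−*t*/*r*),

(defaults *a* = 0.034277, *b* = 0.444865 d⁻¹, *r* = 11.836573 d), and a
protein with degradation rate constant *k* labels as the solution of
d*h*/d*t* = *k*(*F*(*t*) − *h*), *h*(0) = 0. Half-lives *t*₁/₂ = ln 2/*k*
fitted against this forward model are intrinsically corrected for lysine
reuse. Observed H/L ratios convert to labeled fractions *f* =
ratio/(1 + ratio); fitting is least squares on fractions with a
profile-likelihood 95% CI, plus the standard QC filters
(single-timepoint and decreasing-labeling removal, CI-width flags).

**Aged-vs-young comparison.** Median rescaling of aged lifetimes per
dataset, per-protein log₂FC, 3-of-4 direction-consistency filtering, top-k
rLL/rSL extremes, percentile groups, per-protein z-scores,
lifetime-compression correlation with tertile summaries, a raw-ratio
bidirectionality check that separates true compression from
regression-to-the-mean, abundance quadrants, and cell-type specificity
(> 1 log₂ margin rule).

**Sequence features and statistics.** Composition, length, molecular
weight, pI (Henderson–Hasselbalch bisection), GRAVY, average biosynthetic
cost (avECPA) with expensive/affordable residue classes; Pearson
feature–log₂FC correlations, Wilcoxon matched-pairs tests, Welch ANOVA
with Games–Howell or permutation-Dunnett post hocs, Anderson–Darling
log-normality checks.

**Synthetic cohorts.** `cohort_config()` / `simulate_cohort()` generate
ground-truth lifetimes (log-normal, with global aging, targeted rLL/rSL
subsets, and compression injected), MaxQuant-proteinGroups-dialect TSVs
with multiplicative ratio noise, missingness and decoy rows, FASTA
sequences, and annotation tables — all deterministic functions of one
seed.

## Worked example

```r
library(turnoverAging)

pp <- precursor_pool_params()
precursor_fraction(c(14, 21), pp)
#> [1] 0.7040 0.8362          # heavy fraction of the free lysine pool

# forward model for a 10-day half-life, then a noisy refit
f <- protein_heavy_fraction(c(14, 21), log(2) / 10, pp)
f / (1 - f)
#> [1] 0.4260 0.9397          # expected H/L ratios at day 14 / 21
set.seed(1)
obs <- rep(f / (1 - f), each = 3) * exp(rnorm(6, 0, sqrt(log(1.01))))
fit_lifetime(c(0, rep(c(14, 21), each = 3)), c(0, obs), pp)
#>   halflife ci_lower ci_upper    rss ...
#> 1   9.9413   9.0297  10.9565 0.0025    # truth (10 d) inside the 95% CI

# a full synthetic cohort through the whole pipeline
cfg <- run_config(cohort = cohort_config(n_proteins = 200, seed = 42),
                  outdir = "turnover_run")
s <- run_pipeline(cfg)
unlist(s$rescale_factors)
#> cortex_hom cerebellum_hom cortex_syn cerebellum_syn
#>      20.41          23.15      22.04          20.53
```

The rescale factors are the per-dataset median lifetime lengthening of the
aged cohort in percent; the generator injected a global factor of 1.217
(21.7%), and each dataset's estimate recovers it to within sampling noise
at n = 200. `s$wilcoxon_cortex_hom$p` (2.7e-22 here) confirms the global
lengthening; `s$compression$r` and `s$raw_ratio_bidirectional` together
diagnose lifetime compression (with the default config no compression is
injected); `turnover_run/` holds every intermediate TSV plus
`summary.json`.

A command-line front end covers the same stages:

```sh
inst/cli/turnover-aging all --config run_config.json --outdir out/
```

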