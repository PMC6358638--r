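# traitsuccession

Trait-based analysis of longitudinal microbiome cohorts: phylogeny-based
inference of microbial trait values with conservatism gating,
community-weighted trait metrics over host development, and
trait-shuffling null models for turnover and convergence.

## The problem

Infant gut communities assemble over the first years of life, but curated
trait data (oxygen tolerance, sporulation ability, 16S copy number, cell
size, …) exist for only a minority of taxa. This package closes that gap
and carries the analysis through to community-level conclusions:

1. **Tree** — fixed-length 16S V4 sequences are truncated behind the
   forward primer, pairwise dissimilarities computed over unambiguous
   positions, and an ultrametric tree built by average-linkage (UPGMA)
   clustering.
2. **Traits** — heterogeneous literature records are curated into one
   numeric taxon × trait table (mean for continuous, mode for discrete
   traits; sporulation presence imputed at 0.549, absence at 0) and
   mapped onto tree tips.
3. **Hidden-state prediction** — missing tip values are inferred by
   weighted squared-change parsimony (minimizing
   Σ (v_parent − v_child)² / b with observed tips fixed), with subtree
   averaging and independent contrasts as cross-checking methods.
4. **Conservatism gating** — per trait, |Δtrait| between observed-tip
   pairs is modelled against phylogenetic distance x with five candidate
   models (null, linear, log, asymptotic a(1−e^(−e^b x)), logistic
   a/(1+e^((b−x)/c))), selected by AIC; the trait's maximum prediction
   distance is where the winning curve reaches 90% of the mean difference
   among unrelated pairs (x > 0.1). Predictions farther than that from
   any observed tip are discarded; flat traits are excluded entirely.
5. **Community metrics** — samples are rarefied to 5,000 reads; each
   sample is summarized by community-weighted means CWM = Σ pᵢxᵢ (and
   variances); Bray–Curtis measures taxonomic turnover and SD-scaled
   Euclidean distance between CWM vectors measures trait-space turnover.
6. **Succession statistics** — OTUs are classified early/late by OLS
   slope of relative abundance on age (p < 0.05, sign of β); three series
   track variability (adjacent samples), directional turnover (distance
   to each infant's final sample) and cross-infant convergence, in
   6-month bins.
7. **Null models** — every trait-based statistic is recomputed under
   random reassignment of whole trait vectors among OTUs (default 1,000
   shuffles) and compared with the observed series by per-bin Welch
   tests, BH-adjusted.

A synthetic-data generator (`sim_config()` / `simulate_cohort()`)
reproduces the statistical shape of a 56-infant, 36-month cohort —
conserved traits on a shared species pool, early-declining and
late-rising taxa, C-section and antibiotic sub-cohorts — so the entire
pipeline runs and is tested without any external data.

## Worked example

```r
library(traitsuccession)

pl <- run_pipeline(sim_config(seed = 42), n_null_reps = 100)
print(pl)
#> Trait-based succession pipeline
#>   pool: 150 OTUs; 56 infants over 36 months
#>   conservatism thresholds:
#>     oxygen_tolerance       best=linear     threshold=0.227 coverage=1.00
#>     temperature_optimum    best=asymptotic threshold=0.102 coverage=0.93
#>     gram_positive          best=linear     threshold=0.232 coverage=1.00
#>     iga_binding            best=null       threshold=0.000 coverage=0.50
#>   OTU classes: early 45, late 72, none 33
```

The three phylogenetically conserved traits earn positive prediction
thresholds (predictions allowed within 0.10–0.23 sequence dissimilarity
of an observed taxon, with 93–100% of the pool covered after gating),
while the white-noise control trait `iga_binding` is called flat —
null model, threshold 0 — and only its directly observed half survives.
Most OTUs show significant monotone abundance trends, as planted.

```r
print(pl$null$directional$test)
#>   bin observed_mean null_mean         t            p        p_adj  n
#> 1   1     1.0169827 0.2887837 32.055912 1.847330e-39 1.108398e-38 56
#> 2   2     0.8216001 0.2703094 22.070331 1.602743e-30 4.808230e-30 56
#> 3   3     0.4696079 0.2294014  9.598573 1.386358e-13 2.772716e-13 56
#> 4   4     0.2894469 0.1980960  3.450097 1.061144e-03 1.061144e-03 56
#> 5   5     0.1453634 0.1805512 -5.874498 1.352153e-07 2.028230e-07 56
#> 6   6     0.1455327 0.1782357 -5.373623 1.036925e-06 1.244309e-06 56
```

Trait-based directional turnover (each sample's trait-space distance to
the same infant's final sample, per 6-month bin) greatly exceeds the
trait-agnostic null in the first year — communities move through trait
space toward their mature state far faster than shuffled traits would
predict — and falls to (here, below) null levels by year three: exactly
the planted trait-driven succession signal.

See `vignette("trait-succession-methods")` for the models, parameter
conventions, numerical choices, and what the synthetic cohort does and
does not emulate.

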