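---
title: "Trait-based analysis of gut microbiome succession: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based analysis of gut microbiome succession: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitsuccession)
```

## The problem

Longitudinal 16S surveys of the infant gut record which OTUs rise and fall
over the first years of life, but taxonomy alone says little about *why*.
A trait-based view asks instead how the distribution of functional
characteristics — oxygen tolerance, sporulation ability, rRNA operon copy
number, cell size, and so on — shifts as the community assembles.
The obstacle is that curated trait data exist for only a small minority of
taxa. This package implements a complete trait-based succession analysis
around that obstacle:

1. build an ultrametric tree whose branch lengths are 16S V4 sequence
   dissimilarities;
2. map sparse, literature-derived trait values onto its tips;
3. predict the missing values by hidden-state prediction (HSP);
4. decide per trait how far across the tree such predictions can be
   trusted, and discard the rest (conservatism gating);
5. summarize each community sample by community-weighted trait means
   (CWMs) and compare taxonomic (Bray–Curtis) with trait-space turnover;
6. test every trait-based statistic against trait-shuffling null models.

Because the motivating cohort data are an external resource, the package
ships a synthetic-data generator that reproduces the *statistical shape*
of such a cohort, so the whole pipeline is exercised end to end by code
alone.

## Phylogeny and distances

Trees are `ape::phylo` objects. For sequence input, reads are truncated
to the 250 bp behind the forward primer (IUPAC degeneracies honoured),
pairwise dissimilarity is the mismatch proportion over positions where
both bases are unambiguous, and the tree is built by average-linkage
(UPGMA) agglomerative clustering: clusters merging at height *h* end up
at cophenetic distance *h*, so the tree is ultrametric by construction
and its path distances reproduce a perfectly ultrametric input matrix
exactly. Labels are processed in lexicographic order so exact ties merge
deterministically. One convention is fixed package-wide: *phylogenetic
distance = cophenetic distance on this tree*; every threshold and
nearest-neighbour query uses it.

## Trait curation

The vocabulary covers 16 genomic, physiological and life-history traits
(`trait_vocabulary()`). Aggregation over multiple records per taxon uses
the mean for continuous and bounded-score traits and the mode for ordinal
and binary-probabilistic traits, with mode ties averaged so scores stay
in range. Cell length and width are carried as log micrometres; optimal
temperature reported as a range aggregates to the midpoint via the mean
rule. Sporulation is special-cased: quantitative scores pass through and
take precedence, a bare "spores present" maps to 0.549 (the median of
nonzero quantitative scores in the reference assay), "spores absent" to
0. Oxygen tolerance is ordinal 0–5 from obligate anaerobe to obligate
aerobe. Four traits (aggregation, IgA binding, pH and salt optima) are
curated but flagged non-inferable; the conservatism stage rediscovers
this from data.

## Hidden-state prediction

Three algorithms, all exact interpolators (observed tips are never
altered):

* **Weighted squared-change parsimony** (`hsp(..., method = "wscp")`,
  the method of record): minimize
  $\sum_{\text{edges}} (v_{\text{parent}} - v_{\text{child}})^2 / b$
  with observed tips clamped. The quadratic is solved exactly by a
  two-pass recursion — a rootward pass combining locally parsimonious
  states (precision-weighted child messages), then a tipward pass fixing
  each node given its parent. Hidden tips are free variables of the
  objective, so a hidden tip's optimum equals its parent node's value;
  this matches the rootward "locally parsimonious states" description
  while keeping a clean linear-algebra oracle (the tests solve the same
  objective by dense normal equations and demand agreement to 1e-8).
* **Subtree averaging**: a hidden tip takes the unweighted mean of
  observed tips inside the nearest ancestral clade that contains any.
* **Independent contrasts**: the Felsenstein rootward recursion
  $x_k = (x_i/b_i + x_j/b_j)/(1/b_i + 1/b_j)$ with branch extension
  $b_k' = b_k + b_ib_j/(b_i+b_j)$ on the observed-tip-pruned tree; each
  hidden tip takes its nearest reconstructed ancestor's estimate.

Zero-length branches (UPGMA ties) are replaced by 1e-9 of the tree depth.
Discrete traits are encoded numerically, so predictions may be fractional
— read them as probabilistic state estimates; nothing is rounded
downstream.

## Conservatism gating

Whether a prediction is trustworthy depends on how phylogenetically
conserved the trait is. Per trait, the tree is pruned to observed tips,
all tip pairs are binned by distance in 0.005 increments (at most 10,000
pairs kept per bin), and the absolute trait difference $|y|$ is modelled
as a function of distance $x$ with five candidates: null ($|y| \sim 1$),
linear, logarithmic ($x$ floored at half a bin width — the smallest
resolvable distance — to avoid $\log 0$), asymptotic
$a(1 - e^{-e^{b}x})$ through the origin, and logistic
$a/(1 + e^{(b-x)/c})$.

Two numerical decisions matter here and are deliberate:

* **Fitting target.** Models are fitted to the per-bin *mean*
  differences, weighted by the number of pairs in each bin (the variance
  of a bin mean scales inversely with its pair count, so this is the
  matching weighted-least-squares model). Fitting raw pair-level points
  is available as `fit_to = "pairs"` for sensitivity checks but is not
  the default: pairs sharing a tip are strongly dependent, which inflates
  apparent goodness-of-fit gains and makes the AIC competition
  anticonservative.
* **Selection rule.** AIC is $n\ln(\mathrm{RSS}/n) + 2k$ with $k$
  counting parameters plus the error variance; nonlinear fits that fail
  to converge drop out. Models within 2 AIC units of the minimum are
  treated as equivalent fits and the structurally simplest of them wins
  (the usual AIC equivalence convention). Under a trait with no
  phylogenetic signal, strict lowest-AIC would select a spurious
  non-null model in roughly a third of replicates simply because four
  richer models compete against one flat one; the equivalence band
  restores the intended behaviour (flat traits are called flat in about
  95% of replicates) while leaving genuinely conserved traits, whose
  non-null models win by tens of AIC units, untouched.

All RSS values are floored at the numerical noise scale of the response
before entering AIC, so exactly flat or noiseless inputs compare by
parameter count rather than floating-point rounding.

Nonlinear self-starts are deterministic: $a_0$ is the largest bin mean,
the asymptotic rate comes from the half-saturation distance, the logistic
midpoint from the distance at half maximum with $c_0 = 0.02$.

The **null expectation** is the mean $|y|$ over pairs strictly farther
than 0.1; the **threshold** is the smallest distance at which the
best-fitting curve reaches 90% of it, located by bisection to 1e-6,
zero when the null model wins, and capped at the largest observed pair
distance when the curve never gets there. Predictions whose nearest
observed tip is farther than the threshold are discarded
(`gate_predictions()`); observed values are never gated. Thresholds are
invariant to positive rescaling of the trait, since curve and null
expectation scale together.

## Community metrics

Samples are rarefied to 5,000 reads by multivariate hypergeometric
subsampling (shallower samples are dropped and counted). The CWM of a
trait in a sample is $\sum_i p_i x_i$ over OTUs with non-missing values,
with the weights renormalized over that covered subset; if the covered
relative abundance falls below 50% the CWM is reported missing rather
than extrapolated (the floor is configurable, and unrenormalized partial
sums are available). The community-weighted variance uses the same rules.
Taxonomic dissimilarity is Bray–Curtis; trait-space dissimilarity is the
Euclidean distance between CWM vectors after dividing each trait by its
standard deviation across OTU-level (gated) values — computed once per
dataset and frozen, so observed and null-model comparisons share the same
scaling.

## Succession statistics

Ages bin as month $= \lfloor \text{days}/30.44\rfloor + 1$ and 6-month
periods are months 1–6, 7–12, …; these conventions are the package's
(day-level cutoffs are otherwise underdetermined). Per OTU, ordinary
least squares of relative abundance on age in months pooled over all
samples classifies significant negative trends ($p<0.05$, $\beta<0$) as
early successional and significant positive trends as late; constant
series have undefined $p$ and stay unclassified. Cohorts follow the
delivery-mode/antibiotics rules (heavy antibiotics: vaginal with ≥ 50
treatment days, 7 days imputed per unreported course; C-section with ≤ 2
courses; control: vaginal, untreated), and cohort contrasts are Welch
t tests of sample CWMs against controls per trait and period, BH-adjusted
across the whole family.

Three compositional series share one engine, each usable with either
dissimilarity:

* **variability** — adjacent same-infant sample pairs, binned by the
  later sample's age (the dissimilarity is realized then);
* **directional turnover** — every non-final sample against that
  infant's final sample, binned by the sample's own age;
* **convergence** — cross-infant sample pairs within each month of age;
  a period averages its monthly means (≤ 6 units).

The first two average within infant × period and then across infants;
confidence intervals are normal-approximation 95% bands across units,
degenerate for single-unit bins.

## Null models

`shuffle_traits()` permutes whole trait rows among OTUs — each OTU keeps
its abundances but inherits another's full trait vector including its
missingness pattern, preserving every column's multiset and the
inter-trait correlation structure (a per-column mode would break rows
apart; whole-row reassignment is what "shuffling trait values among
OTUs" means here, and a column-wise shuffle is available by permuting
columns independently upstream if wanted). `null_series()` recomputes a
trait-based series for each of `n_reps` shuffles (default 1,000) with the
scaling SDs frozen from the observed table, and averages per-unit null
values across replicates. `observed_vs_null_test()` then runs a Welch
t test per 6-month bin between observed per-unit values and the matched
per-unit null means — equal unit counts by construction, so the 1,000
replicates never masquerade as extra degrees of freedom — with BH
adjustment across bins. An identity permutation reproduces the observed
series exactly, and OTU-based (Bray–Curtis) statistics are untouched by
construction.

A power note: for the convergence series the test units are the ≤ 6
monthly means inside a period, and both observed and null means trend
strongly within the first period, so this unpaired test has modest power
for early-succession signal regardless of cohort size. The directional
series, whose units are infants, is the sensitive instrument for
detecting trait-driven turnover, and is what the package's acceptance
checks use for detection; the convergence series is checked for
calibration (observed inside the central 95% of its null when traits are
unlinked to succession).

## The synthetic cohort generator

`sim_config()` fixes the scenario; `simulate_cohort()` runs it. Defaults
emulate the cohort structure the analysis targets: 56 infants, each with
12–36 samples on a jittered evenly spaced grid over 36 months (a jittered
grid matches "semi-regular intervals" and guarantees the minimum count;
a Poisson process would not); sequencing depth 5,000; a shared pool of
150 OTUs on a pure-birth tree rescaled to a maximum tip-to-tip
dissimilarity of 0.3, about the span of 16S V4 distances among gut
bacteria. Continuous traits evolve by Brownian motion (variance 1 per
unit distance; temperature uses 25 with root 37 °C to give a realistic
range), the binary trait by a symmetric two-state Markov chain (rate 5
per unit distance — chosen for closed-form checks over a threshold
model), and a white-noise control trait has no phylogenetic signal at
all. Half the tips are "observed", mimicking literature coverage.

Expected abundances follow per-OTU logistic trends: early taxa decline
and late taxa rise around midpoints uniform on 6–18 months with
steepness 0.2–0.6 per month, over lognormal(0, 1) baseline abundances
floored at 5% so no taxon vanishes. When roles are trait-linked
(default), the top and bottom 30% of the oxygen-tolerance distribution
become the early and late guilds, planting a trait-driven successional
signal; unlinked roles give the trait-agnostic control. Compositional
noise is Dirichlet-multinomial with one concentration parameter
(θ = 200), the simplest model of realistic overdispersion. Cohort
perturbations multiply expected abundances of trait-selected taxa within
age windows (defaults: ×3 on oxygen-tolerant taxa for C-section infants
in months 0–12; ×0.3 on Gram-positive taxa under antibiotics), and the
infant design plants 6 C-section, 18 heavy-antibiotic and 18 control
infants among 56. Identical configurations (including the master seed,
fanned out deterministically per stage by `stage_seed()`) give
bit-identical output.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: taxonomic identity and realistic abundance
rank curves, sequencing error and chimeras, age-dependent sampling
density, within-infant autocorrelated noise, diet covariates, or any
calibration to the real cohort's distributions. It establishes that the
*pipeline* recovers planted structure, not that the biology is
reproduced.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen as the smallest sizes at
which each property is statistically decisive: oracle equivalence on 100
trees of ≤ 30 tips; HSP recovery and conservatism discrimination on
200-tip trees with 50% observed, 100 replicates; null-model calibration
on 100 simulated 12-infant/60-OTU/18-month datasets with 100 shuffles
each (scaled down from the 1,000-replicate default); detection of planted
turnover over 50 such runs; classification accuracy at the full 56-infant
design. The acceptance script (`scripts/acceptance.R`) recomputes the
same quantities from scratch at comparable sizes.

## Known limitations

* UPGMA assumes a clock; rate-variable lineages distort distances and
  hence thresholds.
* The AIC competition is honest about flatness but cannot distinguish
  *which* non-null shape generated the data when two curves nearly
  coincide over the observed range; only the threshold, not the shape
  label, feeds downstream analysis.
* CWM renormalization assumes missing-trait OTUs resemble covered ones
  abundance-weightedly; the 50% coverage floor bounds, but does not
  remove, that extrapolation.
* Convergence-series significance tests are low-powered by construction
  (six units per period); treat their non-significance cautiously.
* The per-OTU trend regressions pool samples across infants and ignore
  within-infant correlation; their nominal type-I rate is validated only
  under the generator's exchangeable noise.
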