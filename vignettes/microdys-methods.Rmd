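---
title: "Methods: reference-cloud dysbiosis scoring and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-cloud dysbiosis scoring and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`microdys` analyses taxon-by-sample count tables from low-biomass
small-intestinal (duodenal aspirate) 16S profiling, where two questions
dominate: *is a patient's community composition abnormal relative to a
healthy reference?* and *which taxa drive the difference between
symptomatic and healthy cohorts?* The package answers the first with a
reference-cloud dysbiosis index on compositional (Aitchison) geometry and
the second with a random-forest symptom index plus permutation-based
differential abundance, and it ships a synthetic-cohort generator so that
every stage can be exercised and validated without sequence data.

# The compositional model and the dysbiosis index

Sequencing counts carry only relative information, so all distance-based
scoring happens on the simplex. For each sample the proportions are made
strictly positive by multiplicative replacement (zeros set to a small
$\delta$, nonzeros rescaled by $1 - z\delta$ so the row still sums to 1)
and mapped by the centered log-ratio transform
$\mathrm{clr}_i = \ln x_i - \tfrac{1}{D}\sum_j \ln x_j$. Euclidean
distance between CLR vectors is the Aitchison distance, the natural
metric for compositions: it is scale-invariant (multiplying a sample's
counts by any constant changes nothing) and permutation-invariant in the
taxa.

The dysbiosis score of a sample is its mean Aitchison distance to the
reference ("cloud") samples — all of them by default (`k = "all"`), or
the `k` nearest if a local neighbourhood is preferred. Reference samples
are scored leave-one-out: a healthy sample is never part of its own
cloud, so reference and query scores are comparable. The classification
rule is one-sided: a sample is *dysbiotic* iff its statistic exceeds the
reference mean plus two reference standard deviations (sample SD, $n-1$
denominator). A sample that is unusually close to the cloud centre is
"unusually typical", not dysbiotic. The *dysbiosis index* (DI) is the
natural log of the statistic — a strictly monotone transform, so the
classification never depends on the log base.

Two open choices were resolved as follows. The CLR basis is computed
jointly over all samples (reference statistics then use reference rows
only); computing it per group would make query and reference coordinates
incommensurable. The feature level defaults to the genus-collapsed table,
which is more stable than OTU level at aspirate depths; the un-collapsed
table can be used by passing `level = NULL`. The replacement $\delta$
defaults to half a count at the sample's own depth ($0.5/\text{depth}$),
so the imputed mass matches the sample's resolution.

# Orthogonal validation of the classification

An independent route to the same labels starts from the symptom index
(below): healthy-control SI scores are approximately normal on the logit
scale, so the same mean-plus-2-SD rule is applied to logit(SI) of the
healthy group (Shapiro–Wilk normality of those scores is reported
descriptively, never used as a gate). A random forest refit on these new
labels yields an out-of-bag probability of "dysbiotic" membership, and
the Pearson correlation between that probability index and the cloud
score quantifies agreement between the two routes. The refit is skipped
(with a warning) when the logit rule leaves a class with fewer than three
samples, since out-of-bag probabilities are not defined usefully there.

# The symptom index and feature selection

The symptom index (SI) is the out-of-bag vote fraction for the
symptomatic class from a random forest on size-factor-normalized
abundances: a sample is scored only by trees whose bootstrap excluded it,
which is what prevents overtraining. AUC is the scaled Mann–Whitney
statistic with a DeLong 95% interval. Feature relevance uses a
shadow-feature scheme: every iteration shuffles each column, fits a
forest on the real+shadow block, scores a "hit" for features beating the
best shadow, and decides confirmed/rejected by a cumulative binomial test
at `alpha` (Bonferroni-corrected over the features still in play);
rejected features leave the pool and undecided ones stay tentative.
Defaults (500 trees, $\sqrt{p}$ features per split, `alpha = 0.01`,
`max_iter = 100`) are the conventional ones.

Covariate associations regress SI on each of the seven clinical
variables separately (listwise deletion per test, n reported), correct
with Benjamini–Hochberg across the seven, and report the joint $R^2$ of
a combined model containing exactly the covariates passing `q < 0.1`.

# Differential abundance and the power analysis

Counts are normalized with pairwise-ratio size factors: for sample $j$,
the median count ratio to each other sample over shared nonzero taxa,
combined on the log scale and shrunk by $m/(m+1)$ (the mean pairwise
log-ratio estimates $\tfrac{m+1}{m}\log s_j$ when $m$ partners are
available), so exact-ratio data recover exact factors; total-sum scaling
is available as a sensitivity flag. Testing is per taxonomic rank:
square-root transform, exclusion of taxa with prevalence $< 10\%$ or
maximum proportion $< 0.2\%$ (strict inequalities — boundary values are
tested), a two-group permutation test with the Welch $t$ statistic (1000
permutations by default, one shared permutation stream per rank), and BH
correction within the tested taxa of each rank only. When
$\binom{n}{n_1} \le$ `n_perm` the test enumerates all assignments and the
p-value is exact; otherwise the add-one estimator
$(1+\#\{|t^\ast|\ge|t|\})/(1+N)$ keeps p strictly positive. Perfectly
separated groups with zero within-group variance get $t = \pm\infty$, so
enumeration still counts exactly the separating assignments; $p = 1$ with
a warning is reserved for constant input.

The power tool wraps the generator: per replicate it draws both groups
from a Dirichlet-multinomial model, tests each genus with
Wilcoxon–Mann–Whitney (normal approximation with tie correction for
$n_1+n_2 > 25$, exact below), applies BH at the chosen FDR, and reports
per-taxon power, average power over the truly differential taxa, and
any-detection power. The default design point is 65 genera with
abundance ranks 6–15 halved in the larger group, $n = 38$ vs $126$, FDR
5%, 200 replicates.

# What the synthetic cohort emulates — and what it does not

The generator produces genus profiles with geometric rank-abundance
decay (rate 0.85 over 65 genera), Dirichlet-multinomial overdispersion
($\theta = 0.02$, i.e. Dirichlet concentration $\pi/\theta$; a typical
amplicon regime in which ranks 6–15 are "moderately abundant"),
log-normal read depth (median 20,000 reads, $\sigma = 0.5$ log units)
with a 5% fraction of failed libraries at 100–999 reads to exercise the
depth filter, and a latent dysbiotic subpopulation among the cases
(fraction 0.3 by default) drawn from a depleted mean: genera at ranks
6–25 reduced to 10% of their reference abundance. The depletion-style
effect (20 moderately abundant genera largely absent) mirrors how
dysbiosis presents in these communities and provably lowers expected
Shannon diversity. Clinical covariates are Bernoulli with baseline
prevalences (antibiotics 0.25, PPI 0.35, GI surgery 0.15) and
class-linked odds multipliers (3, 2, 2), age uniform on 18–89 with a
+10-year shift in the dysbiotic class, and log-normal culture counts
that put part of the dysbiotic class over the $10^5$ CFU/mL threshold.
One master seed drives everything; each stochastic stage derives a child
seed from a tag, so stages are reproducible independently of draw order.

The generator does *not* emulate real taxonomic correlation structure
(taxa are exchangeable given the rank-abundance curve), phylogenetic
signal in the effect (the tree is random, so UniFrac behaves like a
generic presence/absence metric), batch effects, or contamination —
all present in real aspirate data. Passing tests therefore demonstrate
algorithmic correctness and calibration under the stated generative
model, not clinical performance.

# Numerical choices

* Shannon diversity is reported in bits (base 2); pass `base = exp(1)`
  for nats. Pielou evenness is Shannon over $\log_2$(richness), defined
  as 1 for a single-taxon sample. Both are emitted since "evenness" is
  ambiguous in common usage.
* Faith's PD includes the path to the root (the common amplicon-pipeline
  convention); `include_root = FALSE` excludes it.
* Rarefaction subsamples without replacement and *drops* samples below
  the target depth (IDs logged) rather than erroring, mirroring typical
  pipeline behaviour.
* PCoA reports negative eigenvalues and computes percent variance over
  the positive ones only.
* PERMANOVA's p uses the add-one estimator, or exact enumeration of the
  label multiset when that is cheaper than the requested permutations.
* Pairwise ordination-axis tests use the Welch t-test, robust to the
  unbalanced 38-vs-126 design.
* The 2-SD threshold uses the sample SD with $n-1$ denominator;
  classification at exactly the threshold is healthy-like (strict ">").
* Degenerate references (zero spread in the reference statistics) and
  constant score vectors raise errors rather than returning misleading
  numbers.

# Problem sizes used in the shipped checks

The test suite and the acceptance script are sized for interactive use:
the power design point and the reference-coverage property each use 200
Monte-Carlo replicates (enough for ~1-percentage-point standard error on
the reported percentages); oracle-equivalence checks enumerate
exhaustively at $n \le 8$ samples (and $n \le 12$ for AUC pair
counting); type-I-error calibration of the differential pipeline uses 25
null cohorts of 50 samples over 40 genera; pipeline smoke tests run a
12+24-sample, 25-genus cohort. All are chosen as the smallest sizes at
which the checks are statistically meaningful.

# Known limitations

The cloud statistic's neighbourhood size is configurable but defaults to
the whole reference cloud; with very heterogeneous references a small
`k` can be more sensitive, at the cost of noisier reference statistics.
The shadow-feature selector decides by a Bonferroni-adjusted binomial
test, so with small feature pools and few iterations a minority of noise
features remains tentative rather than rejected. Size-factor
normalization assumes most taxa are not differential between samples;
under gross compositional shifts total-sum scaling may be preferable,
and both are exposed. The BIOM reader accepts the JSON (1.0) dialect
only.
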