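---
title: "Personalized perturbation profiles: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized perturbation profiles: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peepr)
```

## The problem

Group-wise differential expression compares the mean expression of a case
group against a control group, one statistic per gene. Two limitations
follow from the averaging. First, only genes perturbed *consistently* — in
the same direction, in a large share of patients — can reach significance.
Second, the result carries no patient-specific information: a gene that is
strongly up-regulated in a quarter of the patients and normal in the rest
may be declared "differentially expressed" even though the majority of
patients show nothing at that locus.

`peepr` works at the level of the individual subject. Each case (or
control) is compared against the distribution of control expression values,
gene by gene, producing a personal perturbation profile — a "barcode" of
the genes that are unusually high or low *in that subject*. The package
then quantifies how heterogeneous these profiles are across subjects with
the same phenotype, aggregates them into a disease-associated gene pool
using an analytic null model, and turns the pool into a transparent
classifier of disease status.

## Per-subject z-scores and profiles

For gene $i$ and subject $j$ with log2-scale expression $l_i^j$, the
perturbation score is

$$z_i^j = \frac{l_i^j - \langle l_i \rangle_{\mathrm{cont}}}
               {\sigma_{\mathrm{cont}}(l_i)},$$

where mean and standard deviation are taken over the control subjects. If
$j$ is itself a control, it is removed from the reference before computing
the statistics (leave-one-out), so no subject is compared against a
baseline that contains itself — without this, a control's own outliers
drag the reference towards them and mask real deviations, which is also
why the leave-one-out z of an extreme control exceeds its naive z.

The profile (PEEP) of subject $j$ at threshold $z_{\mathrm{thresh}}$ is
the pair of sets $\{i : z_i^j > z_{\mathrm{thresh}}\}$ (up) and
$\{i : z_i^j < -z_{\mathrm{thresh}}\}$ (down). The default
$z_{\mathrm{thresh}} = 2.5$ balances stringency against coverage the same
way a fold-change/FDR cutoff does in group-wise analysis; raising it
strictly shrinks every profile (a property the tests check). Boundary
values $z = \pm z_{\mathrm{thresh}}$ are *not* called, matching the strict
inequalities of the definition.

Numerical choices:

* the dispersion uses the sample estimator (denominator $n-1$): control
  groups in this setting are small (tens of subjects), where the unbiased
  estimator matters;
* genes with zero reference dispersion — in the full control set or any
  leave-one-out subset — have no defined z-score; they are excluded from
  profiles *and* from the gene universe used by every downstream null,
  because keeping unscorable genes in the universe would deflate the
  binomial occupancy model;
* at least 3 controls are required, so each control can still be scored
  against two remaining references.

`stability_analysis()` probes how the choice of control population affects
the scores: it fixes, per gene, the expression level that maps to
$z = 2.5$ under the full control set, then recomputes that level's z-score
under random subsamples of the controls and reports the ratio to 2.5. The
ratio dispersion grows as controls are removed; small fluctuation at
moderate removal indicates the control group is large enough.

## Heterogeneity between profiles

Profiles of two subjects are compared direction-agnostically (the union of
up and down sets) by default, for consistency with the classifier (below);
`direction_matters = TRUE` switches to direction-aware matching. Three
complementary measures are provided:

* **Jaccard index** $J = |A \cap B| / |A \cup B|$ (0 for two empty sets);
* **one-sided Fisher's exact test** on the $2{\times}2$ membership table
  over the measured-gene universe, i.e. the hypergeometric tail
  probability of drawing at least the observed overlap, with Bonferroni
  correction over the pairs tested within the compared group;
* **Pearson correlation** of the full continuous z-profiles, which uses
  all non-excluded genes and therefore does not depend on the threshold.

The universe for the Fisher test is the set of non-excluded measured
genes: that is exactly the sampling frame from which profile members are
drawn, and using anything larger (e.g. all annotated genes) would
overstate significance.

## The combinatorial disease pool

Even random profiles share genes by chance. Under the null model in which
each of $n$ subjects carries $g$ perturbed genes drawn uniformly from $G$,
the number of subjects containing a fixed gene is binomial, so the
expected number of genes appearing in exactly $k$ profiles is

$$G \cdot f(k; n, p), \qquad p = g/G,$$

with $f$ the binomial pmf and $g$ estimated by the mean profile size.
`occupancy_histogram()` tabulates the observed occupancy against this
expectation, and `goodness_of_fit_null()` summarises the discrepancy with
a chi-square-style statistic (adjacent bins pooled to expected counts of
at least 5, trailing remainder merged into the last pooled bin). The
statistic is descriptive: for genuinely random profiles it sits near its
degrees of freedom, while a shared disease module inflates it by orders of
magnitude.

The pool threshold comes from the smallest occupancy count whose null
expectation falls below one gene:

$$X_{\mathrm{rand}} = \min\Big\{x : \sum_{k=x}^{n} G f(k;n,p) < 1\Big\},
  \qquad X = X_{\mathrm{rand}} + 1,$$

solved by testing increasing values. The pool is every gene present in at
least $X$ case profiles, counting a subject once per gene regardless of
direction — patients can carry the same disease gene perturbed in opposite
directions, so requiring directional agreement would discard genuine
module members. $p$ uses the mean *case* profile size, since the pool is
compiled from case profiles. By construction, pools built from random
profiles are empty or nearly so (the expected number of qualifying genes
is below one); the tests verify this on simulated null profiles.

Two numerical details: the tail is evaluated through the binomial survival
function rather than by summing pmf terms, so it does not underflow at
large $nG$; and because the condition $G \cdot \mathrm{tail} < 1$ becomes
a floating-point tie when the tail is within machine epsilon of 1, the
solver also evaluates the equivalent lower-tail form
$\mathrm{cdf}(x-1) > (G-1)/G$, which retains the deficit in that regime.
The strict inequality "< 1" is kept as written: an expectation of exactly
one gene does not qualify.

## Classification from pool fractions

The score of a subject is the fraction of pool genes contained in its
profile (direction-agnostic). `cross_validate()` wraps this in repeated
stratified k-fold cross-validation (default 5 folds, 100 repeats):

* folds are stratified by label, remainders dealt round-robin, so each
  fold keeps approximately the full-data case/control proportions;
* *everything* is refit per fold from the training subjects only — the
  control reference (training controls), the case profiles, the universe,
  and the pool including a re-solved $X$. Held-out subjects are z-scored
  against the training reference; they never contribute to it. The suite
  asserts this bluntness by corrupting held-out subjects and checking the
  training artifacts and the remaining scores are bit-identical;
* one ROC curve per repeat is built from all out-of-fold fractions, using
  every observed fraction as a candidate threshold (classify "case" when
  fraction ≥ threshold, plus a sentinel above the maximum so the curve
  spans (0,0)–(1,1)); the trapezoidal AUC then equals the Mann–Whitney
  probability that a random case outscores a random control (ties ½),
  which an independent pairwise oracle confirms to 1e-10;
* a repeat whose training pool comes up empty is skipped and counted —
  with no shared signal the method abstains rather than guesses.

Per-repeat fold assignment is seeded as `seed + repeat`, so extending the
number of repeats never changes earlier repeats. `twofold_robustness()`
reruns the procedure with 2 folds, halving the training data, to probe
sample-size sensitivity.

The benchmark `knn_classify()` scores a held-out subject by the fraction
of cases among its $k$ most-correlated training subjects (Pearson on the
full log2 expression vectors by default, Spearman switchable; default
$k = 15$, sweep helper over $\{3,5,10,15,20\}$). Ties at the $k$-th rank
are broken by training-sample order after a seeded shuffle, keeping runs
deterministic. Constant expression vectors have no defined correlation;
affected training samples are dropped from the ranking and a fully
constant test sample is flagged and scored 0.5.

## Gene-set enrichment and pathway-level heterogeneity

`enrich_peep()` tests each term of a GMT collection against a profile with
the same one-sided Fisher's exact machinery, after intersecting term genes
with the measured universe (terms that vanish are skipped); significance
is Bonferroni-corrected over the terms actually tested.
`pathway_heterogeneity()` then asks whether subjects enriched for the
*same* term perturb the *same* genes: for every term enriched in at least
3 subjects (configurable), it computes the Jaccard index of the
term-restricted perturbed gene sets for all enriched pairs and pools all
values into one distribution summarised by its 5/25/50/75/95th
percentiles. Low pooled values alongside many enriched subjects are the
signature of a disease module hit at different places in different
patients. `per_pathway_perturbation_table()` exposes the underlying
gene-by-subject direction matrix with up/down margins for display.

## The synthetic generator

`simulate_dataset()` produces data with exactly the structure the method
assumes, so every stage is testable without downloads:

* per-gene Gaussian control baselines, mean ~ U(4, 12) and sd ~ U(0.25, 1)
  on the log2 scale — typical post-normalization microarray intensity
  ranges;
* a planted disease module of `module_size` genes; each case perturbs its
  own random `case_module_fraction` of it, shifted by `effect_size`
  control-sds (direction fixed per gene under `"consistent"`, redrawn per
  case under `"mixed"`);
* every subject — case and control — additionally perturbs
  `background_peep_size` random non-module genes with random signs: the
  private-noise floor that makes control profiles non-empty and profile
  overlap a nontrivial signal.

The default configuration (5000 genes, 25 controls, 40 cases, module 200,
fraction 0.5, background 100, effect 4 sd) describes a moderately
heterogeneous disease: any two cases share only ~half their module hits,
and background perturbations outnumber module hits in every profile. Under
these conditions the pool recovers the planted module with precision and
recall above 0.9, recovery improves monotonically in effect size and
module fraction, and recovery under `"mixed"` directions matches
`"consistent"` — the direction-agnostic pool design verified against its
own ground truth.

What the generator does *not* emulate: probe-level effects, batch
structure, heavy-tailed or skewed expression noise, gene–gene correlation
beyond the module, and label noise. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
performance on any real cohort. One deliberate consequence of Gaussian
noise with an *estimated* reference: a gene whose control sd happens to be
underestimated gets inflated z-scores in every subject at once, and such a
gene can occasionally clear $X$ and enter the pool as a false positive.
The independence assumption of the binomial null cannot see this
correlated failure; it is the main caveat to keep in mind when reading
pool precision.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the pipeline at deliberately
desk-sized conditions chosen to keep every Monte-Carlo estimate stable:
the reference simulation above; 500 replicate draws of 30 random
100-gene profiles over 2000 genes for occupancy calibration; 200 replicate
null pools; a 3×3 grid over effect sizes {2, 4, 8} and module fractions
{0.3, 0.6, 1.0}; and 10–20 cross-validation repeats (the default for real
use is 100). The acceptance script reports, among other quantities, the
pool's precision/recall against the planted module, the occurrence
threshold $X$, cross-validated and knn AUCs, case/control pool-fraction
percentages and within-group mean Jaccard indices, all recomputed from
scratch under the seed passed on the command line.

## Known limitations

* The binomial null assumes independent, equally-sized random profiles;
  real profiles have subject-specific sizes and correlated genes. The
  occupancy fit statistic makes the first-order check, not a formal test.
* The group-wise DE module uses a per-gene Welch t-test; it is a
  comparator baseline, deliberately simple and swappable, not a
  reimplementation of moderated-variance methods.
* Probe collapsing keeps the single probe row with the highest mean
  expression across all samples — one intact row preserves within-row
  covariance, but alternative summarisations (per-sample maximum, medians)
  would give slightly different gene-level matrices.
* GMT collections are consumed as given; ontology up-propagation and
  evidence filtering belong upstream.
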