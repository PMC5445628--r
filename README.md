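# peepr — personalized expression perturbation profiles

Group-wise differential expression answers "which genes differ *on
average* between cases and controls?" — it cannot say which genes are
perturbed *in this patient*, and it misses genes that are strongly
perturbed in different directions in different patients. `peepr`
implements a subject-level alternative for case/control expression
studies (bulk microarray or RNA-seq intensities on a log2 scale):

1. **Profiles.** Every subject is z-scored gene-by-gene against the
   control reference,
   `z_i^j = (l_i^j − ⟨l_i⟩_cont) / σ_cont(l_i)`,
   with leave-one-out references for the controls themselves. Genes with
   `|z| > z_thresh` (default 2.5) form the subject's perturbation profile
   ("barcode") with an up/down direction per gene.
2. **Heterogeneity.** Pairwise profile overlap (Jaccard index, one-sided
   Fisher's exact significance over the measured-gene universe, Pearson
   correlation of continuous z-profiles) and gene-set enrichment with
   per-pathway heterogeneity quantify how differently the same disease
   manifests across patients.
3. **Disease pool.** Under the null that each of `n` profiles is a random
   `g`-subset of `G` genes, the expected number of genes shared by exactly
   `k` subjects is `G·f(k; n, p)` with `p = g/G` (binomial pmf `f`). The
   occurrence threshold is the smallest `X_rand` with
   `Σ_{k≥X_rand} G·f(k;n,p) < 1`, and the **combinatorial disease pool**
   collects every gene present in at least `X = X_rand + 1` case profiles
   (direction-agnostic).
4. **Classification.** The fraction of the pool contained in a subject's
   profile predicts disease status; repeated stratified 5-fold
   cross-validation (pool and reference rebuilt per fold from training
   subjects only) yields ROC/AUC, with a correlation-based knn classifier
   (`k = 15`) as benchmark and a 2-fold variant for sample-size
   robustness.

A synthetic-data generator with a planted, heterogeneously perturbed
disease module makes every stage testable end-to-end, with known ground
truth and no downloads.

## Worked example

```r
library(peepr)

# 5000 genes, 25 controls + 40 cases; a 200-gene disease module of which
# each case perturbs a random half at 4 control-sds, plus 100 private
# background perturbations per subject (cases and controls alike)
sim <- simulate_dataset(simulation_config(seed = 1))
z   <- compute_zscores(sim$data)
peeps <- build_peeps(z, z_thresh = 2.5)
peeps[["case01"]]
#> peep 'case01': 120 up, 117 down (|z| > 2.5)

case_ids <- sample_ids(sim$data)[sim$data$labels == "case"]
pool <- build_pool(peeps[case_ids], z$universe)
pool
#> disease_pool: 198 genes in >= 10 of 40 cases (X_rand = 9, g = 241.7, p = 0.04834, G = 5000)
pool_recovery(pool, sim$module)
#> precision    recall
#>      1.00      0.99

pool_fraction(peeps[["case01"]], pool)   # 0.475
pool_fraction(peeps[["ctrl01"]], pool)   # 0.025

ov <- pairwise_overlap_significance(peeps[case_ids], length(z$universe))
mean(ov$jaccard)        # 0.118  -- cases share little at the gene level...
mean(ov$significant)    # 1      -- ...yet far more than chance (Bonferroni)

cross_validate(sim$data, n_repeats = 10, seed = 1)
#> peep_cv (peep, 5-fold x 10 repeats): AUC = 1.000 +/- 0.000
```

Reading the numbers: each case's barcode holds ~240 genes, of which only
~100 come from the disease module — any two cases share ~12% of their
profiles (Jaccard 0.118), yet every case pair overlaps far beyond chance.
The pool recovers 198 of the 200 planted module genes with no false
positives; cases contain ~47% of the pool against ~2.5% for controls, so
held-out subjects separate perfectly (AUC 1.0).

Group-wise DE (`run_de`), profile stability under control subsampling
(`stability_analysis`), gene-set enrichment (`enrich_peeps`,
`pathway_heterogeneity`) and the knn benchmark (`knn_classify`,
`knn_sweep`) follow the same pattern; see the methods vignette
(`vignettes/perturbation-profiles.Rmd`) for the model details and design
rationale.

## Command line

A thin wrapper over the same functions is installed as `exec/peeptool`:

```sh
peeptool simulate --seed 1 --out sim/
peeptool profiles --matrix sim/matrix.tsv --labels sim/labels.tsv --out prof/
peeptool pool     --peeps prof/peeps.tsv --labels sim/labels.tsv --out pool/
peeptool classify --matrix sim/matrix.tsv --labels sim/labels.tsv \
                  --repeats 100 --seed 17 --out cls/
```

Every output directory receives a `manifest.json` with the package
version, parameters, seed and input checksums; identical inputs and seeds
reproduce outputs byte-for-byte.

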