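# comepi

Co-occurrence and mutual-exclusivity (COME) analysis of DNA promoter
methylation across tumor cohorts.

## The problem

Promoter hypermethylation silences genes. Across a cohort, two genes can be
methylated together far more often than chance (**co-occurrence, CO** —
e.g. a shared upstream driver) or far less often (**mutual exclusivity,
ME** — e.g. redundant hits on one pathway). Finding such pairs is harder
than it looks: genes differ in their baseline methylation rates and samples
differ enormously in their overall methylation load, and any test that
ignores this calls thousands of false pairs. `comepi` is for computational
biologists who want the full path from probe-level beta values to
survival-stratified methylation subtypes, with the statistics done
carefully and every stage testable on synthetic cohorts with known ground
truth.

## The statistic at the core

Gene `g` in sample `s` is methylated when its promoter-average beta (mean of
the probes in the first non-empty class of TSS1500, TSS200, 1stExon, 5'UTR)
exceeds 0.3. The binary matrix is tested against the background model

    P(X_gs = 1) = logis(u_g + v_s),

with gene effects `u` and sample effects `v` fitted so that expected row and
column sums match the observed ones exactly (margin calibration, tolerance
1e-6). For a pair `(a, b)` the observed overlap — samples methylated in
both — is compared with its exact null distribution: a Poisson-binomial sum
over samples of the joint probabilities `P(a,s) P(b,s)`, computed by exact
dynamic programming (no normal approximation). The upper tail is the CO
p-value, the lower tail the ME p-value; Benjamini–Hochberg is applied per
family and pairs are called at `q <= 0.05`.

Downstream, events are filtered by tumor-vs-normal differential occurrence
(two-sided Fisher exact, p <= 0.05 per cancer) and kept when differential in
at least three cancer types; the survivors form CO/ME networks (hub genes,
cancer-gene fractions), functional epigenetic modules (connected subnetworks
with coordinated differential methylation + expression, permutation-tested),
and consensus-clustering subtypes (k-means over subsamples; k chosen by
CDF-elbow or maximum average silhouette) compared by log-rank on
progression-free interval and by Kruskal-Wallis / chi-square on clinical
features.

## Worked example

```r
library(comepi)

# a seeded synthetic cohort: 3 cancers x (100 tumors + 30 normals),
# planted CO/ME pairs and 3 subtypes with distinct event signatures
spec   <- cohort_spec(seed = 7)
cohort <- simulate_cohort(spec)

summary <- run_pipeline(
  inputs  = list(beta = cohort$beta, manifest = cohort$manifest,
                 expr = cohort$expr, clinical = cohort$clinical,
                 annotation = cohort$annotation),
  out_dir = "come_run",
  config  = default_run_config(seed = 7)
)
str(summary$stages$filter)
#> List of 3
#>  $ n_differential: int 105
#>  $ n_frequent    : int 33
#>  $ min_cancers   : num 3
str(summary$stages$survive)
#> List of 3
#>  $ chi2   : num 17.6
#>  $ p_value: num 2.74e-05
#>  $ df     : num 1
```

33 events came out differentially occurring in all three synthetic cancers
(the planted CO/ME pairs plus the subtype signature events), and the
consensus subtypes built from them separate progression-free survival at
chi-square 17.6 (log-rank p = 2.7e-5) — the planted hazard ratio between
subtypes is 3. Stage artifacts (`frequent.tsv`, `edges.tsv`,
`clusters.tsv`, `km_curves.tsv`, ...) are plain TSV in `come_run/`, and a
rerun with the same seed reproduces them byte for byte.

Individual stages are ordinary functions returning tibbles:

```r
bm  <- binarize(aggregate_promoter(cohort$beta, cohort$manifest))
ev  <- test_all_pairs(filter_genes(bm[, cohort$clinical$sample_id[cohort$clinical$is_tumor]]))
dplyr::count(ev, call)
#> # A tibble: 3 x 2
#>   call      n
#>   <chr> <int>
#> 1 CO       33
#> 2 ME       46
#> 3 none   3081
```

Fitted objects have `tidy()` / `glance()` methods and result types have
`autoplot()` / `plot_*()` helpers (KM curves, consensus CDFs, hub
fractions, correlation boxplots).

A thin command-line wrapper ships in `inst/cli/come-methyl`
(`come-methyl simulate`, `come-methyl all --config run.yaml`).

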