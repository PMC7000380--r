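---
title: "Co-occurrence and mutual exclusivity of promoter methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence and mutual exclusivity of promoter methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comepi)
```

## The analysis in one paragraph

Promoter hypermethylation silences genes, and pairs of genes can be
methylated together far more often (co-occurrence, CO) or far less often
(mutual exclusivity, ME) than independent alteration would predict.
`comepi` turns probe-level beta values into gene-level binary methylation
calls, tests every gene pair against a background model that respects both
per-gene alteration rates and per-sample methylation load, filters the
significant events by tumor-versus-normal differential occurrence and
cross-cancer recurrence, assembles the surviving events into networks, mines
those networks for functional epigenetic modules (coordinated differential
methylation and expression), and clusters tumors on their event profiles
into subtypes whose progression-free interval (PFI) and clinical features
are then compared.

## From probes to binary calls

A gene's promoter methylation is the mean beta value of the probes in the
first non-empty region class along the priority order **TSS1500, TSS200,
FirstExon, 5'UTR**. We read the class list as a precedence scheme rather
than pooling across classes: the classes differ systematically in their
relationship to silencing, and precedence keeps each gene's summary
homogeneous. Gene-body probes never contribute. A gene with no promoter
probe is dropped; a gene-sample cell whose selected probes are all missing
is missing.

Binarization calls a gene methylated when its promoter average **strictly
exceeds 0.3**. The two plausible conventions (`>` vs `>=`) differ only on
the measure-zero boundary; we use the strict form and unit-test the boundary
(`0.3 -> 0`, `0.31 -> 1`). Missing promoter averages are imputed as
unmethylated — conservative for co-occurrence, since imputation can only
remove overlap — and the number of imputed cells is reported. Before pair
testing, genes methylated in fewer than 5% or more than 95% of samples are
removed: near-constant rows carry almost no pairwise information and sit on
the boundary of the background model's margin equations.

## The background model and the pair test

The null model for the binary matrix is logit-additive:

$$\Pr(\text{gene } g \text{ methylated in sample } s)
  = \mathrm{logis}(u_g + v_s),$$

with the gene effects $u_g$ and sample effects $v_s$ calibrated so that
every gene's expected methylated-sample count equals its observed row sum
and every sample's expected methylated-gene count equals its observed
column sum. This is the canonical "independent given margins" null: it
keeps genes with high alteration rates and samples with high methylation
load from masquerading as biology. Fitting alternates damped Newton solves
of the two separable blocks from the deterministic start $u = v = 0$ until
both margin residual maxima fall below $10^{-6}$. Margins at 0 or the
dimension limit are clipped half a count inside the boundary; after
clipping, the column targets are rescaled so the two margin totals agree
again (otherwise the system is inconsistent and no fit can converge).

For a pair $(a, b)$ the per-sample joint null probability is
$p_s = \Pr(a,s)\Pr(b,s)$ and the overlap count — samples methylated in both
genes — is Poisson-binomial across samples. Both tails are computed
**exactly** by the truncated convolution recurrence in
$O(n \cdot \min(x, n-x))$; no normal approximation is used at any size, so
there is no accuracy threshold to tune. `p_co` is the upper tail (at least
the observed overlap), `p_me` the lower tail. False-discovery control is
Benjamini–Hochberg applied separately within the CO and the ME p-value
families; a pair is called at `q <= 0.05`, with the smaller raw p deciding
if both families pass.

Two calibration facts shape how results should be read. First, ignoring
the per-sample load is catastrophic: a pooled-rate binomial test on the
same null data (heterogeneous loads, 200 genes by 300 samples) calls about
27% of pairs co-occurring at $\alpha = 0.05$; the stratified test calls
0.7%. Second, the stratified test is *conservative*, not exactly nominal:
because the background probabilities are fitted to the observed margins,
the overlap's true dispersion is the margin-conditional one, which is
smaller than the unconditional Poisson-binomial variance used in the tail.
With the true generating probabilities the CO tail is nominal (measured
0.048 at $\alpha = 0.05$); with fitted margins it drops to roughly 0.007.
This trades some power for strict false-positive control and is a known
property of this family of tests; the planted-event benchmarks below show
the power that remains is ample at cohort scale.

## Event filtration

Per-sample event occurrence is defined as: a CO event occurs where **both**
genes are methylated; an ME event occurs where **exactly one** is. For each
called event and cancer, the 2×2 table (tumor/normal × occurred/not) is
tested with the two-sided Fisher exact test at an unadjusted per-cancer
$\alpha = 0.05$; no multiplicity correction is applied at this stage
because the next rule — keep events differentially occurring in **at least
three cancer types** — acts as the replication filter. An empty result is
legitimate (a cancer can retain nothing) and propagates as an explicit
skipped status rather than an error.

## Networks and functional epigenetic modules

Retained events form a network: genes are nodes, events are typed edges
(a CO and an ME edge may coexist between one pair), per-cancer networks
merge into a pan-cancer network by union, with supporting-cancer sets
unioned. Degree counts both edge types; hub tables report, for each
top-$N$ degree prefix, the fraction of genes flagged as cancer genes or
tumor suppressors.

Module search scores each gene by
$w_g = (|t_{\text{meth}}| + |t_{\text{expr}}|)/2$ — Welch t statistics for
tumor-versus-normal promoter methylation and expression, variances floored
at $10^{-12}$ so degenerate groups yield large finite values — and looks
for connected subnetworks of coordinated signal. Seeds are the top 1% of
nodes by weight (at least 5), restricted to nodes above the baseline
$\bar w$, the mean weight over the *whole statistics universe*. The
baseline is genome-wide rather than network-restricted deliberately: a
frequent-event network is made of signal genes by construction, and a
network-mean baseline would declare nothing a module. From each seed the
expansion repeatedly admits the highest-weight neighboring gene whose
weight exceeds the midpoint of the module's current mean node weight and
$\bar w$, stopping when no admissible neighbor remains or the module
reaches 50 genes. This admission rule, rather than "add only if the mean
edge weight rises", is what we ship: the mean-edge objective is maximized
by the single best edge, so strict-improvement greedy stalls at size two
under noisy weights, whereas the midpoint rule admits signal-level genes
even when they do not raise the mean and never admits background-level
ones. The reported module score remains the mean induced-edge weight
$(w_i + w_j)/2$.

Significance uses permutations of the node statistics over the fixed
topology: the full search is re-run on each permutation and each observed
module's **total** induced edge weight is compared with the permutation
maxima ($p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{\text{perm}})$).
The total, not the mean, is the test statistic because a permutation
occasionally throws a handful of high weights onto adjacent nodes and ties
the observed *mean* while falling far short of the observed *extent*.
On 100-node networks with a planted 8-gene module (|t| inflated by 5),
recovery is essentially perfect (Jaccard 1.0 in most seeds, ≥ 0.6 with
$p \le 0.05$ in well over 90% of runs).

## Subtypes, survival and clinical features

Tumors are profiled on the frequent events (event-by-sample 0/1 matrix)
and consensus-clustered: for each candidate $k$ (default 2–8), 100
subsamples of 80% of samples are clustered by k-means (Euclidean distance
on the binary profiles — squared Euclidean on 0/1 data is Hamming up to a
constant; `stats::kmeans` with 10 random restarts per run under a
deterministic per-replicate seed stream stands in for an explicit
farthest-point initialization), and the consensus matrix records
co-clustering frequencies among co-sampled pairs. Final labels come from
average-linkage hierarchical clustering of $1 - \text{consensus}$ cut at
$k$.

Two selection rules are provided. *Silhouette*: the $k$ maximizing the
average silhouette width on $1 - \text{consensus}$. *CDF elbow*: walk $k$
upward while the relative increase in the area under the consensus CDF is
at least 0.1 — the proportional-area operationalization of the visual
elbow. Ties break toward smaller $k$. A limitation worth knowing: on
genuinely i.i.d. noise the consensus-CDF area keeps growing with $k$ (the
well-documented overfitting behavior of consensus clustering), so the
area rule alone will not fall back to the minimum $k$ there; the
silhouette rule does.

Survival uses the product-limit estimator and the standard
observed-minus-expected log-rank statistic with hypergeometric variance
(through the `survival` package), PFI as the sole endpoint. Records with
zero events overall return $p = 1$ by convention. Clinical features are
tested across subtypes with Kruskal–Wallis (continuous) and Pearson
chi-square without continuity correction (categorical); both choices are
configurable but match common library defaults.

## What the synthetic cohorts emulate — and what they do not

The generators produce every input the pipeline consumes, with ground
truth attached:

* **Probe betas** are drawn from Beta(2, 18) (mean 0.1) for unmethylated
  and Beta(12, 8) (mean 0.6) for methylated gene-sample states — bimodal
  with small overlap around the 0.3 threshold, so aggregation plus
  binarization recovers the generating state for ≥ 99% of cells.
* **Null structure**: per-sample loads $0.8 \cdot \text{Beta}(2,5)$ times
  per-gene rates uniform on [0.5, 1.5] — the heterogeneity that breaks
  naive tests.
* **Planted CO** pairs share a latent driver (both genes = driver OR a
  10% leak); **planted ME** pairs show an exactly-one pattern with
  probability 0.8 and background otherwise. Both mechanisms have
  closed-form marginals, which the tests check.
* **Subtypes**: each subtype owns a connected chain of signature genes
  driven by one subtype-specific driver (85% in the subtype, 10%
  elsewhere), so signature events both separate subtypes and form
  connected subnetworks for the module stage; signature genes get
  expression anti-correlated with promoter methylation (epigenetic
  repression) and background-typical rates.
* **Tumor/normal contrast**: normals carry background only, creating the
  differential occurrence the Fisher stage detects.
* **Survival and clinical covariates**: exponential PFI with per-subtype
  hazards (default 0.004/0.002/0.0013 events per day, hazard ratio 3
  between extremes) and independent exponential censoring targeting 30%;
  age, gender, stage, grade and histological type distributions shift
  with subtype.

The default cohort is three cancers × (100 tumors + 30 normals) × 80
genes — sized so every stage has realistic power at desk scale. What the
generators deliberately do **not** model: probe-level measurement error
correlated within samples (batch effects), tumor purity and cell-type
composition, genomic proximity of probes, copy-number-driven methylation
changes, and realistic gene-gene correlation beyond the planted
mechanisms. Passing tests therefore demonstrate that the statistics do
what they claim under controlled heterogeneity, not that real TCGA-scale
results would be reproduced numerically.

## Numerical and design choices

* Exact Poisson-binomial tails everywhere; the DP is run from the shorter
  tail so cost is $O(n \cdot \min(x, n-x))$ per pair (compiled).
* Background fit: deterministic zero start, damped Newton (step clamp ±4),
  tolerance $10^{-6}$ per margin, hard error on non-convergence.
* Gene pairs are unordered; keys are canonicalized lexicographically at
  every boundary, so `(A,B)` and `(B,A)` cannot diverge.
* All tabular artifacts are TSV (UTF-8, Unix newlines, `NA` for missing)
  with floats at 10 significant digits; writers sort rows deterministically
  so identical inputs produce byte-identical files.
* Every source of randomness flows from one seed through a documented
  integer derivation (`(seed * 1000003 + offset) mod (2^31 - 1)`), making
  the full pipeline byte-reproducible.
* Problem sizes used in the validation suite (chosen as the smallest
  cohorts at which the planted effects are clearly detectable): 200–500
  genes, 300 tumors for pair testing; 200 samples × 60 events for
  subtyping; 100-node networks for modules; 150 patients per arm for
  survival.

## Known limitations

* The pair test is conservative under its own fitted background (see
  above); borderline events near `q = 0.05` are under-called rather than
  over-called.
* The CDF-elbow rule does not fall back to the minimum $k$ on pure noise.
* ME events are scarcer than CO events in cohorts whose dependence comes
  from shared drivers; the ME lower tail is also intrinsically more
  discrete at realistic overlap counts.
* Module significance requires contrast within the statistics universe: a
  network consisting entirely of equally strong signal genes yields no
  significant module by construction, as the permutation null then
  reproduces observed coordination.
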