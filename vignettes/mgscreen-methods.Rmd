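---
title: "Methods: dose-response gene screening with mgscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response gene screening with mgscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mgscreen` implements a downstream inference cascade for ordered-dose bulk
RNA-seq experiments — the motivating design is tea seedlings grown
hydroponically at 0, 0.4 and 0.8 mmol/L Mg with three biological replicates
per level — together with a synthetic-data module that generates inputs with
known planted structure. This vignette documents the models, the tunable
parameters, the numerical choices, and what validation on synthetic data
does and does not establish.

## The data model

The pipeline starts from a gene-level count table with gene lengths, a
sample design table mapping samples to ordered treatment levels, a GMT
term-to-gene annotation and (optionally) a physiochemical index table.
Counts are normalized to FPKM,

$$\mathrm{FPKM}_{gj} = \frac{c_{gj}}{(L_g/10^3)\,(N_j/10^6)},$$

with $L_g$ the gene length in bp and $N_j$ the per-sample assigned total.
FPKM is a *relative* measure: a strong induction of a few genes inflates
$N_j$ and deflates every other gene's FPKM in that sample. This
compositional coupling is real, visible in the synthetic data (see below),
and deliberately not corrected — the cascade mirrors an FPKM-based analysis
convention, not a compositional one.

## Differential expression at three replicates

Fold changes are computed on group-mean FPKM with a pseudo-count of 1,
$\log_2((\bar x_B + 1)/(\bar x_A + 1))$; the pseudo-count keeps zero-mean
genes finite and damps ratios of very small FPKMs. Significance comes from
a two-sample t-statistic on $\log_2(\mathrm{FPKM}+1)$. With $n = 3$ per
group an unmoderated Welch test has 2–4 degrees of freedom; after
Benjamini–Hochberg correction across thousands of genes its power is
essentially zero, so the default test shrinks per-gene pooled variances
toward an empirical-Bayes prior: the scaled-inverse-$\chi^2$ prior
$(d_0, s_0^2)$ is fitted by moment-matching on $\log s^2_g$ (Newton
inversion of the trigamma function), the posterior variance is
$s^2_{\mathrm{mod}} = (d_0 s_0^2 + d s^2_g)/(d_0 + d)$, and the statistic is
referred to a t distribution on $d_0 + d$ degrees of freedom. The unit tests
verify this agrees with the independent limma implementation to numerical
precision and that both methods keep the null type-I error near nominal on
simulated null counts. `method = "welch"` restores the plain test.

A gene is *called* when $q < 0.05$ and $|\log_2\mathrm{FC}| \ge 1$
(`thresholds$q`, `thresholds$fc`). A gene *trends up* when its three group
means strictly increase **and** it is called in both adjacent comparisons;
ties or single-comparison significance yield `none`. Strictness makes the
trend label conservative and deterministic.

## OPLS-DA, VIP and validation

Key-gene screening uses a two-class orthogonal partial least squares
discriminant analysis implemented from scratch (no CRAN/Bioconductor
package in the dependency set provides OPLS). Design choices, all
overridable:

* **Scaling**: columns are mean-centered and unit-variance scaled
  (autoscaling), the common chemometrics default; `y` is coded $\pm 1$ and
  centered.
* **Components**: two classes need exactly one predictive component. For
  each of `n_ortho` orthogonal components the y-orthogonal part of the
  provisional loading, $w_o \propto p - (w^\top p)\,w$, is extracted and
  deflated; the predictive component is one NIPALS PLS1 round on the
  deflated matrix. `select_n_ortho()` scans $0..5$ and keeps the smallest
  count maximizing cross-validated $Q^2$.
* **Sign convention**: the first non-negligible entry of $w$ is forced
  positive, so refits are reproducible. A consequence is that relabeling
  the classes negates the y-loading $c$ and the predictions but not the
  scores $t$; $R^2Y$, $Q^2$ and VIP are invariant either way.
* **Cross-validation**: class-stratified K-fold with $K = 7$ by default,
  capped at the sample count (so 3 + 3 designs use leave-one-out);
  $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ with SS about the overall coded
  mean. Fold assignment is deterministic given a seed.
* **Permutation test**: labels are permuted uniformly `n_perm = 199` times
  and the model refitted and cross-validated each time; the add-one rule
  $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$
  makes 0.005 the smallest attainable p-value. At $n = 3+3$ only 20
  distinct label assignments exist and a uniform draw reproduces the
  observed partition (identically or mirrored) with probability 0.1, so
  reported p-values at that depth bottom out near 0.05-0.1; the 0.005 floor
  is attainable from about 6 + 6 samples upward. This is an honest property
  of exact label permutation at small n, not a defect of the model.
* **VIP**: for a single predictive component the SSY-weighted definition
  collapses to $\mathrm{VIP}_j = \sqrt{J}\,|w_j|$ with
  $\mathrm{mean}(\mathrm{VIP}^2) = 1$ exactly; $\mathrm{VIP} > 1$ is the
  conventional screening cut. S-plot coordinates (covariance and Pearson
  correlation of each scaled variable with $t$) are exported for
  inspection; zero-variance variables get `NA` correlation.

The OPLS input in the pipeline is $\log_2(\mathrm{FPKM}+1)$ over all
non-constant genes of the two groups being compared. Fitting on all genes
(rather than a pre-filtered significant subset) keeps the VIP universe
aligned with the trend table, which is what the key-gene intersection
requires.

## Key genes, characteristic genes

Key genes satisfy $\mathrm{VIP} > 1$ in *both* adjacent-dose models and
have a monotone trend; they are partitioned up/down by the trend label, not
by loading sign. The characteristic subset ranks key genes by total FPKM
across all samples (ties broken lexicographically by gene id) and takes the
shortest prefix whose cumulative share reaches `coverage = 0.9`. A greedy
largest-first prefix is the minimal-cardinality solution for a
cumulative-share rule; the tests verify minimality by exhaustive prefix
scan.

## Enrichment and pathway profiles

Term enrichment is the hypergeometric upper tail
$p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$
with BH adjustment within the tested family and significance at
$q < 0.05$. The universe is all genes in the count table — the screening is
transcriptome-wide, so annotation-restricted universes would overstate
enrichment; this is configurable by passing a different `universe`.
Pathway profiles sum member-gene FPKM per sample and classify the group
means: strictly increasing = `up`, strictly decreasing = `down`, middle
group strictly below both ends = `V`, anything else (including ties and
all-zero profiles) = `other`. Pairwise Welch tests with BH adjustment
accompany the profiles as a compact significance readout.

## Integration

* **RDA** — pathway totals (response) are regressed on a configurable
  subset of physiochemical indexes (default: the five quality indexes, so
  the explanatory count stays below the nine samples). Both matrices are
  centered and unit-variance scaled because the indexes carry heterogeneous
  units (SPAD, relative fluorescence, mg/g); the ordination is vegan's RDA,
  and the constrained fraction equals the least-squares projection share of
  the response variance (cross-checked against an independent projection
  oracle in the tests). Rank-deficient explanatory matrices are rejected
  with the collinear columns named.
* **Correlation network** — all pairwise Pearson correlations among Mg
  level, physio indexes and pathway totals; edges kept at $|r| \ge 0.8$ and
  $p < 0.05$ (t transform, $n-2$ df). P-values are uncorrected by default —
  the network is a descriptive sign/strength display — with BH available
  via `adjust = TRUE`. Zero-variance variables are skipped with a warning.
* **Entropy-weighted TOPSIS** — the method needs criterion weights and no
  expert weighting is available, so weights come from information entropy:
  columns are min-shifted to non-negative, normalized to proportions,
  $e_j = -\frac{1}{\ln m}\sum_i p_{ij}\ln p_{ij}$ (with $0\ln 0 := 0$), and
  $w_j \propto 1 - e_j$; a constant criterion carries no information and
  gets weight zero. TOPSIS vector-normalizes columns (making rankings
  invariant to per-criterion rescaling), applies the weights, and ranks
  samples by closeness to the polarity-respecting ideal point. The pipeline
  treats samples as alternatives and reports criterion weights for three
  families separately (photosynthetic indexes, quality indexes, pathway
  totals), which is the reading that makes "which index is most affected
  by Mg" a well-posed weight question.

## The synthetic-data generator

The generator defines the validation conditions; it emulates the study
design, not any particular deposited dataset.

* **Counts**: NB with $\mathrm{Var} = \mu + \phi\mu^2$ ($\phi = 0$ is the
  Poisson limit). Per-gene base means are log-normal
  ($\log\mu \sim \mathcal N(\log 100, 1)$) so the cumulative-coverage
  filter faces a realistic dynamic range; gene lengths are uniform on
  500–5000 bp; defaults are 3000 genes, 150 planted up + 150 planted down
  at `effect_log2fc = 2` per dose step, dispersion 0.1 — a typical
  overdispersion for bulk RNA-seq with good replicates.
* **Annotation**: up to four planted terms draw `enrich_frac = 0.8` of
  their members from planted genes (two per direction); the rest sample
  uniformly. Planted term ids are recorded for recovery checks.
* **Physio table**: ten indexes with strictly monotone group-mean profiles
  (photosynthetic indexes, theanine and soluble sugar rising; tea
  polyphenol, flavone and caffeine falling) and 5% multiplicative Gaussian
  replicate noise. The paper-scale profile values (SPAD ~45–60,
  Fv/Fm ~0.72–0.81, contents in mg/g) are the package's own choices — no
  replicate-level variances were available to emulate — and the noise CV
  matches the tolerance scale of a controlled greenhouse protocol.

What the generator does *not* emulate: batch effects, GC/length bias,
correlated co-expression modules, unbalanced designs, and annotation
incompleteness. Passing recovery tests on this generator therefore shows
the cascade's filters behave as specified under their own assumptions; it
does not certify performance on real tissue data.

One emergent feature worth knowing: because FPKM is relative, strongly
induced planted genes inflate the library total and push *all* null genes
into small coherent dose trends. At the default effect size this coupling
is mild; at extreme effect sizes it makes null genes genuinely
dose-associated on the FPKM scale, and the moderated test correctly flags
them. Recovery tests are therefore run at the study-regime effect size.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed and restores the caller's RNG state.
  Reruns are byte-identical.
* Zero-variance genes are rejected by the user-facing OPLS fit (autoscaling
  would divide by zero) and neutralized inside cross-validation folds,
  where a gene can be constant in a training split by chance.
* Degenerate DE inputs (all genes zero-variance) fall back to p = 1 for
  zero differences rather than erroring.
* Validation sizes: the test suite exercises the study-scale design
  (3000 × 9) for recovery checks and smaller matrices elsewhere; screening
  recovery and the separable-regime check aggregate five replicate
  simulations each, estimating the property rather than asserting a single
  binomial draw.

## Known limitations

* The trend filter requires exactly three ordered groups; longer dose
  series would need a generalized monotonicity test.
* FPKM (not TPM or a compositional transform) is the normalization by
  convention; conclusions about down-trends partially reflect library
  renormalization.
* Permutation p-values at 3 + 3 samples are floor-limited near 0.1 by the
  label space; treat $Q^2$ as the primary validity readout at that depth.
* The GO/KEGG surrogate is a flat GMT family; DAG-aware enrichment and
  topology-aware pathway scoring are out of scope.
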