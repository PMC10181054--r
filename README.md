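# mgscreen

Magnesium-responsive gene and pathway screening for tea-leaf transcriptomes.

Tea (*Camellia sinensis*) cultivation leans heavily on fertilization, and
magnesium — a cofactor of chlorophyll synthesis and dozens of enzymes — shapes
both yield and leaf quality. A standard way to dissect a dose response is to
grow plants hydroponically across ordered Mg levels (e.g. 0, 0.4 and
0.8 mmol/L with 3 biological replicates), sequence the leaf transcriptome,
and cascade the gene-level counts through trend-filtered differential
expression, multivariate key-gene screening, pathway enrichment, and
integration with physiochemical measurements. `mgscreen` implements that
cascade as a tested, reusable R package for analysts working with small-n,
ordered-dose bulk RNA-seq designs, together with a synthetic-data module
that generates count tables with known planted structure so every stage can
be validated end to end.

## The cascade

1. **Normalization** — counts to FPKM:
   `FPKM_gj = counts_gj / ((length_g/10^3) * (total_j/10^6))`, plus PCA
   contribution rates (eigenvalue fractions) per component.
2. **Differential expression** — per adjacent dose pair, log2 fold changes
   `log2((mean_B + 1)/(mean_A + 1))` on FPKM and a t-test on
   `log2(FPKM + 1)`. The default test moderates per-gene variances toward an
   empirical-Bayes scaled-inverse-chi-square prior (posterior
   `s²_mod = (d₀s₀² + d s²)/(d₀ + d)`, tested on `d₀ + d` df), which keeps
   3-replicate designs powered; plain Welch is available. P-values are
   Benjamini–Hochberg adjusted; calls need `q < 0.05` and `|log2FC| ≥ 1`.
3. **Trend classification** — a gene trends *up* iff its group means strictly
   increase across the three dose levels **and** both adjacent comparisons
   are significant; *down* mirrored.
4. **OPLS-DA screening** — a from-scratch two-class orthogonal PLS: NIPALS
   predictive component after orthogonal-signal deflation, `R²Y`,
   K-fold cross-validated `Q² = 1 − PRESS/SS`, label-permutation p-values
   with the add-one rule (199 permutations ⇒ smallest p 0.005), S-plot
   coordinates, and VIP scores (`VIP_j = √J |w_j|`, so `mean(VIP²) = 1`;
   `VIP > 1` flags influential genes).
5. **Key and characteristic genes** — key genes pass `VIP > 1` in *both*
   adjacent-dose models and carry a monotone trend; the characteristic
   subset is the shortest expression-ranked prefix covering ≥ 90% of the
   key genes' total FPKM (the "bubble map" filter).
6. **Enrichment** — hypergeometric upper-tail tests of the characteristic
   genes against GMT terms with BH correction, plus per-pathway summed
   expression profiles (group means ± SE and trend class).
7. **Integration** — redundancy analysis of pathway expression on
   physiochemical indexes, a thresholded Pearson correlation network
   (`|r| ≥ 0.8`, `p < 0.05`), and entropy-weighted TOPSIS ranking
   (criterion weights from information entropy; alternatives ranked by
   closeness `d⁻/(d⁺ + d⁻)` to the ideal point).

## Worked example

```r
library(mgscreen)

design <- make_design(3)                      # M1 < M2 < M3, 3 replicates
sim <- generate_counts(design, n_genes = 3000, n_up = 150, n_down = 150,
                       effect_log2fc = 2, dispersion = 0.1, seed = 42)
fpkm <- compute_fpkm(sim$counts, sim$lengths)

X <- t(log2(fpkm[, design$sample[design$group %in% c("M2", "M3")]] + 1))
X <- X[, apply(X, 2, sd) > 0]
fit <- fit_opls(X, rep(c("M2", "M3"), each = 3))
print(fit)
#> Two-class OPLS-DA model
#>   samples: 6   variables: 3000   orthogonal components: 0
#>   classes: M2 (-1) vs M3 (+1)
#>   R2Y = 0.9993

print(permutation_test(X, rep(c("M2", "M3"), each = 3),
                       n_perm = 199, seed = 1))
#> OPLS-DA permutation test (199 permutations)
#>   R2Y = 0.9993  (p = 0.13)
#>   Q2  = 0.9392  (p = 0.055)

run <- run_pipeline(list(seed = 42, out_dir = "mg_run"))
print(run)
#> mgscreen pipeline run: mg_run
#>   genes 3000, samples 9
#>   trend: 111 up / 139 down
#>   key genes: 250 (111 up, 139 down); characteristic: 95
#>   significant terms: 2
```

Reading the numbers: the two dose groups are linearly separable in gene
space (`R²Y ≈ 1`) and the cross-validated `Q² = 0.94` confirms real
predictive structure rather than overfit — though with only 3 + 3 samples
the permutation p-value cannot go below ~0.05, because a random relabeling
reproduces the observed partition about 1 time in 10. Of the 300 planted
dose-responsive genes, 250 survive the full VIP ∩ trend screen (zero false
positives here), and 95 of them carry ≥ 90% of the key genes' expression.
The two significant terms are exactly the two planted pathways. Stage
tables (`screening.tsv`, `enrichment.tsv`, `network_edges.tsv`, …) and a
`report.json` funnel summary land in the output directory, and a rerun
with the same seed reproduces them byte for byte.

A thin CLI over the same functions lives at `inst/scripts/mgscreen.R`
(`simulate`, `normalize`, `de`, `opls`, `screen`, `enrich`, `integrate`,
`run-all`).

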