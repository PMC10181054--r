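Package: mgscreen
Title: Magnesium-Responsive Gene and Pathway Screening for Tea Leaf
    Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Downstream inference cascade for detecting magnesium-responsive
    genes and pathways in bulk tea-leaf transcriptomes grown under ordered Mg
    dose levels. Normalizes gene-level counts to FPKM, performs moderated-t
    differential expression with Benjamini-Hochberg correction and monotone
    trend classification across dose levels, screens key genes by two-class
    OPLS-DA variable importance (VIP) with cross-validated Q2 and permutation
    validation, reduces key genes to a characteristic subset by cumulative
    expression coverage, tests term enrichment by the hypergeometric
    distribution, and integrates pathway expression with physiochemical
    indexes through redundancy analysis, thresholded correlation networks and
    entropy-weighted TOPSIS. Includes a negative-binomial synthetic-data
    generator with planted monotone genes, planted enriched terms and monotone
    physiochemical profiles, so the whole cascade can be exercised and
    validated at desk scale with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
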