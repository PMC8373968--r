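Package: lncLandscape
Title: Cross-Dataset Differential Expression Landscapes of Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping long noncoding RNA (lncRNA)
    expression landscapes across several expression datasets with
    overlapping but non-identical group coverage, as arises when RNA-seq
    and microarray cohorts of tumour histological subtypes are analysed
    jointly. Provides platform-specific preprocessing (low-count
    filtering, trimmed-mean-of-M-values scaling, log-CPM with
    mean-variance precision weights for counts; quantile normalization
    and probe collapse for arrays), per-gene linear modelling with
    empirical-Bayes variance moderation and Benjamini-Hochberg false
    discovery control, cross-dataset validation of differential calls,
    a decision cascade assigning each lncRNA to a common or
    subtype-specific category, and guilt-by-association functional
    inference via Pearson coexpression and Fisher exact gene-set
    enrichment. A synthetic-data generator plants category structure,
    coexpression modules and enriched gene sets with a full ground-truth
    table so every stage can be scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR
Config/testthat/edition: 3
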