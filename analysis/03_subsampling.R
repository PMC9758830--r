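#!/usr/bin/env Rscript

# How many regions are enough? For every tumor with at least 5 regions,
# enumerate all k-region subsets (k = 2 .. m), recompute the raw and
# normalized diversity scores on each subset against the fixed full-cohort
# PCA basis, and summarize their stability as the coefficient of variation
# (CV) and the coefficient of deviation from the full-region gold standard
# (CD).

suppressPackageStartupMessages(library(hetgeo))

expr   <- read_expression("data/cohort/expression.tsv")
meta   <- read_metadata("data/cohort/metadata.tsv")
coords <- read_coordinates("data/cohort/coordinates.tsv", meta)

emb <- fit_pca(expr, meta, n_pcs = 15)
counts <- table(emb$patient)
tumors <- names(counts)[counts >= 5]
cat("subsampling", length(tumors), "tumors with >= 5 regions\n")

res <- do.call(rbind, lapply(tumors, function(p) {
  m <- counts[[p]]
  out <- subsample_experiment(emb, coords, p, k_range = 2:m)
  cbind(patient_id = p, out)
}))
print(res, digits = 3)

agg <- stats::aggregate(res[c("cv_raw", "cv_norm", "cd_raw", "cd_norm")],
                        by = res["k"], FUN = mean, na.rm = TRUE)
cat("\nmean across tumors, by number of regions k:\n")
print(agg, digits = 3)

dir.create("results", showWarnings = FALSE)
utils::write.table(res, "results/03_subsampling.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(agg, "results/03_subsampling_mean.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
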