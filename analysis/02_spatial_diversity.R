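#!/usr/bin/env Rscript

# Patient-level heterogeneity: transcriptomic diversity Div(t) on the first
# 15 principal components, physical sampling diversity Div(p), the
# normalized score Div(t)/Div(p), genomic (Jaccard) diversity, and the
# correlation between molecular and physical pairwise distances.

suppressPackageStartupMessages(library(hetgeo))

expr   <- read_expression("data/cohort/expression.tsv")
meta   <- read_metadata("data/cohort/metadata.tsv")
coords <- read_coordinates("data/cohort/coordinates.tsv", meta)
vars   <- read_variants("data/cohort/variants.tsv")

chk <- validate_bundle(expr, meta, coords, variants = vars)
stopifnot(length(chk$errors) == 0)

dist_sum <- pooled_distance_summary(coords)
cat(sprintf("pooled within-tumor sampling distances: median %.2f (range %.2f-%.2f, %d pairs)\n",
            dist_sum$median, dist_sum$min, dist_sum$max, dist_sum$n_pairs))

scores <- diversity_scores(expr, meta, coords, variants = vars)
scores$ith_class_raw <- classify_ith(setNames(scores$div_t,
                                              scores$patient_id))
print(scores, digits = 3)

# matched within-tumor pairwise distances: physical vs transcriptomic and
# physical vs genomic, per tumor and pooled
tumors <- scores$patient_id
phys <- lapply(tumors, function(p) pairwise_physical_distance(coords, p))
mol <- lapply(tumors, function(p) {
  ids <- rownames(phys[[match(p, tumors)]])
  pairwise_transcriptomic_distance(expr, ids)
})
gen <- lapply(tumors, function(p) {
  ids <- rownames(phys[[match(p, tumors)]])
  pairwise_genomic_distance(vars[ids])
})
names(phys) <- names(mol) <- names(gen) <- tumors

per_tumor <- distance_correlation(phys, mol)
pooled_t  <- distance_correlation(phys, mol, scope = "pooled")
pooled_g  <- distance_correlation(phys, gen, scope = "pooled")
cat(sprintf("pooled physical-vs-transcriptomic rho %.3f (p %.3g, %d pairs)\n",
            pooled_t$rho, pooled_t$p, pooled_t$n_pairs))
cat(sprintf("pooled physical-vs-genomic rho %.3f (p %.3g, %d pairs)\n",
            pooled_g$rho, pooled_g$p, pooled_g$n_pairs))

dir.create("results", showWarnings = FALSE)
utils::write.table(scores, "results/02_patient_diversity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(per_tumor, "results/02_distance_correlation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
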