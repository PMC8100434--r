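#!/usr/bin/env Rscript
# Immune-infiltration correlates of the NOTCH+/co-DDR+ stratum: ssGSEA
# over the 28 immune-cell signatures, Ward (ward.D) clustering into
# immune-high/intermediate/low, pre-ranked GSEA of the GoodBenefit vs
# BadBenefit contrast, and per-gene contrasts for IL4 / TNFRSF18 / TNFSF15.

suppressMessages(library(copath))

src <- "results/synthetic_cohort"
out <- "results/immune"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

co <- cohort(read_clinical(file.path(src, "clinical.tsv")),
             read_maf(file.path(src, "mutations.maf.tsv")))
amat <- build_alteration_matrix(co, default_catalog())
strata <- assign_strata(amat)
expr <- read_expression(file.path(src, "expression.tsv"))
signatures <- default_immune_signatures()

scores <- score_cohort(expr, signatures, alpha = 0.25)
clusters <- cluster_immune(scores, k = 3)
ranked <- group_rank_list(expr, strata)
gsea <- preranked_gsea(ranked, signatures, n_perm = 1000, seed = 17)
contrasts <- compare_gene_expression(expr, strata,
                                     c("IL4", "TNFRSF18", "TNFSF15"))

write.table(data.frame(sample_id = rownames(scores), scores,
                       check.names = FALSE),
            file.path(out, "ssgsea_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(clusters, file.path(out, "immune_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gsea, file.path(out, "gsea_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(contrasts, file.path(out, "gene_contrasts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sizes <- table(clusters$cluster)
called <- gsea[gsea$call != "ns", c("signature", "nes", "q_value", "call")]
cat(sprintf(
  "Immune clusters: high %d / intermediate %d / low %d.
%d signatures enriched and %d depleted in GoodBenefit (q < 0.10):\n",
  sizes["immune-high"], sizes["immune-intermediate"], sizes["immune-low"],
  sum(called$call == "enriched"), sum(called$call == "depleted")))
print(called, row.names = FALSE)
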