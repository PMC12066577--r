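#!/usr/bin/env Rscript
# Stage 5 -- transcriptome similarity of the DP population: select genes
# differentially expressed between any pair of SPR / DP / SPF (fold change
# >= 2, Welch p < 0.05), place each gene's DP mean on the SPR-SPF axis
# (index +1 = SPR-like, -1 = SPF-like), and bin at +/-0.5 / +/-1.5.

suppressPackageStartupMessages(library(clonefate))

seed <- 20260921
tab <- simulate_expression_table(seed = stage_seed(seed, 31))
res <- similarity_analysis(tab)
write.csv(res$per_gene, "results/similarity.csv", row.names = FALSE)

cat(sprintf("DE union: %d of %d genes\n", length(res$de$union), nrow(tab$expr)))
cat("DE genes per pair:\n"); print(res$de$n_per_pair)
cat("\nsimilarity bin fractions over DE genes:\n")
print(round(res$fractions, 3))
cat(sprintf("\n-> %.0f%% of DE genes are SPR-like, %.0f%% intermediate, %.0f%% distinct\n",
            100 * res$fractions[["SPR-like"]],
            100 * res$fractions[["intermediate"]],
            100 * (res$fractions[["distinct-low"]] + res$fractions[["distinct-high"]])))
cat("\npopulation correlation of mean expression:\n")
print(round(res$correlation, 3))
jsonlite::write_json(
  list(n_de = length(res$de$union),
       de_per_pair = as.list(res$de$n_per_pair),
       bin_fractions = as.list(res$fractions)),
  "results/similarity_summary.json", auto_unbox = TRUE, digits = NA)
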