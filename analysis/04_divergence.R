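#!/usr/bin/env Rscript
# Step 4: global expression divergence. Computes pairwise sample distances
# on the filtered compendium, summarizes them by group-pair class and
# compares the disease-vs-control divergences against the RA-vs-OA
# divergence with the Mann-Whitney U test.
library(raometa)

comp <- read_compendium("results/compendium.tsv")
dm <- distance_matrix(comp)
labels <- comp$samples$group

summ <- summarize_by_class(dm, labels)
cmp <- compare_divergences(dm, labels)

print(summ, row.names = FALSE)
for (i in seq_len(nrow(cmp))) {
  message(sprintf("%s vs %s: U = %.0f, p = %.3g (%s)",
                  cmp$class_a[i], cmp$class_b[i], cmp$U[i], cmp$p_value[i],
                  cmp$direction[i]))
}
message("note: distance pairs share samples, so these p-values are descriptive")

write.table(dm, "results/distance_matrix.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
write.table(summ, "results/distance_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cmp, "results/distance_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/distance_{matrix,summaries,comparisons}.tsv")
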