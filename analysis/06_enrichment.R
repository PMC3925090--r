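#!/usr/bin/env Rscript
# Step 6: gene-set over-representation. Tests the DE gene lists of the two
# disease-vs-control contrasts against the annotation catalog, with the
# presence-filtered gene universe as background, and reports recovery of
# the planted terms.
library(raometa)

comp <- read_compendium("results/compendium.tsv")
sets <- read_gmt("results/synthetic/annotation.gmt")
planted_ids <- vapply(Filter(function(s) grepl("planted", s$term_name), sets),
                      `[[`, character(1), "term_id")

for (ct in c("RA_vs_NT", "OA_vs_NT")) {
  de_tab <- read.delim(sprintf("results/de_%s.tsv", ct))
  de <- de_tab$gene[de_tab$status != "not_significant"]
  res <- enrich(de, comp$genes, sets, fdr = 0.05)
  hit <- res$term_id[res$enriched]
  message(sprintf("%s: %d DE genes; %d terms enriched at FDR < 0.05 (%d of %d planted)",
                  ct, length(de), length(hit),
                  sum(hit %in% planted_ids), length(planted_ids)))
  write.table(res, sprintf("results/enrichment_%s.tsv", ct), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
message("wrote results/enrichment_*.tsv")
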