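#!/usr/bin/env Rscript
# Step 3: harmonization. Reads the simulated per-dataset intensity tables,
# z-scores every array on the log2 scale, merges the datasets on shared
# gene symbols and applies the >60% presence filter.
library(raometa)

indir <- "results/synthetic"
files <- setdiff(list.files(indir, pattern = "^SYN.*\\.tsv$", full.names = TRUE),
                 file.path(indir, "metadata.tsv"))
matrices <- lapply(files, read_expression_tsv,
                   meta_path = file.path(indir, "metadata.tsv"))
comp_all <- build_compendium(matrices)
comp <- presence_filter(comp_all, 0.6)

message(sprintf("union gene space: %d genes over %d samples",
                length(comp_all$genes), nrow(comp_all$samples)))
message(sprintf("%d genes detected in more than 60%% of samples (%d removed)",
                length(comp$genes), length(comp_all$genes) - length(comp$genes)))
write_compendium(comp, "results/compendium.tsv")
message("wrote results/compendium.tsv (+ .json sidecar)")
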