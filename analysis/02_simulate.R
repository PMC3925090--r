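#!/usr/bin/env Rscript
# Step 2: synthetic compendium inputs. Generates six multi-platform
# datasets mirroring the mix of comparison designs in the manifest
# (two-disease, disease-vs-control and RA-only series), together with the
# spike ground truth and an annotation catalog with five planted terms.
library(raometa)

seed <- 1L
cfg <- sim_config(seed = seed)
sim <- simulate_compendium_inputs(cfg)
sets <- simulate_annotation(cfg, sim$truth)

outdir <- "results/synthetic"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
for (m in sim$matrices) {
  write_expression_tsv(m, file.path(outdir, paste0(m$accession, ".tsv")))
}
write_metadata_tsv(sim$matrices, file.path(outdir, "metadata.tsv"))
write_truth_table(sim$truth, file.path(outdir, "truth.tsv"))
write_gmt(sets, file.path(outdir, "annotation.gmt"))

message(sprintf("simulated %d datasets over %d genes (seed %d)",
                cfg$n_datasets, cfg$n_genes, seed))
message(sprintf("spiked genes: %d RA, %d OA (%d shared)",
                sum(sim$truth$spiked_ra), sum(sim$truth$spiked_oa),
                sum(sim$truth$spiked_shared)))
message("wrote ", outdir, "/")
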