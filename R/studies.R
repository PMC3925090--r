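# Seeded simulation studies over the synthetic generator. These drive the
# repository's analysis scripts and the operating-characteristic checks of
# the SAM, divergence and enrichment stages.

#' Two-group study conditions for SAM operating characteristics
#'
#' The reference two-group configuration: 2000 genes, 100 spiked with
#' absolute log2 effects in [1.5, 3], 10 disease vs 10 control arrays
#' (two datasets of 5 + 5, full gene coverage), log2 noise SD 1.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
two_group_config <- function(seed) {
  sim_config(seed = seed, n_genes = 2000L, n_datasets = 2L,
             designs = "RA_NT",
             samples_per_group = c(RA = 5L, OA = 0L, NT = 5L),
             panel_coverage = c(1, 1),
             n_spiked_ra = 100L, n_spiked_oa = 0L,
             shared_spike_fraction = 0,
             spike_log2_effect = c(1.5, 3.0), noise_log2_sd = 1.0)
}

#' Realized FDR and power of the SAM stage on spiked data
#'
#' Runs the full pipeline stage (simulate, harmonize, SAM with default
#' calling criteria) on seeded replicates of [two_group_config()] and
#' scores the calls against the ground truth: the false-discovery
#' proportion (FDP) among called genes and the sensitivity for strong
#' spikes (absolute log2 effect of at least \code{strong_effect}).
#'
#' @param n_reps Number of replicates.
#' @param base_seed Replicate \code{i} uses seed \code{base_seed + i}.
#' @param config_fn Function seed -> [sim_config()]; defaults to
#'   [two_group_config()].
#' @param sam_cfg Base [sam_config()]; the permutation seed is re-derived
#'   per replicate.
#' @param strong_effect Absolute log2 effect defining a "strong" spike.
#' @return Data frame with one row per replicate: \code{seed},
#'   \code{n_called}, \code{fdp}, \code{sensitivity_strong}.
#' @export
sam_operating_characteristics <- function(n_reps = 20L, base_seed = 0L,
                                          config_fn = two_group_config,
                                          sam_cfg = sam_config(),
                                          strong_effect = 2.0) {
  rows <- lapply(seq_len(n_reps), function(i) {
    cfg <- config_fn(base_seed + i)
    sim <- simulate_compendium_inputs(cfg)
    comp <- presence_filter(build_compendium(sim$matrices))
    sam_cfg$seed <- base_seed + i
    fit <- run_sam(comp, sim$matrices, contrast = c("RA", "NT"), sam_cfg)
    res <- fit$results
    truth <- sim$truth[match(res$gene, sim$truth$gene), ]
    called <- res$status != "not_significant"
    fp <- called & truth$delta_ra == 0
    strong <- abs(truth$delta_ra) >= strong_effect
    data.frame(seed = base_seed + i, n_called = sum(called),
               fdp = if (sum(called)) sum(fp) / sum(called) else 0,
               sensitivity_strong = if (sum(strong))
                 sum(called & strong) / sum(strong) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Divergence ordering across seeded replicates
#'
#' Simulates full multi-dataset compendia, computes the pairwise distance
#' matrix and runs [compare_divergences()], recording per seed whether the
#' disease-vs-control divergence exceeds the disease-vs-disease divergence
#' (mean ordering and Mann-Whitney p-values). With
#' \code{shared_spike_fraction} high, the RA-NT and OA-NT distances should
#' dominate RA-OA; with \code{null = TRUE} no effects are spiked at all.
#'
#' @param n_seeds Number of seeded replicates.
#' @param base_seed Replicate \code{i} uses seed \code{base_seed + i}.
#' @param shared_spike_fraction Shared-pathology fraction (default 0.8).
#' @param null Simulate with no group effects (overrides spikes to 0).
#' @param n_genes Gene-universe size per replicate.
#' @return Data frame with per-seed columns \code{p_ra}, \code{p_oa}
#'   (RA_NT vs RA_OA and OA_NT vs RA_OA p-values), \code{dir_ra},
#'   \code{dir_oa} (directions) and \code{mean_ordered} (both
#'   disease-control class means exceed the RA-OA mean).
#' @export
divergence_ordering_study <- function(n_seeds = 50L, base_seed = 0L,
                                      shared_spike_fraction = 0.8,
                                      null = FALSE, n_genes = 2000L) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = base_seed + i, n_genes = n_genes,
                      n_spiked_ra = if (null) 0L else 100L,
                      n_spiked_oa = if (null) 0L else 100L,
                      shared_spike_fraction = if (null) 0 else shared_spike_fraction)
    sim <- simulate_compendium_inputs(cfg)
    comp <- presence_filter(build_compendium(sim$matrices))
    dm <- distance_matrix(comp)
    labels <- comp$samples$group
    cmp <- compare_divergences(dm, labels)
    summ <- summarize_by_class(dm, labels)
    mean_of <- function(cl) summ$mean_distance[summ$pair_class == cl]
    row_of <- function(a) cmp[cmp$class_a == a & cmp$class_b == "RA_OA", ]
    ra <- row_of("RA_NT"); oa <- row_of("OA_NT")
    data.frame(seed = base_seed + i,
               p_ra = ra$p_value, dir_ra = ra$direction,
               p_oa = oa$p_value, dir_oa = oa$direction,
               mean_ordered = mean_of("RA_NT") > mean_of("RA_OA") &&
                 mean_of("OA_NT") > mean_of("RA_OA"))
  })
  do.call(rbind, rows)
}

#' Planted-term recovery of the enrichment stage
#'
#' Simulates the default compendium truth plus annotation, submits the
#' ground-truth spiked genes as the DE list against the full gene universe,
#' and counts how many planted terms are flagged enriched and what fraction
#' of all terms is flagged.
#'
#' @param n_seeds Number of seeded replicates.
#' @param base_seed Replicate \code{i} uses seed \code{base_seed + i}.
#' @param planting_factor Enrichment weight of spiked genes in planted
#'   terms (1 = uniform annotation, no signal).
#' @param fdr FDR cutoff passed to [enrich()].
#' @return Data frame with per-seed \code{n_planted_flagged},
#'   \code{n_planted}, \code{frac_terms_flagged}.
#' @export
enrichment_recovery_study <- function(n_seeds = 20L, base_seed = 0L,
                                      planting_factor = 5, fdr = 0.05) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = base_seed + i, planting_factor = planting_factor)
    sim <- simulate_compendium_inputs(cfg)
    sets <- simulate_annotation(cfg, sim$truth)
    de <- sim$truth$gene[sim$truth$spiked_ra | sim$truth$spiked_oa]
    res <- enrich(de, sim$truth$gene, sets, fdr = fdr)
    planted_ids <- vapply(sets[vapply(sets, `[[`, logical(1), "planted")],
                          `[[`, character(1), "term_id")
    data.frame(seed = base_seed + i,
               n_planted_flagged = sum(res$enriched &
                                         res$term_id %in% planted_ids),
               n_planted = length(planted_ids),
               frac_terms_flagged = mean(res$enriched))
  })
  do.call(rbind, rows)
}
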