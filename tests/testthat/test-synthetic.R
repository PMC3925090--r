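test_that("the generator honors dataset count, panel coverage and designs", {
  cfg <- sim_config(seed = 1, n_datasets = 6)
  sim <- simulate_compendium_inputs(cfg)
  expect_length(sim$matrices, 6L)
  sizes <- vapply(sim$matrices, function(m) length(m$genes), integer(1))
  expect_true(all(sizes >= 0.7 * cfg$n_genes & sizes <= 0.95 * cfg$n_genes))
  # per-dataset groups follow the design template
  grps <- lapply(sim$matrices, function(m) sort(unique(m$groups)))
  expect_equal(grps[[1]], c("OA", "RA"))
  expect_equal(grps[[2]], c("NT", "OA", "RA"))
  expect_equal(grps[[6]], "RA")
  # truth table structure
  expect_equal(sum(sim$truth$spiked_ra), cfg$n_spiked_ra)
  expect_equal(sum(sim$truth$spiked_oa), cfg$n_spiked_oa)
  expect_equal(sum(sim$truth$spiked_shared),
               floor(cfg$shared_spike_fraction *
                     min(cfg$n_spiked_ra, cfg$n_spiked_oa)))
  shared <- sim$truth$spiked_shared
  expect_equal(sim$truth$delta_ra[shared], sim$truth$delta_oa[shared])
  spk <- abs(sim$truth$delta_ra[sim$truth$spiked_ra])
  expect_true(all(spk >= 1.5 & spk <= 3))
})

test_that("the zero-noise no-effect limit yields identical sample columns", {
  cfg <- sim_config(seed = 3, n_genes = 50, n_datasets = 2,
                    designs = "RA_NT",
                    samples_per_group = c(RA = 3L, OA = 0L, NT = 3L),
                    noise_log2_sd = 0, n_spiked_ra = 0, n_spiked_oa = 0,
                    platform_log_offset_sd = 0,
                    platform_gain_range = c(1, 1), term_size = c(5L, 10L))
  sim <- simulate_compendium_inputs(cfg)
  for (m in sim$matrices) {
    expect_true(all(m$values == m$values[, 1]))
  }
})

test_that("identical config and seed give bit-identical outputs", {
  cfg <- sim_config(seed = 11, n_genes = 200, n_datasets = 3)
  a <- simulate_compendium_inputs(cfg)
  b <- simulate_compendium_inputs(cfg)
  expect_identical(a, b)
  expect_identical(simulate_annotation(cfg, a$truth),
                   simulate_annotation(cfg, b$truth))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(term_size = c(10, 5000), n_genes = 2000),
               "term_size")
  expect_error(sim_config(designs = "RA_NT",
                          samples_per_group = c(RA = 0L, OA = 0L, NT = 0L)),
               "zero samples")
  expect_error(sim_config(panel_coverage = c(0.9, 0.7)))
})

small_cfg <- function(seed, planting_factor = 5) {
  sim_config(seed = seed, n_genes = 400, n_datasets = 1, designs = "RA_only",
             samples_per_group = c(RA = 2L, OA = 0L, NT = 0L),
             n_spiked_ra = 40L, n_spiked_oa = 40L, shared_spike_fraction = 0.5,
             n_terms = 20L, term_size = c(10L, 40L), planted_terms = 5L,
             planting_factor = planting_factor)
}

test_that("a saturated term contains the whole gene universe", {
  cfg <- sim_config(seed = 5, n_genes = 100, n_terms = 1,
                    n_spiked_ra = 10L, n_spiked_oa = 10L,
                    term_size = c(100L, 100L), planted_terms = 0L)
  sim <- simulate_compendium_inputs(cfg)
  sets <- simulate_annotation(cfg, sim$truth)
  expect_length(sets, 1L)
  expect_setequal(sets[[1]]$members, sim$truth$gene)
})

test_that("planting_factor = 1 leaves planted terms indistinguishable", {
  # chi-square p comparing spiked-gene content of planted vs background
  # terms should be roughly uniform across seeds when nothing is planted
  ps <- vapply(1:100, function(s) {
    cfg <- small_cfg(s, planting_factor = 1)
    sim <- simulate_compendium_inputs(cfg)
    sets <- simulate_annotation(cfg, sim$truth)
    spiked <- sim$truth$gene[sim$truth$spiked_ra | sim$truth$spiked_oa]
    planted <- vapply(sets, `[[`, logical(1), "planted")
    k <- vapply(sets, function(gs) sum(gs$members %in% spiked), numeric(1))
    size <- vapply(sets, function(gs) length(gs$members), numeric(1))
    tab <- rbind(c(sum(k[planted]), sum(size[planted]) - sum(k[planted])),
                 c(sum(k[!planted]), sum(size[!planted]) - sum(k[!planted])))
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("planted terms over-sample spiked genes in expectation", {
  excess <- vapply(1:50, function(s) {
    cfg <- small_cfg(s)
    sim <- simulate_compendium_inputs(cfg)
    sets <- simulate_annotation(cfg, sim$truth)
    spiked <- sim$truth$gene[sim$truth$spiked_ra | sim$truth$spiked_oa]
    genome_frac <- length(spiked) / cfg$n_genes
    planted <- Filter(function(gs) gs$planted, sets)
    mean(vapply(planted, function(gs) mean(gs$members %in% spiked),
                numeric(1))) - genome_frac
  }, numeric(1))
  expect_gt(mean(excess), 0)
  expect_gt(mean(excess > 0), 0.9)
})

test_that("platform effects shift dataset means but not z-scored profiles", {
  cfg <- sim_config(seed = 8, n_genes = 300, n_datasets = 3,
                    designs = "RA_NT",
                    samples_per_group = c(RA = 4L, OA = 0L, NT = 4L),
                    panel_coverage = c(1, 1),
                    n_spiked_ra = 0, n_spiked_oa = 0,
                    platform_log_offset_sd = 1, noise_log2_sd = 0.3)
  sim <- simulate_compendium_inputs(cfg)
  dataset_means <- vapply(sim$matrices, function(m) mean(log2(m$values)),
                          numeric(1))
  expect_gt(max(dataset_means) - min(dataset_means), 0.2)
  comp <- build_compendium(sim$matrices)
  # same-gene z-profiles correlate strongly across datasets
  c1 <- comp$z[, comp$samples$dataset == "SYN01"][, 1]
  c2 <- comp$z[, comp$samples$dataset == "SYN02"][, 1]
  expect_gt(stats::cor(c1, c2), 0.9)
})
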