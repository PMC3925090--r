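test_that("zscore_sample standardizes exactly and preserves order", {
  expect_equal(zscore_sample(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(10, 20, 30, 40, 50, 100)
  expect_equal(zscore_sample(x), oracle_zscore(x), tolerance = 1e-12)
  # permutation equivariance
  set.seed(1)
  perm <- sample(length(x))
  expect_equal(zscore_sample(x[perm]), zscore_sample(x)[perm])
  # output moments
  for (i in 1:10) {
    v <- stats::rlnorm(50, 8, 1)
    z <- zscore_sample(v)
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(stats::sd(z) - 1), 1e-9)
  }
})

test_that("zscore_sample is invariant under positive affine transforms", {
  set.seed(42)
  for (i in 1:20) {
    x <- stats::rnorm(30, 10, 3)
    a <- stats::runif(1, 0.1, 10)
    b <- stats::runif(1, -5, 5)
    expect_equal(zscore_sample(a * x + b), zscore_sample(x), tolerance = 1e-9)
  }
})

test_that("zscore_sample rejects degenerate input", {
  expect_error(zscore_sample(c(2, 2, 2)), "all values equal")
  expect_error(zscore_sample(c(1, NA, 3)), "non-finite")
  expect_error(zscore_sample(3), "length >= 2")
})

test_that("collapse_duplicates averages repeated symbols in place", {
  m <- rbind(c(2, 4), c(4, 8))
  out <- collapse_duplicates(m, c("A", "A"))
  expect_equal(out$genes, "A")
  expect_equal(unname(out$values[1, ]), c(3, 6))

  m2 <- rbind(c(1, 2), c(3, 4))
  out2 <- collapse_duplicates(m2, c("a", "B"))
  expect_equal(out2$genes, c("A", "B"))
  expect_equal(unname(out2$values), m2)

  # three copies of one symbol against an independent summation
  set.seed(3)
  m3 <- matrix(stats::runif(12, 1, 100), 4, 3)
  out3 <- collapse_duplicates(m3, c("X", "Y", "X", "X"))
  manual <- (m3[1, ] + m3[3, ] + m3[4, ]) / 3
  expect_equal(out3$genes, c("X", "Y"))
  expect_equal(unname(out3$values["X" == out3$genes, ]), unname(manual))
})

test_that("the packaged duplicated-symbol fixture collapses case-insensitively", {
  f <- system.file("extdata", "duplicated_symbols_example.tsv",
                   package = "raometa")
  df <- utils::read.delim(f)
  out <- collapse_duplicates(as.matrix(df[, -1]), df$gene)
  expect_equal(out$genes, c("TNF", "IL6", "COL2A1"))
  expect_equal(unname(out$values[1, ]), c(12, 22, 34))  # mean of three probes
})

make_em <- function(acc, genes, n, seed, groups = NULL) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(length(genes) * n, 6, 1), length(genes), n)
  if (is.null(groups)) groups <- rep(c("RA", "NT"), length.out = n)
  expression_matrix(acc, vals, genes, sprintf("%s_s%d", acc, seq_len(n)), groups)
}

test_that("build_compendium z-scores every column and tracks presence", {
  genes <- sprintf("G%02d", 1:20)
  m1 <- make_em("D1", genes, 3, 1)
  m2 <- make_em("D2", genes, 2, 2)
  comp <- build_compendium(list(m1, m2))
  expect_equal(unname(comp$presence_fraction), rep(1, 20))
  for (j in seq_len(ncol(comp$z))) {
    v <- comp$z[!is.na(comp$z[, j]), j]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(stats::sd(v) - 1), 1e-9)
  }
  # a gene on only one 3-sample panel out of 5 samples has presence 0.6
  m3 <- make_em("D3", c(genes[1:19], "EXTRA"), 3, 3)
  comp2 <- build_compendium(list(m3, m2))
  expect_equal(unname(comp2$presence_fraction["EXTRA"]), 0.6)
})

test_that("gene symbols merge case-insensitively across datasets", {
  m1 <- make_em("D1", c("abc", "DEF"), 2, 1)
  m2 <- make_em("D2", c("ABC", "def"), 2, 2)
  comp <- build_compendium(list(m1, m2))
  expect_setequal(comp$genes, c("ABC", "DEF"))
  expect_equal(unname(comp$presence_fraction), c(1, 1))
})

test_that("the synthetic six-dataset compendium satisfies the column contract", {
  sim <- simulate_compendium_inputs(sim_config(seed = 4, n_genes = 300))
  comp <- build_compendium(sim$matrices)
  mu <- apply(comp$z, 2, function(v) mean(v[!is.na(v)]))
  sd_ <- apply(comp$z, 2, function(v) stats::sd(v[!is.na(v)]))
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(sd_ - 1) < 1e-9))
})

toy_compendium <- function(fracs) {
  # hand-built compendium with prescribed presence fractions
  genes <- sprintf("G%d", seq_along(fracs))
  structure(list(genes = genes,
                 samples = data.frame(sample_id = sprintf("s%d", 1:100),
                                      dataset = "D", group = "RA",
                                      stringsAsFactors = FALSE),
                 z = matrix(stats::rnorm(length(fracs) * 100),
                            length(fracs), 100,
                            dimnames = list(genes, sprintf("s%d", 1:100))),
                 presence_fraction = stats::setNames(fracs, genes)),
            class = "compendium")
}

test_that("presence_filter applies a strict inequality at the threshold", {
  comp <- toy_compendium(c(0.2, 0.6, 0.61, 0.9, 1.0))
  out <- presence_filter(comp, 0.6)
  expect_setequal(out$genes, c("G3", "G4", "G5"))
  # exactly-at-threshold genes go, fully present genes stay
  expect_false("G2" %in% out$genes)
  expect_true("G5" %in% out$genes)
  # idempotent on its own output
  expect_equal(presence_filter(out, 0.6), out)
  expect_warning(presence_filter(toy_compendium(c(0.1, 0.2)), 0.6),
                 "removed all genes")
})

test_that("z-scoring removes between-dataset platform variance", {
  # platform offsets/gains on, no group effects: per-gene one-way variance
  # ratio (between-dataset over within-dataset mean squares) stays near 1
  sim <- simulate_compendium_inputs(
    sim_config(seed = 6, n_genes = 500, n_datasets = 4,
               designs = "RA_NT", samples_per_group = c(RA = 6L, OA = 0L, NT = 6L),
               panel_coverage = c(1, 1), n_spiked_ra = 0, n_spiked_oa = 0,
               platform_log_offset_sd = 1))
  comp <- build_compendium(sim$matrices)
  ds <- comp$samples$dataset
  ratios <- apply(comp$z, 1, function(v) {
    fit <- stats::anova(stats::lm(v ~ ds))
    fit$`Mean Sq`[1] / fit$`Mean Sq`[2]
  })
  expect_lt(mean(ratios), 1.05)
})
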