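test_that("relative_difference matches the pooled-SD formula and is antisymmetric", {
  set.seed(20)
  x <- matrix(sample(1:20, 32, replace = TRUE), 4, 8)
  is1 <- rep(c(TRUE, FALSE), each = 4)
  got <- relative_difference(x, is1, s0 = 0.5)
  want <- oracle_sam(x, is1, s0 = 0.5, deltas = 0)
  expect_equal(got$d, want$d)
  expect_equal(got$s, want$s)
  # swapping labels negates d, leaves s unchanged
  swapped <- relative_difference(x, !is1, s0 = 0.5)
  expect_equal(swapped$d, -got$d)
  expect_equal(swapped$s, got$s)
  # identical class means give d = 0
  xc <- rbind(c(1, 2, 3, 1, 2, 3))
  expect_equal(relative_difference(xc, rep(c(TRUE, FALSE), each = 3), 0.1)$d, 0)
  # zero scatter with s0 = 0 is undefined
  xz <- rbind(c(1, 1, 2, 2))
  expect_error(relative_difference(xz, c(TRUE, TRUE, FALSE, FALSE), 0),
               "zero scatter")
})

test_that("estimate_s0 follows the quantile conventions", {
  expect_equal(estimate_s0(stats::rnorm(100), 1:100, "percentile5"), 5.95)
  set.seed(21)
  for (i in 1:5) {
    s <- stats::rlnorm(200)
    r <- stats::rnorm(200)
    expect_gte(estimate_s0(r, s, "tusher_cv"), 0)
    expect_gte(estimate_s0(r, s, "percentile5"), 0)
  }
  expect_warning(s0 <- estimate_s0(stats::rnorm(10), rep(0, 10)), "floor")
  expect_equal(s0, 1e-8)
  expect_warning(estimate_s0(stats::rnorm(50), stats::rlnorm(50), "tusher_cv"),
                 "fewer than 100")
})

test_that("homoscedastic data yield a flat scatter-window spread at the chosen s0", {
  # equal-variance genes: for fudge factors at or above the median scatter
  # the spread of d barely depends on the scatter window, and the
  # CV-minimizing estimate itself achieves a flat window profile. (At very
  # small s0 the windows differ mechanically: conditioning on the sampled
  # scatter makes the d spread scale as 1/(s + s0) even without real
  # heteroscedasticity.)
  set.seed(22)
  G <- 2000
  x <- matrix(stats::rnorm(G * 20), G, 20)
  is1 <- rep(c(TRUE, FALSE), each = 10)
  rd <- relative_difference(x, is1, 0)
  win <- cut(rank(rd$s, ties.method = "first"), 4, labels = FALSE)
  window_cv <- function(s0) {
    d <- relative_difference(x, is1, s0)$d
    v <- vapply(split(d, win), function(dd) stats::mad(dd), numeric(1))
    stats::sd(v) / mean(v)
  }
  # stabilization improves monotonically with s0 on equal-variance genes
  cvs <- vapply(unname(stats::quantile(rd$s, c(0, 0.5, 1))), window_cv,
                numeric(1))
  expect_true(all(diff(cvs) < 0))
  expect_true(all(cvs < 0.15))
  # and the CV-minimizing estimate achieves a flat window profile
  s0_hat <- estimate_s0(rd$d * rd$s, rd$s, "tusher_cv")
  expect_lt(window_cv(s0_hat), 0.1)
})

test_that("permutation_null enumerates exhaustively and is seed-stable", {
  set.seed(23)
  x <- matrix(stats::rnorm(8 * 6), 8, 6)
  is1 <- rep(c(TRUE, FALSE), each = 3)
  null <- permutation_null(x, is1, s0 = 0.1)
  expect_true(null$exhaustive)
  expect_equal(null$n_perm, 20L)                       # C(6,3)
  expect_equal(dim(null$d_perm), c(8L, 20L))
  # columns sorted, expected order statistics are row means
  expect_true(all(apply(null$d_perm, 2, function(v) !is.unsorted(v))))
  expect_equal(null$d_expected, rowMeans(null$d_perm))

  # random-draw path is deterministic under the config seed
  x2 <- matrix(stats::rnorm(10 * 16), 10, 16)
  is2 <- rep(c(TRUE, FALSE), each = 8)
  cfg <- sam_config(n_permutations = 150, seed = 5)
  a <- permutation_null(x2, is2, 0.1, cfg)
  b <- permutation_null(x2, is2, 0.1, cfg)
  expect_false(a$exhaustive)
  expect_identical(a, b)
})

test_that("null d order statistics track the permutation expectation", {
  set.seed(24)
  x <- matrix(stats::rnorm(500 * 12), 500, 12)
  is1 <- rep(c(TRUE, FALSE), each = 6)
  rd <- relative_difference(x, is1, s0 = 0.05)
  null <- permutation_null(x, is1, 0.05)
  # extreme order statistics of one realization fluctuate freely; the
  # agreement band applies to the central 90% of ranks
  keep <- ceiling(0.05 * length(rd$d)):floor(0.95 * length(rd$d))
  gap <- max(abs(sort(rd$d)[keep] - null$d_expected[keep]))
  expect_lt(gap, 0.05 * diff(range(rd$d)))
})

test_that("call_at_delta boundaries behave as specified", {
  set.seed(25)
  x <- matrix(stats::rnorm(30 * 6), 30, 6)
  is1 <- rep(c(TRUE, FALSE), each = 3)
  rd <- relative_difference(x, is1, 0.1)
  null <- permutation_null(x, is1, 0.1)
  huge <- call_at_delta(rd$d, null, 1e6)
  expect_equal(huge$n_called, 0L)
  expect_equal(huge$estimated_fdr, 0)
  zero <- call_at_delta(rd$d, null, 0)
  expect_true(all(zero$called))
})

test_that("the d/delta/FDR machinery matches brute-force enumeration exactly", {
  set.seed(26)
  for (rep in 1:3) {
    G <- sample(6:10, 1)
    x <- matrix(stats::rnorm(G * 6, sd = 2), G, 6)
    x[1:2, 1:3] <- x[1:2, 1:3] + 4          # two shifted genes
    is1 <- rep(c(TRUE, FALSE), each = 3)
    s0 <- 0.2
    deltas <- c(0, 0.3, 0.8, 1.5, 3)
    want <- oracle_sam(x, is1, s0, deltas)
    rd <- relative_difference(x, is1, s0)
    expect_equal(rd$d, want$d)
    null <- permutation_null(x, is1, s0)
    expect_equal(null$d_perm, unname(want$perm))
    expect_equal(null$d_expected, want$dbar)
    for (k in seq_along(deltas)) {
      got <- call_at_delta(rd$d, null, deltas[k])
      expect_equal(got$called, want$calls[[k]]$called)
      expect_equal(got$estimated_fdr, want$calls[[k]]$fdr)
    }
  }
})

test_that("choose_delta picks the smallest qualifying delta on the grid", {
  set.seed(27)
  G <- 50
  x <- matrix(stats::rnorm(G * 8), G, 8)
  x[1:5, 1:4] <- x[1:5, 1:4] + 5
  is1 <- rep(c(TRUE, FALSE), each = 4)
  rd <- relative_difference(x, is1, 0.2)
  null <- permutation_null(x, is1, 0.2)
  sel <- choose_delta(rd$d, null, sam_config(n_delta = 40))
  # n_called non-increasing along the grid
  expect_true(all(diff(sel$grid$n_called) <= 0))
  # the selection is the first grid delta under the FDR threshold
  first <- which(sel$grid$estimated_fdr < 0.05)[1]
  expect_equal(sel$delta, sel$grid$delta[first])
  # grid consistency with call_at_delta at the chosen point
  at <- call_at_delta(rd$d, null, sel$delta)
  expect_equal(sel$n_called, at$n_called)
  expect_equal(sel$estimated_fdr, at$estimated_fdr)
  # q-values are minimal FDRs over calling deltas, within [0, 1]
  expect_true(all(sel$q_values >= 0 & sel$q_values <= 1))
  expect_true(all(sel$q_values[sel$called] <= sel$estimated_fdr))
})

test_that("fold_change follows the linear mean ratio", {
  x <- rbind(c(8, 8, 2, 2), c(3, 3, 3, 3))
  fc <- fold_change(x, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fc$fc, c(4, 1))
  expect_equal(fc$log2_fc, c(2, 0))
  expect_error(fold_change(rbind(c(-1, 1, 1, 1)), c(TRUE, TRUE, FALSE, FALSE)),
               "positive")
  # a planted log2 effect of 2 is recovered within sampling error
  set.seed(28)
  lin <- 2^rbind(c(stats::rnorm(20, 10, 1), stats::rnorm(20, 8, 1)))
  est <- fold_change(lin, rep(c(TRUE, FALSE), each = 20))
  expect_lt(abs(est$log2_fc - 2), 0.3)
})

test_that("run_sam flags a saturated toy consistently and swaps cleanly", {
  toy <- make_toy_matrices(seed = 7)
  comp <- presence_filter(build_compendium(toy$matrices))
  cfg <- sam_config(seed = 1)
  suppressWarnings(fit <- run_sam(comp, toy$matrices, c("RA", "NT"), cfg))
  res <- fit$results[order(fit$results$gene), ]
  delta <- toy$delta[match(res$gene, toy$genes)]
  expect_true(all(res$status != "not_significant"))
  expect_true(all(res$status[delta > 0] == "up_regulated"))
  expect_true(all(res$status[delta < 0] == "down_regulated"))
  # status invariant: significant iff q < 0.05 and |log2 fc| > 1
  expect_equal(res$status != "not_significant",
               res$q_value < cfg$fdr_threshold &
                 abs(res$log2_fc) > cfg$lfc_threshold)

  # reversed contrast: d negated, fold change inverted, statuses exchanged
  suppressWarnings(rev <- run_sam(comp, toy$matrices, c("NT", "RA"), cfg))
  rres <- rev$results[order(rev$results$gene), ]
  expect_equal(rres$d_score, -res$d_score, tolerance = 1e-12)
  expect_equal(rres$fold_change, 1 / res$fold_change, tolerance = 1e-12)
  expect_equal(rres$status == "up_regulated", res$status == "down_regulated")
})

test_that("genes with missing values are dropped from the contrast", {
  toy <- make_toy_matrices(seed = 8, G = 80)
  # remove some genes from the second dataset's panel
  m2 <- toy$matrices[[2]]
  keep <- 11:80
  m2 <- expression_matrix(m2$accession, m2$values[keep, ], m2$genes[keep],
                          m2$sample_ids, m2$groups)
  mats <- list(toy$matrices[[1]], m2)
  comp <- build_compendium(mats)        # no presence filter: keep partial genes
  suppressWarnings(
    expect_message(fit <- run_sam(comp, mats, c("RA", "NT"), sam_config(seed = 1)),
                   "dropped"))
  expect_equal(fit$run$n_genes_dropped, 10L)
  expect_equal(nrow(fit$results), 70L)
})

test_that("null two-group data produce almost no calls", {
  null_cfg <- function(seed) {
    sim_config(seed = seed, n_genes = 2000, n_datasets = 2, designs = "RA_NT",
               samples_per_group = c(RA = 5L, OA = 0L, NT = 5L),
               panel_coverage = c(1, 1), n_spiked_ra = 0, n_spiked_oa = 0)
  }
  oc <- suppressWarnings(
    sam_operating_characteristics(n_reps = 10, base_seed = 200,
                                  config_fn = null_cfg))
  # under the null every call is false; the mean FDP over replicates must
  # stay within the nominal rate plus Monte-Carlo error
  mc_se <- stats::sd(oc$fdp) / sqrt(nrow(oc))
  expect_lte(mean(oc$fdp), 0.05 + 2 * mc_se)
  expect_gte(mean(oc$n_called == 0), 0.9)
})
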