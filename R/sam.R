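#' SAM analysis configuration
#'
#' @param n_permutations Number of random label permutations when exhaustive
#'   enumeration is infeasible (must be at least 100).
#' @param seed Seed for the permutation RNG.
#' @param fdr_threshold FDR cutoff for the differential-expression call
#'   (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1, i.e.
#'   minimal two-fold change).
#' @param s0_method Fudge-factor estimator: \code{"tusher_cv"} (coefficient
#'   of variation minimization over a quantile grid) or
#'   \code{"percentile5"} (5th percentile of the gene scatters).
#' @param exhaustive_limit Enumerate all distinct label assignments when
#'   their number does not exceed this limit (default 10000).
#' @param n_delta Number of grid points for the delta threshold search.
#' @return A list of class \code{"sam_config"}.
#' @export
sam_config <- function(n_permutations = 1000L, seed = 1L, fdr_threshold = 0.05,
                       lfc_threshold = 1.0, s0_method = c("tusher_cv", "percentile5"),
                       exhaustive_limit = 10000L, n_delta = 100L) {
  s0_method <- match.arg(s0_method)
  stopifnot(n_permutations >= 100L, fdr_threshold > 0, lfc_threshold > 0,
            exhaustive_limit >= 2L, n_delta >= 2L)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold, s0_method = s0_method,
                 exhaustive_limit = as.integer(exhaustive_limit),
                 n_delta = as.integer(n_delta)),
            class = "sam_config")
}

# d-scores and gene scatters for an assignment matrix: `assign` is an
# N x P logical/0-1 matrix, one column per label assignment (TRUE = group 1).
# Returns list(d = G x P, s = G x P); fully vectorized in P.
d_scores_for_assignments <- function(x, assign, s0) {
  n1 <- colSums(assign)[1]
  N <- nrow(assign); n2 <- N - n1
  S1 <- x %*% assign
  Q1 <- (x * x) %*% assign
  tot <- rowSums(x); qtot <- rowSums(x * x)
  M1 <- S1 / n1
  M2 <- (tot - S1) / n2
  ss1 <- pmax(Q1 - n1 * M1 * M1, 0)
  ss2 <- pmax((qtot - Q1) - n2 * M2 * M2, 0)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (N - 2))
  list(d = (M1 - M2) / (s + s0), s = s, r = M1 - M2)
}

#' SAM relative-difference score
#'
#' The moderated two-class statistic
#' \eqn{d_i = (\bar{x}_{1,i} - \bar{x}_{2,i}) / (s_i + s_0)}, where the gene
#' scatter \eqn{s_i} is the pooled standard deviation scaled by
#' \eqn{\sqrt{1/n_1 + 1/n_2}} and \eqn{s_0} is the fudge factor
#' stabilizing low-variance genes. Swapping the class labels negates
#' \eqn{d_i} and leaves \eqn{s_i} unchanged.
#'
#' @param x Numeric matrix, genes x samples, no missing values.
#' @param is_group1 Logical vector over samples; \code{TRUE} marks the
#'   first-named (disease) class. Each class needs at least 2 samples.
#' @param s0 Non-negative fudge factor.
#' @return Data frame with per-gene \code{d} and \code{s}.
#' @export
relative_difference <- function(x, is_group1, s0 = 0) {
  stopifnot(is.matrix(x), !anyNA(x), is.logical(is_group1),
            length(is_group1) == ncol(x), s0 >= 0)
  n1 <- sum(is_group1); n2 <- sum(!is_group1)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  res <- d_scores_for_assignments(x, matrix(as.numeric(is_group1)), s0)
  if (s0 == 0 && any(res$s == 0)) {
    stop("gene with zero scatter in both classes and s0 = 0: d undefined")
  }
  data.frame(d = res$d[, 1], s = res$s[, 1], row.names = rownames(x))
}

#' Estimate the SAM fudge factor s0
#'
#' \code{tusher_cv}: evaluates candidate values on the grid of scatter
#' quantiles at probabilities 0, 0.05, ..., 1 and picks the candidate
#' minimizing the coefficient of variation of the median absolute deviation
#' of the d-scores computed within percentile windows of the scatter —
#' i.e. the value making the spread of d independent of gene variance.
#' \code{percentile5}: the 5th percentile of the scatters (linear
#' interpolation). \code{tusher_cv} needs at least 100 genes; with fewer it
#' falls back to \code{percentile5} with a warning.
#'
#' @param r Per-gene class mean differences (numerator of d).
#' @param s Per-gene scatters, non-negative.
#' @param method \code{"tusher_cv"} or \code{"percentile5"}.
#' @return A single non-negative value; a small positive floor (1e-8) with
#'   a warning when all scatters are zero.
#' @export
estimate_s0 <- function(r, s, method = c("tusher_cv", "percentile5")) {
  method <- match.arg(method)
  stopifnot(length(r) == length(s), all(s >= 0))
  if (all(s == 0)) {
    warning("all gene scatters are zero; using floor s0 = 1e-8")
    return(1e-8)
  }
  if (method == "tusher_cv" && length(s) < 100L) {
    warning("fewer than 100 genes: falling back to percentile5 for s0")
    method <- "percentile5"
  }
  if (method == "percentile5") {
    return(unname(stats::quantile(s, 0.05)))
  }
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas)
  n_windows <- min(100L, max(2L, floor(length(s) / 25)))
  win <- cut(rank(s, ties.method = "first"),
             breaks = n_windows, labels = FALSE)
  cv <- vapply(cand, function(s0a) {
    d <- r / (s + s0a)
    v <- vapply(split(d, win), function(dd) stats::mad(dd, constant = 1) / 0.64,
                numeric(1))
    v <- v[is.finite(v)]
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  unname(cand[which.min(cv)])
}

#' Permutation null distribution of SAM d-scores
#'
#' Recomputes the d-score under permuted class labels, keeping the fudge
#' factor fixed. All \eqn{\binom{n}{n_1}} distinct label assignments are
#' enumerated when their number does not exceed
#' \code{config$exhaustive_limit}; otherwise \code{config$n_permutations}
#' seeded uniform draws are used. Each permutation's d-vector is sorted and
#' the expected order statistics \eqn{\bar{d}_E(i)} are the per-rank means
#' over permutations.
#'
#' @param x Numeric matrix, genes x samples, no missing values.
#' @param is_group1 Logical class indicator over samples.
#' @param s0 Fudge factor from [estimate_s0()].
#' @param config A [sam_config()].
#' @return List with \code{d_perm} (genes x permutations matrix, each
#'   column sorted ascending), \code{d_expected} (expected order
#'   statistics), \code{exhaustive}, \code{n_perm}.
#' @export
permutation_null <- function(x, is_group1, s0, config = sam_config()) {
  stopifnot(is.matrix(x), !anyNA(x), length(is_group1) == ncol(x))
  N <- ncol(x); n1 <- sum(is_group1)
  if (n1 < 2L || N - n1 < 2L) stop("each class needs at least 2 samples")
  n_distinct <- choose(N, n1)
  if (n_distinct < 2) stop("fewer than 2 distinct label assignments")
  if (n_distinct <= config$exhaustive_limit) {
    idx <- utils::combn(N, n1)
    exhaustive <- TRUE
  } else {
    set.seed(config$seed)
    idx <- replicate(config$n_permutations, sample.int(N, n1))
    exhaustive <- FALSE
  }
  P <- ncol(idx)
  assign <- matrix(0, N, P)
  assign[cbind(as.vector(idx), rep(seq_len(P), each = n1))] <- 1
  d <- d_scores_for_assignments(x, assign, s0)$d
  d_sorted <- apply(d, 2L, sort)
  list(d_perm = d_sorted, d_expected = rowMeans(d_sorted),
       exhaustive = exhaustive, n_perm = P)
}

# Cut thresholds for one delta: t_up is the smallest observed d (in sorted
# order) whose displacement above the expected order statistic reaches
# delta; t_lo is the symmetric lower cut.
delta_cuts <- function(d_sorted, d_expected, delta) {
  up <- d_sorted - d_expected >= delta
  lo <- d_expected - d_sorted >= delta
  list(t_up = if (any(up)) min(d_sorted[up]) else Inf,
       t_lo = if (any(lo)) max(d_sorted[lo]) else -Inf)
}

# Count of elements of a sorted vector >= t / <= t (ties included).
count_ge <- function(sorted_vec, t) {
  length(sorted_vec) - findInterval(t, sorted_vec, left.open = TRUE)
}
count_le <- function(sorted_vec, t) findInterval(t, sorted_vec)

#' Call genes at a given delta and estimate the FDR
#'
#' A gene is called when its d-score lies beyond the cut thresholds
#' implied by \code{delta}: the upper cut is the smallest observed d whose
#' displacement over the expected order statistic reaches \code{delta}
#' (lower cut symmetric). The estimated FDR is the average, over
#' permutations, of the number of permuted d-scores beyond the cuts,
#' divided by the number of called genes (0 by convention when nothing is
#' called), capped at 1.
#'
#' @param d Observed per-gene d-scores (original gene order).
#' @param null A [permutation_null()] result.
#' @param delta Non-negative displacement threshold.
#' @return List with \code{called} (logical, original gene order),
#'   \code{n_called}, \code{estimated_fdr}, \code{t_up}, \code{t_lo}.
#' @export
call_at_delta <- function(d, null, delta) {
  stopifnot(delta >= 0)
  d_sorted <- sort(d)
  cuts <- delta_cuts(d_sorted, null$d_expected, delta)
  called <- d >= cuts$t_up | d <= cuts$t_lo
  n_called <- sum(called)
  if (n_called == 0L) {
    fdr <- 0
  } else {
    cnt <- apply(null$d_perm, 2L, function(col) {
      count_ge(col, cuts$t_up) + count_le(col, cuts$t_lo)
    })
    fdr <- min(mean(cnt) / n_called, 1)
  }
  list(called = called, n_called = n_called, estimated_fdr = fdr,
       t_up = cuts$t_up, t_lo = cuts$t_lo)
}

#' Pick the delta threshold and derive per-gene q-values
#'
#' Scans a grid of \code{config$n_delta} equally spaced delta values
#' spanning [0, max displacement] and selects the smallest delta whose
#' estimated FDR falls below \code{config$fdr_threshold} — the balance
#' point between the number of significant calls and a low FDR. Each
#' gene's q-value is the smallest estimated FDR over all grid deltas at
#' which the gene is called.
#'
#' @param d Observed per-gene d-scores.
#' @param null A [permutation_null()] result.
#' @param config A [sam_config()].
#' @return List with \code{delta}, \code{n_called}, \code{estimated_fdr},
#'   \code{called} (at the chosen delta), \code{q_values}, and the full
#'   \code{grid} data frame (delta, n_called, estimated_fdr). When no grid
#'   delta achieves the threshold, a warning is issued and nothing is
#'   called.
#' @export
choose_delta <- function(d, null, config = sam_config()) {
  G <- length(d)
  d_sorted <- sort(d)
  disp <- max(abs(d_sorted - null$d_expected))
  deltas <- seq(0, disp, length.out = config$n_delta)
  t_up <- t_lo <- numeric(length(deltas))
  for (k in seq_along(deltas)) {
    cuts <- delta_cuts(d_sorted, null$d_expected, deltas[k])
    t_up[k] <- cuts$t_up; t_lo[k] <- cuts$t_lo
  }
  # permutation exceedance counts for every delta, one pass per column
  cnt <- matrix(0L, length(deltas), ncol(null$d_perm))
  for (j in seq_len(ncol(null$d_perm))) {
    col <- null$d_perm[, j]
    cnt[, j] <- (G - findInterval(t_up, col, left.open = TRUE)) +
      findInterval(t_lo, col)
  }
  mean_cnt <- rowMeans(cnt)
  n_called <- (G - findInterval(t_up, d_sorted, left.open = TRUE)) +
    findInterval(t_lo, d_sorted)
  fdr <- ifelse(n_called == 0L, 0, pmin(mean_cnt / pmax(n_called, 1L), 1))

  q <- rep(1, G)
  for (k in seq_along(deltas)) {
    called_k <- d >= t_up[k] | d <= t_lo[k]
    q[called_k] <- pmin(q[called_k], fdr[k])
  }
  ok <- fdr < config$fdr_threshold
  if (!any(ok)) {
    warning("no delta on the grid achieves FDR < ", config$fdr_threshold)
    sel <- NA_integer_
  } else {
    sel <- which(ok)[1]
  }
  list(delta = if (is.na(sel)) NA_real_ else deltas[sel],
       n_called = if (is.na(sel)) 0L else n_called[sel],
       estimated_fdr = if (is.na(sel)) NA_real_ else fdr[sel],
       called = if (is.na(sel)) rep(FALSE, G) else (d >= t_up[sel] | d <= t_lo[sel]),
       q_values = q,
       grid = data.frame(delta = deltas, n_called = n_called,
                         estimated_fdr = fdr))
}

#' Linear-scale fold change between two classes
#'
#' \code{fc = mean(group 1) / mean(group 2)} per gene on the linear
#' intensity scale, with \code{log2_fc = log2(fc)}.
#'
#' @param x Numeric matrix of strictly positive linear intensities.
#' @param is_group1 Logical class indicator over columns (TRUE = disease).
#' @return Data frame with per-gene \code{fc} and \code{log2_fc}.
#' @export
fold_change <- function(x, is_group1) {
  stopifnot(is.matrix(x), all(is.finite(x)), length(is_group1) == ncol(x))
  if (any(x <= 0)) stop("fold change requires strictly positive intensities")
  m1 <- rowMeans(x[, is_group1, drop = FALSE])
  m2 <- rowMeans(x[, !is_group1, drop = FALSE])
  data.frame(fc = m1 / m2, log2_fc = log2(m1 / m2), row.names = rownames(x))
}

#' Run the full SAM differential-expression analysis on a compendium
#'
#' Computes d-scores on the z-scored compendium values for the two contrast
#' groups, estimates the fudge factor, builds the permutation null, picks
#' the delta threshold at the configured FDR, and attaches linear fold
#' changes computed on per-dataset median-scaled raw intensities pooled
#' across datasets. A gene's status is \code{up_regulated} when
#' \code{q < fdr_threshold} and \code{log2_fc > lfc_threshold} (higher in
#' the first-named, disease, group), \code{down_regulated} for the
#' symmetric case, otherwise \code{not_significant}. Genes with any
#' missing value among the contrasted samples are excluded (their count is
#' reported via \code{message()}).
#'
#' @param compendium A (typically presence-filtered) [build_compendium()]
#'   result.
#' @param matrices The raw [expression_matrix()] list the compendium was
#'   built from (for fold changes).
#' @param contrast Character vector of two groups, disease first, e.g.
#'   \code{c("RA", "NT")}.
#' @param config A [sam_config()].
#' @return List with \code{run} (class \code{"sam_run"}: \code{s0},
#'   \code{delta}, \code{n_called}, \code{estimated_fdr},
#'   \code{permutation_count}, \code{exhaustive}, \code{contrast},
#'   \code{n_genes_used}, \code{n_genes_dropped}, \code{seed}) and
#'   \code{results}, a data frame with one row per analyzed gene —
#'   \code{gene}, \code{d_score}, \code{s}, \code{fold_change},
#'   \code{log2_fc}, \code{q_value}, \code{status} — sorted by decreasing
#'   absolute log2 fold change.
#' @export
run_sam <- function(compendium, matrices, contrast = c("RA", "NT"),
                    config = sam_config()) {
  stopifnot(inherits(compendium, "compendium"), length(contrast) == 2L,
            contrast[1] != contrast[2], all(contrast %in% MANIFEST_GROUPS))
  in_contrast <- compendium$samples$group %in% contrast
  if (sum(compendium$samples$group == contrast[1] ) < 2L ||
      sum(compendium$samples$group == contrast[2]) < 2L) {
    stop("contrast ", contrast[1], " vs ", contrast[2],
         ": each group needs at least 2 samples")
  }
  sub <- compendium$z[, in_contrast, drop = FALSE]
  groups <- compendium$samples$group[in_contrast]
  complete <- rowSums(is.na(sub)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " gene(s) dropped from contrast ", contrast[1], " vs ",
            contrast[2], " due to missing values")
  }
  if (sum(complete) < 2L) stop("too few complete genes for the contrast")
  z <- sub[complete, , drop = FALSE]
  genes <- compendium$genes[complete]
  is1 <- groups == contrast[1]

  base <- d_scores_for_assignments(z, matrix(as.numeric(is1)), 0)
  s0 <- estimate_s0(base$r[, 1], base$s[, 1], config$s0_method)
  rd <- relative_difference(z, is1, s0 = s0)
  null <- permutation_null(z, is1, s0, config)
  sel <- choose_delta(rd$d, null, config)

  fcm <- pooled_scaled_matrix(matrices, genes,
                              colnames(compendium$z)[in_contrast],
                              compendium$samples$dataset[in_contrast])
  fc <- fold_change(fcm, is1)

  status <- rep("not_significant", length(genes))
  sig <- sel$q_values < config$fdr_threshold & abs(fc$log2_fc) > config$lfc_threshold
  status[sig & fc$log2_fc > 0] <- "up_regulated"
  status[sig & fc$log2_fc < 0] <- "down_regulated"

  results <- data.frame(gene = genes, d_score = rd$d, s = rd$s,
                        fold_change = fc$fc, log2_fc = fc$log2_fc,
                        q_value = sel$q_values, status = status,
                        stringsAsFactors = FALSE)
  results <- results[order(-abs(results$log2_fc)), ]
  rownames(results) <- NULL
  run <- structure(list(s0 = s0, delta = sel$delta, n_called = sel$n_called,
                        estimated_fdr = sel$estimated_fdr,
                        permutation_count = null$n_perm,
                        exhaustive = null$exhaustive, contrast = contrast,
                        n_genes_used = length(genes),
                        n_genes_dropped = n_dropped, seed = config$seed),
                   class = "sam_run")
  list(run = run, results = results)
}

#' @export
print.sam_run <- function(x, ...) {
  cat("<sam_run> ", x$contrast[1], " vs ", x$contrast[2], ": ",
      x$n_genes_used, " genes, s0=", signif(x$s0, 4), ", delta=",
      signif(x$delta, 4), ", called=", x$n_called, " at FDR~",
      signif(x$estimated_fdr, 3), " (", x$permutation_count,
      if (x$exhaustive) " exhaustive" else " random", " permutations)\n",
      sep = "")
  invisible(x)
}

# Pooled per-dataset median-scaled linear intensities for the given genes
# and samples. Genes must be measured in every contributing dataset (true
# by construction after complete-case filtering in run_sam).
pooled_scaled_matrix <- function(matrices, genes, sample_ids, sample_datasets) {
  out <- matrix(NA_real_, length(genes), length(sample_ids),
                dimnames = list(genes, sample_ids))
  for (m in matrices) {
    cols <- which(sample_datasets == m$accession)
    if (!length(cols)) next
    ids <- sample_ids[cols]
    sid <- match(ids, m$sample_ids)
    if (anyNA(sid)) sid <- match(sub(paste0("^", m$accession, "\\."), "", ids),
                                 m$sample_ids)
    gid <- match(genes, m$genes)
    if (anyNA(sid)) stop("sample ids not found in dataset ", m$accession)
    vals <- m$values / stats::median(m$values)
    out[, cols] <- vals[gid, sid]
  }
  if (anyNA(out)) stop("fold-change matrix has unmatched entries")
  out
}
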