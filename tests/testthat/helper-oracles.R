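# Independent brute-force oracles, written as plain loops over first
# principles so they share no code path with the package implementation.

oracle_zscore <- function(x) {
  m <- sum(x) / length(x)
  ss <- sum((x - m)^2) / (length(x) - 1)
  (x - m) / sqrt(ss)
}

# Mann-Whitney U by explicit pair counting; exact two-sided p by
# enumerating every way to assign the pooled values to the two groups.
oracle_mw <- function(x, y) {
  ufun <- function(xs, ys) {
    u <- 0
    for (xi in xs) for (yj in ys) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  u_obs <- ufun(x, y)
  mid <- n * (N - n) / 2
  cs <- utils::combn(N, n)
  us <- apply(cs, 2, function(ix) ufun(pooled[ix], pooled[-ix]))
  list(U = u_obs, p = mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9))
}

# Upper-tail hypergeometric probability from factorial point masses.
oracle_hyper_factorial <- function(k, K, n, N) {
  pm <- function(j) {
    exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
  }
  sum(vapply(k:min(K, n), pm, numeric(1)))
}

# Upper-tail hypergeometric probability by enumerating every draw of n
# genes from a background of N with K marked (N small).
oracle_hyper_enum <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# Direct step-up BH formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Shared-gene Euclidean distance rescaled to the full gene space, by loop.
oracle_pair_distance <- function(za, zb, G = length(za)) {
  tot <- 0; g <- 0
  for (i in seq_along(za)) {
    if (!is.na(za[i]) && !is.na(zb[i])) {
      tot <- tot + (za[i] - zb[i])^2
      g <- g + 1
    }
  }
  sqrt(tot * G / g)
}

# Full SAM machinery on a small instance: d-scores by explicit pooled-SD
# formula, exhaustive permutation null, cut thresholds and mean-count
# FDR by scanning loops. `deltas` is a vector of thresholds to evaluate.
oracle_sam <- function(x, is1, s0, deltas) {
  G <- nrow(x); N <- ncol(x); n1 <- sum(is1)
  dfun <- function(memb) {
    d <- numeric(G); s <- numeric(G)
    for (g in seq_len(G)) {
      a <- x[g, memb]; b <- x[g, !memb]
      pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
        (length(a) + length(b) - 2)
      s[g] <- sqrt(pooled_var * (1 / length(a) + 1 / length(b)))
      d[g] <- (mean(a) - mean(b)) / (s[g] + s0)
    }
    list(d = d, s = s)
  }
  obs <- dfun(is1)
  combs <- utils::combn(N, n1)
  perm <- sapply(seq_len(ncol(combs)), function(j) {
    sort(dfun(seq_len(N) %in% combs[, j])$d)
  })
  dbar <- rowMeans(perm)
  ds <- sort(obs$d)
  calls <- lapply(deltas, function(delta) {
    up <- ds[ds - dbar >= delta]
    lo <- ds[dbar - ds >= delta]
    t_up <- if (length(up)) min(up) else Inf
    t_lo <- if (length(lo)) max(lo) else -Inf
    called <- obs$d >= t_up | obs$d <= t_lo
    cnt <- apply(perm, 2, function(col) sum(col >= t_up) + sum(col <= t_lo))
    fdr <- if (sum(called) == 0) 0 else min(mean(cnt) / sum(called), 1)
    list(called = called, fdr = fdr, t_up = t_up, t_lo = t_lo)
  })
  list(d = obs$d, s = obs$s, dbar = dbar, perm = perm, calls = calls)
}

# Small two-dataset spiked fixture used across SAM tests.
make_toy_matrices <- function(seed = 7, G = 60, n = 5, effect = 3,
                              noise_sd = 0.05, frac_spiked = 1) {
  set.seed(seed)
  mu <- stats::rnorm(G, 8, 2)
  delta <- numeric(G)
  spiked <- sample(G, round(frac_spiked * G))
  delta[spiked] <- sample(c(-effect, effect), length(spiked), replace = TRUE)
  mk <- function(acc) {
    y <- cbind(matrix(mu + delta, G, n), matrix(mu, G, n)) +
      matrix(stats::rnorm(G * 2 * n, 0, noise_sd), G)
    expression_matrix(acc, 2^y, sprintf("G%03d", seq_len(G)),
                      sprintf("%s_s%02d", acc, seq_len(2 * n)),
                      rep(c("RA", "NT"), each = n))
  }
  list(matrices = list(mk("TOYA"), mk("TOYB")), delta = delta,
       genes = sprintf("G%03d", seq_len(G)))
}
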