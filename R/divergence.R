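PAIR_CLASSES <- c("RA_NT", "OA_NT", "RA_OA", "within_RA", "within_OA", "within_NT")

pair_class_of <- function(a, b) {
  if (a == b) return(paste0("within_", a))
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key, "NTRA" = "RA_NT", "NTOA" = "OA_NT", "OARA" = "RA_OA",
         stop("unknown group pair: ", a, ", ", b))
}

#' Expression distance between two sample profiles
#'
#' Euclidean distance over the genes measured in both profiles, rescaled to
#' the full compendium gene space so that pairs with different panel overlap
#' are on a comparable scale:
#' \deqn{d(a, b) = \sqrt{ \sum_{g \in shared} (z_{a,g} - z_{b,g})^2 \cdot G / g_{shared} }}
#' where \eqn{G} is the total number of compendium genes and
#' \eqn{g_{shared}} the number of genes non-missing in both profiles.
#'
#' @param za,zb Numeric z-score profiles of equal length; \code{NA} marks a
#'   gene missing from that sample's platform.
#' @param n_genes Total gene-space size \eqn{G}; defaults to
#'   \code{length(za)}.
#' @return Non-negative scalar distance; 0 iff the profiles agree on every
#'   shared gene. Errors if no gene is shared.
#' @export
pair_distance <- function(za, zb, n_genes = length(za)) {
  stopifnot(length(za) == length(zb), n_genes >= length(za))
  shared <- !is.na(za) & !is.na(zb)
  g <- sum(shared)
  if (g == 0L) stop("undefined distance: no shared non-missing genes")
  sqrt(sum((za[shared] - zb[shared])^2) * n_genes / g)
}

#' All pairwise sample distances of a compendium
#'
#' Computes the full symmetric matrix of [pair_distance()] values between
#' all sample columns, using masked matrix algebra rather than per-pair
#' loops. Pairs with no shared genes yield \code{NA} with a warning.
#'
#' @param compendium A [build_compendium()] result (usually after
#'   [presence_filter()]).
#' @return Symmetric numeric matrix with zero diagonal, dimnamed by sample
#'   id.
#' @export
distance_matrix <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  Z <- compendium$z
  if (ncol(Z) < 2L) stop("need at least two samples")
  M <- !is.na(Z)
  Z0 <- ifelse(M, Z, 0)
  shared <- crossprod(M)                 # g_shared per sample pair
  A <- crossprod(Z0^2, M)                # sum over shared of za^2
  D2 <- (A + t(A) - 2 * crossprod(Z0)) * (nrow(Z) / shared)
  D2[shared == 0L] <- NA_real_
  if (anyNA(D2)) warning("sample pair(s) with no shared genes: distance set to NA")
  D <- sqrt(pmax(D2, 0))
  diag(D) <- 0
  dimnames(D) <- list(colnames(Z), colnames(Z))
  D
}

#' Summarize pairwise distances by group pair class
#'
#' Partitions the distance multiset into the six group-pair classes
#' (\code{RA_NT}, \code{OA_NT}, \code{RA_OA}, \code{within_RA},
#' \code{within_OA}, \code{within_NT}) and reports each class's pair count,
#' mean distance and standard error of the mean (SD over pairs divided by
#' the square root of the pair count; 0 when only one pair exists). Classes
#' with no pairs are omitted.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param labels Character vector of group labels, one per sample
#'   (column order of \code{dm}).
#' @return Data frame with columns \code{pair_class}, \code{n_pairs},
#'   \code{mean_distance}, \code{standard_error}.
#' @export
summarize_by_class <- function(dm, labels) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), length(labels) == ncol(dm))
  lists <- class_distance_lists(dm, labels)
  out <- lapply(names(lists), function(cl) {
    v <- lists[[cl]]
    data.frame(pair_class = cl, n_pairs = length(v),
               mean_distance = mean(v, na.rm = TRUE),
               standard_error = if (length(v) > 1L)
                 stats::sd(v, na.rm = TRUE) / sqrt(length(v)) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Raw per-class distance multisets (upper triangle only for within-class).
class_distance_lists <- function(dm, labels) {
  out <- list()
  for (cl in PAIR_CLASSES) out[[cl]] <- numeric(0)
  groups <- unique(labels)
  for (i in seq_along(groups)) {
    for (j in i:length(groups)) {
      a <- groups[i]; b <- groups[j]
      ia <- which(labels == a); ib <- which(labels == b)
      cl <- pair_class_of(a, b)
      v <- if (a == b) {
        if (length(ia) < 2L) numeric(0) else dm[t(utils::combn(ia, 2L))]
      } else {
        as.vector(dm[ia, ib])
      }
      out[[cl]] <- c(out[[cl]], v)
    }
  }
  out[vapply(out, length, integer(1)) > 0L]
}

#' Mann-Whitney U test with exact enumeration on small samples
#'
#' Computes \eqn{U = \sum_{i,j} [x_i > y_j] + 0.5 [x_i = y_j]} and a
#' two-sided p-value. When the number of distinct group assignments
#' \eqn{\binom{n+m}{n}} does not exceed \code{exhaustive_limit}, the exact
#' permutation distribution of U is enumerated (ties handled by midranks);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exhaustive_limit Maximum number of enumerable assignments for the
#'   exact path (default 10000).
#' @return List with \code{U}, \code{p_value}, and \code{exact} (logical).
#' @export
mann_whitney <- function(x, y, exhaustive_limit = 10000) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(U = U, p_value = 1, exact = TRUE))
  }
  dev <- abs(U - n * m / 2)
  if (choose(N, n) <= exhaustive_limit) {
    idx <- utils::combn(N, n)
    ru <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(ru - n * m / 2) >= dev - 1e-9)
    list(U = U, p_value = p, exact = TRUE)
  } else {
    tie <- table(pooled)
    v <- n * m / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (v <= 0) return(list(U = U, p_value = 1, exact = FALSE))
    z <- max(dev - 0.5, 0) / sqrt(v)
    list(U = U, p_value = min(1, 2 * stats::pnorm(-z)), exact = FALSE)
  }
}

#' Compare divergence distributions between group-pair classes
#'
#' Applies the two-sided [mann_whitney()] test to the three distance-class
#' contrasts of interest — disease-vs-control divergence against
#' disease-vs-disease divergence (\code{RA_NT} vs \code{RA_OA} and
#' \code{OA_NT} vs \code{RA_OA}) and the two disease-vs-control classes
#' against each other — and reports the direction of each difference.
#' Distance pairs share samples and are therefore not independent; the test
#' is applied to the pair multisets regardless, and p-values should be read
#' with that caveat. No multiple-testing correction is applied.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param labels Group label per sample.
#' @param exhaustive_limit Passed to [mann_whitney()].
#' @return Data frame with columns \code{class_a}, \code{class_b}, \code{U},
#'   \code{p_value}, \code{direction} (\code{a_greater}, \code{b_greater} or
#'   \code{none}). Comparisons whose classes are absent are skipped with a
#'   warning.
#' @export
compare_divergences <- function(dm, labels, exhaustive_limit = 10000) {
  lists <- class_distance_lists(dm, labels)
  wanted <- list(c("RA_NT", "RA_OA"), c("OA_NT", "RA_OA"), c("RA_NT", "OA_NT"))
  rows <- list()
  for (w in wanted) {
    if (!all(w %in% names(lists))) {
      warning("skipping comparison ", w[1], " vs ", w[2], ": class missing")
      next
    }
    a <- lists[[w[1]]]; b <- lists[[w[2]]]
    mw <- mann_whitney(a, b, exhaustive_limit)
    direction <- if (mw$U > length(a) * length(b) / 2) "a_greater"
                 else if (mw$U < length(a) * length(b) / 2) "b_greater"
                 else "none"
    rows[[length(rows) + 1L]] <- data.frame(
      class_a = w[1], class_b = w[2], U = mw$U, p_value = mw$p_value,
      direction = direction, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
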