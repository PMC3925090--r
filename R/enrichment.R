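#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one term per line, tab-separated
#' \code{term_id<TAB>description<TAB>member1<TAB>member2...}. Member
#' symbols are uppercased.
#'
#' @param path Path to a GMT file.
#' @return List of gene sets; each element has \code{term_id},
#'   \code{term_name} and \code{members}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("GMT line with fewer than 3 fields")
    list(term_id = parts[1], term_name = parts[2],
         members = unique(toupper(parts[-(1:2)])))
  })
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets List of gene sets with \code{term_id}, \code{term_name},
#'   \code{members} (as from [read_gmt()] or [simulate_annotation()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    paste(c(gs$term_id, gs$term_name, gs$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided over-representation p-value
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge k)} of observing at
#' least \code{k} term members in a differential-expression list of size
#' \code{n} drawn from a background of \code{N} genes of which \code{K}
#' belong to the term — the one-sided Fisher exact test for enrichment.
#'
#' @param k Observed overlap.
#' @param K Term size within the background.
#' @param n DE-list size.
#' @param N Background size.
#' @return p-value in (0, 1]; exactly 1 when \code{k = 0}.
#' @export
overrepresentation_p <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1)
  if (K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment
#' \eqn{p^{adj}_{(i)} = \min_{j \ge i} \min(m p_{(j)} / j, 1)}, mapped back
#' to the input order. Never decreases a p-value and is idempotent.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests every gene set for over-representation of the DE list against the
#' background universe with the one-sided hypergeometric test, adjusts
#' across terms by Benjamini-Hochberg, and flags terms passing the FDR
#' cutoff. Set members outside the background are ignored; sets with no
#' background member are omitted.
#'
#' @param de_genes Character vector of DE gene symbols (must be a subset of
#'   \code{background}).
#' @param background Character vector of background ("all expressed") gene
#'   symbols.
#' @param gene_sets List of gene sets (see [read_gmt()]).
#' @param fdr FDR cutoff for the \code{enriched} flag (default 0.05).
#' @return Data frame sorted by ascending p-value with columns
#'   \code{term_id}, \code{term_name}, \code{n_overlap},
#'   \code{overlap_genes} (comma-separated), \code{p_value},
#'   \code{adjusted_p}, \code{enriched}.
#' @export
enrich <- function(de_genes, background, gene_sets, fdr = 0.05) {
  background <- unique(toupper(background))
  de_genes <- unique(toupper(de_genes))
  if (!length(background)) stop("empty background")
  missing <- setdiff(de_genes, background)
  if (length(missing)) {
    stop("DE genes not in background: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  N <- length(background); n <- length(de_genes)
  rows <- lapply(gene_sets, function(gs) {
    members <- intersect(gs$members, background)
    if (!length(members)) return(NULL)
    overlap <- intersect(members, de_genes)
    p <- overrepresentation_p(length(overlap), length(members), n, N)
    data.frame(term_id = gs$term_id, term_name = gs$term_name,
               n_overlap = length(overlap),
               overlap_genes = paste(sort(overlap), collapse = ","),
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(term_id = character(0)))
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$enriched <- out$adjusted_p < fdr
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
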