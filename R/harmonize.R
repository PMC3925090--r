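#' Construct a single-dataset expression matrix
#'
#' Container for one dataset's genes-by-samples intensity table on the
#' linear scale, with a group label per sample. Gene symbols are uppercased
#' and duplicated symbols (multiple probes mapping to one gene) are collapsed
#' to their per-sample arithmetic mean via [collapse_duplicates()].
#'
#' @param accession Dataset identifier string.
#' @param values Numeric matrix, genes in rows, samples in columns. All
#'   entries must be finite and strictly positive (linear intensities).
#' @param genes Character vector of gene symbols, one per row.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param groups Character vector of group labels per sample, from
#'   \code{RA}, \code{OA}, \code{NT}.
#' @return An object of class \code{"expression_matrix"}: a list with
#'   elements \code{accession}, \code{values} (dimnamed matrix),
#'   \code{genes}, \code{sample_ids}, \code{groups}.
#' @export
expression_matrix <- function(accession, values, genes, sample_ids, groups) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession),
            is.matrix(values), is.numeric(values),
            length(genes) == nrow(values), length(sample_ids) == ncol(values),
            length(groups) == ncol(values))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", accession)
  if (!all(groups %in% MANIFEST_GROUPS)) {
    stop("unknown group label(s): ",
         paste(setdiff(unique(groups), MANIFEST_GROUPS), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("non-finite intensity values in ", accession)
  if (any(values <= 0)) stop("intensities must be strictly positive in ", accession)
  coll <- collapse_duplicates(values, toupper(genes))
  dimnames(coll$values) <- list(coll$genes, sample_ids)
  structure(list(accession = accession, values = coll$values,
                 genes = coll$genes, sample_ids = sample_ids, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", x$accession, ": ", length(x$genes), " genes x ",
      length(x$sample_ids), " samples (",
      paste(sprintf("%s=%d", MANIFEST_GROUPS,
                    vapply(MANIFEST_GROUPS, function(g) sum(x$groups == g),
                           integer(1))), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Per-array z-score standardization
#'
#' Standardizes one array's intensity vector across its genes:
#' \eqn{z_i = (x_i - \bar{x}) / s}, with \eqn{\bar{x}} the mean intensity of
#' the array and \eqn{s} the sample standard deviation (denominator
#' \eqn{n - 1}) of all measured intensities on that array. The output is
#' invariant under positive affine transforms of the input
#' (\code{zscore_sample(a * x + b)} equals \code{zscore_sample(x)} for
#' \code{a > 0}), which is what makes arrays from different platforms
#' comparable after standardization.
#'
#' @param x Numeric vector of length at least 2 with finite values, not all
#'   equal.
#' @return Numeric vector of z-scores with mean 0 and sample standard
#'   deviation 1, in the input order.
#' @examples
#' zscore_sample(c(1, 2, 3))
#' @export
zscore_sample <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) stop("need a numeric vector of length >= 2")
  if (!all(is.finite(x))) stop("non-finite value in input")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate scale: all values equal")
  (x - mean(x)) / s
}

#' Collapse duplicated gene symbols by row means
#'
#' Rows sharing a symbol (after uppercasing) are averaged per sample; the
#' collapsed row takes the position of the symbol's first occurrence.
#'
#' @param values Numeric matrix, rows = probes/genes, columns = samples.
#' @param symbols Character vector of (possibly duplicated) symbols per row.
#' @return List with \code{values} (collapsed matrix) and \code{genes}
#'   (unique uppercased symbols in first-occurrence order).
#' @export
collapse_duplicates <- function(values, symbols) {
  stopifnot(is.matrix(values), length(symbols) == nrow(values))
  symbols <- toupper(symbols)
  if (!anyDuplicated(symbols)) {
    return(list(values = values, genes = symbols))
  }
  keep <- !duplicated(symbols)
  uniq <- symbols[keep]
  grp <- match(symbols, uniq)
  counts <- tabulate(grp, nbins = length(uniq))
  sums <- rowsum(values, group = grp, reorder = TRUE)
  list(values = sums / counts, genes = uniq)
}

#' Merge z-scored datasets into a gene compendium
#'
#' Each sample column is log2-transformed and z-scored across the genes its
#' own dataset measures ([zscore_sample()]); datasets are then merged on the
#' union of their uppercased gene symbols, with genes off a dataset's panel
#' recorded as missing (\code{NA}). No imputation is performed. The per-gene
#' presence fraction is the share of all compendium samples in which the
#' gene was measured.
#'
#' @param matrices List of at least two [expression_matrix()] objects.
#' @return An object of class \code{"compendium"}: list with \code{genes}
#'   (union symbol vector), \code{samples} (data frame: \code{sample_id},
#'   \code{dataset}, \code{group}), \code{z} (genes x samples matrix of
#'   z-scores with \code{NA} for unmeasured genes), and
#'   \code{presence_fraction} (named numeric vector).
#' @seealso [presence_filter()]
#' @export
build_compendium <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2L,
            all(vapply(matrices, inherits, logical(1), "expression_matrix")))
  accs <- vapply(matrices, `[[`, character(1), "accession")
  if (anyDuplicated(accs)) stop("duplicate dataset accessions among inputs")
  genes <- unique(unlist(lapply(matrices, `[[`, "genes")))
  samples <- do.call(rbind, lapply(matrices, function(m) {
    data.frame(sample_id = m$sample_ids, dataset = m$accession,
               group = m$groups, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(samples$sample_id)) {
    samples$sample_id <- paste(samples$dataset, samples$sample_id, sep = ".")
  }
  z <- matrix(NA_real_, length(genes), nrow(samples),
              dimnames = list(genes, samples$sample_id))
  col0 <- 0L
  for (m in matrices) {
    idx <- match(m$genes, genes)
    zd <- apply(log2(m$values), 2L, zscore_sample)
    z[idx, col0 + seq_along(m$sample_ids)] <- zd
    col0 <- col0 + length(m$sample_ids)
  }
  presence <- rowMeans(!is.na(z))
  names(presence) <- genes
  structure(list(genes = genes, samples = samples, z = z,
                 presence_fraction = presence),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat("<compendium> ", length(x$genes), " genes x ", nrow(x$samples),
      " samples from ", length(unique(x$samples$dataset)), " dataset(s); ",
      "median presence ", sprintf("%.2f", stats::median(x$presence_fraction)),
      "\n", sep = "")
  invisible(x)
}

#' Filter compendium genes by presence fraction
#'
#' Retains exactly the genes measured in strictly more than
#' \code{threshold} of all samples ("more than 60\%" at the default); a gene
#' present in exactly the threshold fraction is removed. Sample columns are
#' unchanged.
#'
#' @param compendium A [build_compendium()] result.
#' @param threshold Presence fraction cutoff in (0, 1); default 0.6.
#' @return A filtered \code{"compendium"}. If no gene survives, an empty
#'   compendium is returned with a warning.
#' @export
presence_filter <- function(compendium, threshold = 0.6) {
  stopifnot(inherits(compendium, "compendium"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  keep <- compendium$presence_fraction > threshold
  if (!any(keep)) warning("presence filter removed all genes")
  compendium$genes <- compendium$genes[keep]
  compendium$z <- compendium$z[keep, , drop = FALSE]
  compendium$presence_fraction <- compendium$presence_fraction[keep]
  compendium
}
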