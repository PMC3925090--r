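# Readers and writers for the package's tab-separated file dialects.

#' Write one dataset's expression table
#'
#' Expression TSV dialect: first column \code{gene}, remaining columns the
#' sample ids, linear-scale intensities.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene = em$genes, em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-sample metadata
#'
#' Metadata TSV dialect: \code{sample_id  dataset  group  tissue}.
#'
#' @param matrices List of [expression_matrix()] objects.
#' @param path Output path.
#' @param tissue Tissue label recorded for every sample (the synthetic
#'   generator has no tissue structure).
#' @return \code{path}, invisibly.
#' @export
write_metadata_tsv <- function(matrices, path, tissue = "synovial") {
  df <- do.call(rbind, lapply(matrices, function(m) {
    data.frame(sample_id = m$sample_ids, dataset = m$accession,
               group = m$groups, tissue = tissue, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read one dataset's expression table plus its sample metadata
#'
#' @param expr_path Expression TSV (see [write_expression_tsv()]).
#' @param meta_path Metadata TSV covering the dataset's samples.
#' @param accession Dataset accession; defaults to the accession recorded
#'   in the metadata for these samples.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(expr_path, meta_path, accession = NULL) {
  df <- utils::read.delim(expr_path, check.names = FALSE, quote = "")
  if (names(df)[1] != "gene") stop("expression TSV must start with a 'gene' column")
  meta <- utils::read.delim(meta_path, check.names = FALSE, quote = "",
                            colClasses = "character")
  ids <- names(df)[-1]
  sel <- match(ids, meta$sample_id)
  if (anyNA(sel)) stop("sample id(s) missing from metadata: ",
                       paste(utils::head(ids[is.na(sel)], 5), collapse = ", "))
  if (is.null(accession)) {
    accession <- unique(meta$dataset[sel])
    if (length(accession) != 1L) stop("samples span multiple datasets")
  }
  expression_matrix(accession, as.matrix(df[, -1, drop = FALSE]),
                    df$gene, ids, meta$group[sel])
}

#' Serialize a compendium to TSV plus a JSON sidecar
#'
#' The TSV holds the z-score matrix (first column \code{gene}, \code{NA}
#' for genes off a sample's platform); the JSON sidecar records sample
#' provenance and per-gene presence fractions.
#'
#' @param compendium A [build_compendium()] result.
#' @param path Output TSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_compendium <- function(compendium, path) {
  stopifnot(inherits(compendium, "compendium"))
  df <- data.frame(gene = compendium$genes, compendium$z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(samples = compendium$samples,
               presence_fraction = as.list(compendium$presence_fraction))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a compendium written by [write_compendium()]
#'
#' @param path Compendium TSV path (sidecar expected at
#'   \code{paste0(path, ".json")}).
#' @return A \code{"compendium"} object.
#' @export
read_compendium <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- df$gene
  structure(list(genes = df$gene,
                 samples = as.data.frame(side$samples,
                                         stringsAsFactors = FALSE),
                 z = z,
                 presence_fraction = unlist(side$presence_fraction)),
            class = "compendium")
}

#' Write SAM differential-expression results
#'
#' DE table dialect mirroring published summary tables:
#' \code{gene  d_score  fold_change  log2_fc  q_value  status}.
#'
#' @param sam A [run_sam()] result.
#' @param path Output TSV path; run provenance (s0, delta, permutations,
#'   seed) goes to \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_sam_results <- function(sam, path) {
  utils::write.table(sam$results[, c("gene", "d_score", "fold_change",
                                     "log2_fc", "q_value", "status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sam$run), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the synthetic ground-truth table
#'
#' @param truth Truth data frame from [simulate_compendium_inputs()].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
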