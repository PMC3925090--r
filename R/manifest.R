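#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for the study-design manifest.
MANIFEST_GROUPS  <- c("RA", "OA", "NT")
MANIFEST_TISSUES <- c("synovial", "peripheral_blood", "bone_marrow")
MANIFEST_HEADER  <- c("accession", "tissue", "platform", "group", "n")
DESIGN_CLASSES   <- c("has_NT", "RA_vs_OA_only", "RA_only")

#' Load a study-design manifest
#'
#' Reads a tab-separated manifest describing the microarray datasets entering
#' the meta-analysis: one row per (dataset, group) with the number of arrays
#' contributed by that group. Rows repeating a (dataset, group) combination
#' are aggregated by summing their counts, mirroring source tables that list
#' a control cohort in several batches. The group token \code{"NC"} (normal
#' control) is accepted as a synonym of \code{"NT"}.
#'
#' @param path Path to a tab-separated file with header
#'   \code{accession tissue platform group n}. Tissues must be one of
#'   \code{synovial}, \code{peripheral_blood}, \code{bone_marrow}; groups one
#'   of \code{RA}, \code{OA}, \code{NT} (or \code{NC}).
#' @return A data frame of class \code{"raometa_manifest"} with one row per
#'   dataset and columns \code{accession}, \code{tissue}, \code{platform},
#'   \code{n_RA}, \code{n_OA}, \code{n_NT}, in first-appearance order.
#' @seealso [summarize_manifest()], [write_manifest()]
#' @examples
#' path <- system.file("extdata", "table1_manifest.tsv", package = "raometa")
#' man <- load_manifest(path)
#' nrow(man)
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file does not exist: ", path)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", strip.white = FALSE)
  if (!identical(names(raw), MANIFEST_HEADER)) {
    stop("manifest header must be exactly: ", paste(MANIFEST_HEADER, collapse = "\t"))
  }
  if (nrow(raw) == 0L) stop("no records in manifest: ", path)

  raw$group[raw$group == "NC"] <- "NT"
  bad_grp <- which(!raw$group %in% MANIFEST_GROUPS)
  if (length(bad_grp)) {
    stop("unknown group token '", raw$group[bad_grp[1]], "' at manifest line ",
         bad_grp[1] + 1L)
  }
  bad_tis <- which(!raw$tissue %in% MANIFEST_TISSUES)
  if (length(bad_tis)) {
    stop("unknown tissue token '", raw$tissue[bad_tis[1]], "' at manifest line ",
         bad_tis[1] + 1L)
  }
  n <- suppressWarnings(as.integer(raw$n))
  bad_n <- which(is.na(n) | n < 0L | raw$n != as.character(n))
  if (length(bad_n)) {
    stop("sample count must be a non-negative integer at manifest line ",
         bad_n[1] + 1L)
  }

  acc <- unique(raw$accession)
  if (any(!nzchar(acc))) stop("empty accession in manifest")
  rows <- lapply(acc, function(a) {
    sub <- raw[raw$accession == a, , drop = FALSE]
    if (length(unique(sub$tissue)) > 1L || length(unique(sub$platform)) > 1L) {
      stop("duplicate accession '", a, "' with conflicting tissue/platform")
    }
    cnt <- vapply(MANIFEST_GROUPS,
                  function(g) sum(n[raw$accession == a & raw$group == g]),
                  integer(1))
    if (all(cnt == 0L)) stop("dataset '", a, "' has no samples in any group")
    data.frame(accession = a, tissue = sub$tissue[1], platform = sub$platform[1],
               n_RA = cnt[["RA"]], n_OA = cnt[["OA"]], n_NT = cnt[["NT"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("raometa_manifest", "data.frame")
  out
}

#' Write a manifest in the canonical dialect
#'
#' Serializes a manifest back to the tab-separated (dataset, group) dialect
#' read by [load_manifest()]: groups in RA, OA, NT order, zero-count groups
#' omitted. \code{load_manifest(write_manifest(m, f))} reproduces \code{m}
#' exactly, and the writer is a fixpoint on its own output files.
#'
#' @param manifest A manifest as returned by [load_manifest()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "raometa_manifest"))
  lines <- paste(MANIFEST_HEADER, collapse = "\t")
  for (i in seq_len(nrow(manifest))) {
    for (g in MANIFEST_GROUPS) {
      cnt <- manifest[[paste0("n_", g)]][i]
      if (cnt > 0L) {
        lines <- c(lines, paste(manifest$accession[i], manifest$tissue[i],
                                manifest$platform[i], g, cnt, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

classify_design <- function(n_ra, n_oa, n_nt, accession) {
  # Precedence: any normal controls first, then the RA-vs-OA two-group
  # design, then RA-only profiling studies. Anything else is malformed.
  if (n_nt > 0L) return("has_NT")
  if (n_ra > 0L && n_oa > 0L) return("RA_vs_OA_only")
  if (n_ra > 0L && n_oa == 0L) return("RA_only")
  stop("dataset '", accession, "' fits no design class (groups: RA=", n_ra,
       ", OA=", n_oa, ", NT=", n_nt, ")")
}

#' Summarize a study-design manifest
#'
#' Tallies datasets, samples and tissues, and classifies every dataset into
#' exactly one comparison-design class: \code{has_NT} (contributes normal
#' controls), \code{RA_vs_OA_only} (exactly the RA and OA groups), or
#' \code{RA_only}. A dataset with controls is classed \code{has_NT} even
#' when it also profiles both diseases.
#'
#' @param manifest A manifest as returned by [load_manifest()].
#' @return A list with \code{n_datasets}, \code{n_samples} (sum of all group
#'   counts), \code{tissue_counts} (named integer vector) and
#'   \code{design_counts} (named integer vector over the three classes).
#' @examples
#' man <- load_manifest(system.file("extdata", "table1_manifest.tsv",
#'                                  package = "raometa"))
#' summarize_manifest(man)$design_counts
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "raometa_manifest"), nrow(manifest) >= 1L)
  classes <- vapply(seq_len(nrow(manifest)), function(i) {
    classify_design(manifest$n_RA[i], manifest$n_OA[i], manifest$n_NT[i],
                    manifest$accession[i])
  }, character(1))
  tissue_counts <- vapply(MANIFEST_TISSUES,
                          function(t) sum(manifest$tissue == t), integer(1))
  design_counts <- vapply(DESIGN_CLASSES,
                          function(cl) sum(classes == cl), integer(1))
  list(n_datasets = nrow(manifest),
       n_samples = sum(manifest$n_RA) + sum(manifest$n_OA) + sum(manifest$n_NT),
       tissue_counts = tissue_counts,
       design_counts = design_counts)
}
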