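#' Run the meta-analysis pipeline end to end
#'
#' Orchestrates harmonize -> divergence -> SAM (per contrast) ->
#' enrichment over either simulated datasets (when the config carries a
#' \code{simulate} block) or expression/metadata TSV files on disk, and
#' writes every stage's tables plus a run-provenance JSON under
#' \code{outdir}. Identical config and seed produce byte-identical
#' outputs.
#'
#' @param config A named list, or a path to a YAML/JSON file holding one.
#'   Recognized fields: \code{seed} (integer, default 1); \code{outdir}
#'   (required); \code{simulate} (list of [sim_config()] overrides, or
#'   \code{TRUE} for defaults) or \code{expression} (list with \code{dir}
#'   containing \code{<accession>.tsv} files and \code{metadata} path);
#'   \code{presence_threshold} (default 0.6); \code{contrasts} (character
#'   subset of \code{RA_vs_NT}, \code{OA_vs_NT}, \code{RA_vs_OA}; default
#'   all three); \code{sam} (list of [sam_config()] overrides);
#'   \code{enrichment_fdr} (default 0.05); \code{gmt} (path to a GMT file;
#'   for simulated runs the simulated annotation is used when no GMT is
#'   given); \code{manifest} (optional manifest TSV to summarize).
#' @return Invisibly, a list with the compendium, per-contrast SAM
#'   results, enrichment tables and the vector of written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$outdir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " stage failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  manifest_summary <- NULL
  if (!is.null(config$manifest)) {
    manifest_summary <- stage("manifest", {
      man <- load_manifest(config$manifest)
      summarize_manifest(man)
    })
  }

  sets <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      overrides <- if (isTRUE(config$simulate)) list() else config$simulate
      overrides$seed <- seed
      cfg <- do.call(sim_config, overrides)
      out <- simulate_compendium_inputs(cfg)
      out$annotation <- simulate_annotation(cfg, out$truth)
      out
    })
    matrices <- sim$matrices
    truth <- sim$truth
    sets <- sim$annotation
    message("simulate: ", length(matrices), " dataset(s), ",
            nrow(truth), " genes")
    write_truth_table(truth, file.path(outdir, "truth.tsv"))
    emit(file.path(outdir, "truth.tsv"))
    write_gmt(sets, file.path(outdir, "annotation.gmt"))
    emit(file.path(outdir, "annotation.gmt"))
  } else if (!is.null(config$expression)) {
    matrices <- stage("load", {
      files <- sort(list.files(config$expression$dir, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (!length(files)) stop("no expression TSVs in ", config$expression$dir)
      lapply(files, read_expression_tsv, meta_path = config$expression$metadata)
    })
  } else {
    stop("config needs either a 'simulate' block or an 'expression' block")
  }
  if (!is.null(config$gmt)) sets <- read_gmt(config$gmt)

  threshold <- if (is.null(config$presence_threshold)) 0.6
               else config$presence_threshold
  comp <- stage("harmonize", {
    comp <- presence_filter(build_compendium(matrices), threshold)
    message("harmonize: ", length(comp$genes), " genes retained at presence > ",
            threshold, " across ", nrow(comp$samples), " samples")
    write_compendium(comp, file.path(outdir, "compendium.tsv"))
    emit(file.path(outdir, "compendium.tsv"))
    emit(file.path(outdir, "compendium.tsv.json"))
    comp
  })

  stage("divergence", {
    dm <- distance_matrix(comp)
    labels <- comp$samples$group
    summ <- summarize_by_class(dm, labels)
    utils::write.table(summ, file.path(outdir, "distance_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(outdir, "distance_summaries.tsv"))
    if (length(unique(labels)) >= 2L) {
      cmpdf <- compare_divergences(dm, labels)
      if (!is.null(cmpdf)) {
        utils::write.table(cmpdf, file.path(outdir, "distance_comparisons.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit(file.path(outdir, "distance_comparisons.tsv"))
      }
    }
  })

  contrasts <- if (is.null(config$contrasts))
    c("RA_vs_NT", "OA_vs_NT", "RA_vs_OA") else config$contrasts
  stopifnot(length(contrasts) >= 1L)
  sam_overrides <- if (is.null(config$sam)) list() else config$sam
  sam_overrides$seed <- seed
  scfg <- do.call(sam_config, sam_overrides)
  enr_fdr <- if (is.null(config$enrichment_fdr)) 0.05 else config$enrichment_fdr

  sam_results <- list(); enr_results <- list()
  for (ct in contrasts) {
    pair <- strsplit(ct, "_vs_", fixed = TRUE)[[1]]
    fit <- stage(paste0("sam[", ct, "]"), {
      if (!all(pair %in% comp$samples$group)) {
        stop("contrast ", ct, ": group(s) ",
             paste(setdiff(pair, comp$samples$group), collapse = ", "),
             " absent from the compendium")
      }
      run_sam(comp, matrices, contrast = pair, config = scfg)
    })
    message("sam[", ct, "]: ", sum(fit$results$status != "not_significant"),
            " DE gene(s) of ", nrow(fit$results))
    sam_results[[ct]] <- fit
    de_path <- file.path(outdir, paste0("de_", ct, ".tsv"))
    write_sam_results(fit, de_path)
    emit(de_path); emit(paste0(de_path, ".json"))

    if (!is.null(sets)) {
      enr <- stage(paste0("enrichment[", ct, "]"), {
        de <- fit$results$gene[fit$results$status != "not_significant"]
        if (!length(de)) return(NULL)
        enrich(de, comp$genes, sets, fdr = enr_fdr)
      })
      if (!is.null(enr)) {
        enr_results[[ct]] <- enr
        ep <- file.path(outdir, paste0("enrichment_", ct, ".tsv"))
        utils::write.table(enr, ep, sep = "\t", quote = FALSE, row.names = FALSE)
        emit(ep)
        message("enrichment[", ct, "]: ", sum(enr$enriched),
                " term(s) at FDR < ", enr_fdr)
      }
    }
  }

  prov <- list(seed = seed,
               package_version = as.character(utils::packageVersion("raometa")),
               presence_threshold = threshold, contrasts = contrasts,
               n_datasets = length(matrices),
               n_genes_retained = length(comp$genes),
               manifest_summary = manifest_summary)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  emit(file.path(outdir, "provenance.json"))

  invisible(list(compendium = comp, sam = sam_results,
                 enrichment = enr_results, files = written))
}
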