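#' Configuration for the synthetic compendium generator
#'
#' Describes a multi-dataset microarray simulation with the statistical
#' structure the meta-analysis assumes: several datasets measuring
#' overlapping gene panels, platform-specific intensity offsets (log2 scale)
#' and gains (linear scale), group-specific spiked log2 fold-changes with a
#' component shared between the RA and OA disease groups, log-normal
#' measurement noise, and annotation terms with planted enrichment among
#' spiked genes.
#'
#' @param seed Integer seed; the generator derives one seed per dataset
#'   (\code{seed + dataset index}) so datasets can be regenerated
#'   independently, and \code{seed + n_datasets + 1} for the annotation.
#' @param n_genes Size of the gene universe.
#' @param n_datasets Number of simulated datasets.
#' @param panel_coverage Length-2 interval in (0, 1]: the fraction of the
#'   gene universe each dataset's platform measures is drawn uniformly from
#'   it.
#' @param samples_per_group Named integer vector \code{c(RA=, OA=, NT=)}:
#'   arrays per group in every dataset whose design includes that group.
#' @param designs Character vector (recycled to \code{n_datasets}) of
#'   per-dataset group designs such as \code{"RA_OA"}, \code{"RA_OA_NT"},
#'   \code{"RA_NT"}, \code{"OA_NT"}, \code{"RA_only"}. The default template
#'   mixes two-disease, disease-vs-control and RA-only designs in the
#'   proportions seen in published RA/OA compendia.
#' @param baseline_log2_mean,baseline_log2_sd Mean and spread of per-gene
#'   baseline log2 intensities \eqn{\mu_g} (defaults 8 and 2, typical of
#'   microarray intensity distributions).
#' @param platform_log_offset_sd SD of the per-dataset additive log2 offset.
#' @param platform_gain_range Interval for the per-dataset multiplicative
#'   gain applied on the linear scale.
#' @param n_spiked_ra,n_spiked_oa Number of genes spiked in RA (resp. OA)
#'   relative to NT.
#' @param shared_spike_fraction Fraction (of the smaller spike set) of
#'   spiked genes shared between RA and OA, with identical effect size and
#'   sign — the shared-pathology component. The shared count is
#'   \code{floor(shared_spike_fraction * min(n_spiked_ra, n_spiked_oa))}.
#' @param spike_log2_effect Interval of absolute spiked log2 effects; each
#'   spiked gene gets a uniform draw with random sign.
#' @param noise_log2_sd SD of per-measurement Gaussian noise on the log2
#'   scale (log-normal on the linear scale).
#' @param n_terms,term_size,planted_terms,planting_factor Annotation
#'   parameters: number of gene sets, size interval, number of terms with
#'   planted enrichment, and the sampling-weight factor of spiked genes in
#'   planted terms (1 = no planting).
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_datasets = 6L,
                       panel_coverage = c(0.7, 0.95),
                       samples_per_group = c(RA = 8L, OA = 8L, NT = 8L),
                       designs = NULL,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 2,
                       platform_log_offset_sd = 0.5,
                       platform_gain_range = c(0.8, 1.25),
                       n_spiked_ra = 100L,
                       n_spiked_oa = 100L,
                       shared_spike_fraction = 0.4,
                       spike_log2_effect = c(1.5, 3.0),
                       noise_log2_sd = 1.0,
                       n_terms = 50L,
                       term_size = c(10L, 80L),
                       planted_terms = 5L,
                       planting_factor = 5) {
  # tolerate list-typed values arriving from YAML/JSON configs
  samples_per_group <- unlist(samples_per_group)
  panel_coverage <- as.numeric(unlist(panel_coverage))
  platform_gain_range <- as.numeric(unlist(platform_gain_range))
  spike_log2_effect <- as.numeric(unlist(spike_log2_effect))
  term_size <- as.numeric(unlist(term_size))
  if (is.null(designs)) {
    designs <- rep(c("RA_OA", "RA_OA_NT", "RA_NT", "OA_NT", "RA_OA", "RA_only"),
                   length.out = n_datasets)
  } else {
    designs <- rep(unlist(designs), length.out = n_datasets)
  }
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_genes >= 1, n_datasets >= 1,
              length(panel_coverage) == 2L, panel_coverage[1] <= panel_coverage[2],
              panel_coverage[1] > 0, panel_coverage[2] <= 1,
              all(MANIFEST_GROUPS %in% names(samples_per_group)),
              all(samples_per_group >= 0),
              baseline_log2_sd >= 0, platform_log_offset_sd >= 0,
              length(platform_gain_range) == 2L,
              platform_gain_range[1] > 0,
              platform_gain_range[1] <= platform_gain_range[2],
              n_spiked_ra >= 0, n_spiked_oa >= 0,
              n_spiked_ra + n_spiked_oa <= n_genes,
              shared_spike_fraction >= 0, shared_spike_fraction <= 1,
              length(spike_log2_effect) == 2L,
              spike_log2_effect[1] <= spike_log2_effect[2],
              noise_log2_sd >= 0,
              n_terms >= 1, length(term_size) == 2L,
              term_size[1] >= 1, term_size[1] <= term_size[2],
              planted_terms >= 0, planted_terms <= n_terms,
              planting_factor >= 1)
    if (term_size[2] > n_genes) {
      stop("term_size upper bound exceeds the gene universe")
    }
    for (d in seq_len(n_datasets)) {
      grps <- design_groups(designs[d])
      if (sum(samples_per_group[grps]) == 0) {
        stop("dataset ", d, " (design ", designs[d], ") has zero samples")
      }
    }
  })
  invisible(cfg)
}

design_groups <- function(design) {
  if (design == "RA_only") return("RA")
  grps <- strsplit(design, "_", fixed = TRUE)[[1]]
  if (!length(grps) || !all(grps %in% MANIFEST_GROUPS)) {
    stop("unknown design string: ", design)
  }
  grps
}

#' Simulate multi-platform expression datasets with ground truth
#'
#' Draws per-gene baseline log2 levels \eqn{\mu_g}, plants RA and OA spike
#' sets (with a shared component carrying identical effects in both
#' diseases), and generates each dataset on its own gene panel:
#' for dataset \eqn{d}, sample \eqn{s} in group \eqn{G} and gene \eqn{g},
#' the log2 intensity is
#' \eqn{y = \mu_g + \delta_{G,g} + o_d + \epsilon}, with
#' \eqn{\epsilon \sim N(0, \sigma_{noise})} and dataset offset
#' \eqn{o_d \sim N(0, \sigma_{platform})}; the stored linear intensity is
#' \eqn{gain_d \cdot 2^y}. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with \code{matrices} (list of [expression_matrix()], one per
#'   dataset, accessions \code{SYN01}, \code{SYN02}, ...) and \code{truth},
#'   a data frame with one row per gene: \code{gene}, \code{mu},
#'   \code{delta_ra}, \code{delta_oa} (spiked log2 effects, 0 when not
#'   spiked), \code{spiked_ra}, \code{spiked_oa}, \code{spiked_shared}.
#' @export
simulate_compendium_inputs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  G <- config$n_genes
  genes <- sprintf("G%05d", seq_len(G))

  set.seed(config$seed)
  mu <- stats::rnorm(G, config$baseline_log2_mean, config$baseline_log2_sd)
  n_shared <- floor(config$shared_spike_fraction *
                    min(config$n_spiked_ra, config$n_spiked_oa))
  n_total <- config$n_spiked_ra + config$n_spiked_oa - n_shared
  picked <- if (n_total > 0) sample.int(G, n_total) else integer(0)
  shared_idx  <- utils::head(picked, n_shared)
  ra_only_idx <- picked[n_shared + seq_len(config$n_spiked_ra - n_shared)]
  oa_only_idx <- utils::tail(picked, config$n_spiked_oa - n_shared)
  eff <- function(k) {
    if (k == 0) return(numeric(0))
    stats::runif(k, config$spike_log2_effect[1], config$spike_log2_effect[2]) *
      sample(c(-1, 1), k, replace = TRUE)
  }
  delta_ra <- delta_oa <- numeric(G)
  shared_eff <- eff(n_shared)
  delta_ra[shared_idx] <- shared_eff
  delta_oa[shared_idx] <- shared_eff
  delta_ra[ra_only_idx] <- eff(length(ra_only_idx))
  delta_oa[oa_only_idx] <- eff(length(oa_only_idx))

  matrices <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    set.seed(config$seed + d)
    acc <- sprintf("SYN%02d", d)
    panel <- sort(sample.int(G, round(stats::runif(1, config$panel_coverage[1],
                                                   config$panel_coverage[2]) * G)))
    offset <- stats::rnorm(1, 0, config$platform_log_offset_sd)
    gain <- stats::runif(1, config$platform_gain_range[1],
                         config$platform_gain_range[2])
    grps <- design_groups(config$designs[d])
    grps <- grps[config$samples_per_group[grps] > 0]
    cols <- list(); labels <- character(0); ids <- character(0)
    for (g in grps) {
      ns <- config$samples_per_group[[g]]
      delta <- switch(g, RA = delta_ra, OA = delta_oa, NT = numeric(G))
      y <- matrix(mu[panel] + delta[panel] + offset, length(panel), ns) +
        matrix(stats::rnorm(length(panel) * ns, 0, config$noise_log2_sd),
               length(panel), ns)
      cols[[g]] <- gain * 2^y
      labels <- c(labels, rep(g, ns))
      ids <- c(ids, sprintf("%s_%s_%02d", acc, g, seq_len(ns)))
    }
    matrices[[d]] <- expression_matrix(acc, do.call(cbind, cols),
                                       genes[panel], ids, labels)
  }
  truth <- data.frame(gene = genes, mu = mu,
                      delta_ra = delta_ra, delta_oa = delta_oa,
                      spiked_ra = delta_ra != 0, spiked_oa = delta_oa != 0,
                      spiked_shared = seq_len(G) %in% shared_idx,
                      stringsAsFactors = FALSE)
  list(matrices = matrices, truth = truth)
}

#' Simulate annotation gene sets with planted enrichment
#'
#' Generates \code{n_terms} gene sets over the simulated gene universe.
#' The first \code{planted_terms} terms sample spiked genes (RA or OA, per
#' the truth table) with probability weight \code{planting_factor} relative
#' to non-spiked genes; the remaining terms sample uniformly. With
#' \code{planting_factor = 1} planted and non-planted terms are
#' statistically indistinguishable.
#'
#' @param config The [sim_config()] used to generate \code{truth}.
#' @param truth Truth table from [simulate_compendium_inputs()].
#' @return List of gene sets; each element is a list with \code{term_id},
#'   \code{term_name}, \code{members} (character vector) and \code{planted}
#'   (logical).
#' @export
simulate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth),
            nrow(truth) == config$n_genes)
  set.seed(config$seed + config$n_datasets + 1L)
  spiked <- truth$spiked_ra | truth$spiked_oa
  weights_planted <- ifelse(spiked, config$planting_factor, 1)
  sizes <- round(stats::runif(config$n_terms, config$term_size[1],
                              config$term_size[2]))
  lapply(seq_len(config$n_terms), function(i) {
    planted <- i <= config$planted_terms
    w <- if (planted) weights_planted else rep(1, config$n_genes)
    members <- sample(truth$gene, sizes[i], prob = w)
    list(term_id = sprintf("TERM%03d", i),
         term_name = sprintf("synthetic %s term %d",
                             if (planted) "planted" else "background", i),
         members = sort(members), planted = planted)
  })
}
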