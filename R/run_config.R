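#' Analysis run configuration
#'
#' Bundles every tunable threshold of the pipeline with validated defaults.
#' The configuration travels with a run and is serialized into the JSON
#' summary so results are reproducible from the report alone.
#'
#' @param min_alt Minimum alt-read count for a mutation to be called present
#'   in a lesion (default 3).
#' @param min_vaf Minimum variant allele fraction for presence (default 0.03).
#' @param min_depth_absent Minimum depth required before an allele may be
#'   called absent (default 20); shallower loci are indeterminate.
#' @param clonal_ccf CCF at or above which a mutation is considered clonal
#'   (default 0.95).
#' @param clonal_prob Posterior probability mass of `CCF >= clonal_ccf`
#'   required for the clonal label (default 0.5).
#' @param fdr_level False-discovery-rate level for MSI locus calls and
#'   enrichment q-values (default 0.05).
#' @param msi_event_threshold Number of significant slippage events at or
#'   above which a lesion is classified MSI-H (default 10).
#' @param discordance_cutoff Segment-level copy-ratio correlation below which
#'   an adenoma-carcinoma pair is called discordant (default 0.5).
#' @param msi_min_reads Minimum total reads per histogram for a
#'   microsatellite locus to be tested (default 20).
#' @param n_iter,burn_in,thin Gibbs sampler chain settings
#'   (defaults 10000 / 2000 / 5).
#' @param n_perm Number of gene-label permutations for enrichment testing
#'   (default 1000; values below 100 are refused at run time).
#' @param gsea_weight Weighting exponent `p` of the running-sum enrichment
#'   statistic (default 1).
#' @param score_aggregation How per-gene scores aggregate multiple
#'   delta-CCF records: `"mean"` (default) or `"max_abs"`.
#' @param exclude_hypermutators If `TRUE`, cases flagged as hypermutated are
#'   dropped before building the enrichment ranking (default `FALSE`).
#' @param seed Integer seed recorded and applied by pipeline entry points.
#'
#' @return An object of class `"adeca_run_config"` (a validated list).
#' @export
#' @examples
#' cfg <- run_config(fdr_level = 0.1)
#' cfg$fdr_level
run_config <- function(min_alt = 3,
                       min_vaf = 0.03,
                       min_depth_absent = 20,
                       clonal_ccf = 0.95,
                       clonal_prob = 0.5,
                       fdr_level = 0.05,
                       msi_event_threshold = 10,
                       discordance_cutoff = 0.5,
                       msi_min_reads = 20,
                       n_iter = 10000,
                       burn_in = 2000,
                       thin = 5,
                       n_perm = 1000,
                       gsea_weight = 1,
                       score_aggregation = c("mean", "max_abs"),
                       exclude_hypermutators = FALSE,
                       seed = 1L) {
  score_aggregation <- match.arg(score_aggregation)
  cfg <- list(
    min_alt = min_alt, min_vaf = min_vaf, min_depth_absent = min_depth_absent,
    clonal_ccf = clonal_ccf, clonal_prob = clonal_prob,
    fdr_level = fdr_level, msi_event_threshold = msi_event_threshold,
    discordance_cutoff = discordance_cutoff, msi_min_reads = msi_min_reads,
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), n_perm = as.integer(n_perm),
    gsea_weight = gsea_weight, score_aggregation = score_aggregation,
    exclude_hypermutators = isTRUE(exclude_hypermutators),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$min_alt >= 0, cfg$min_vaf >= 0, cfg$min_vaf <= 1,
    cfg$min_depth_absent >= 0,
    cfg$clonal_ccf > 0, cfg$clonal_ccf <= 1,
    cfg$clonal_prob >= 0, cfg$clonal_prob <= 1,
    cfg$fdr_level > 0, cfg$fdr_level < 1,
    cfg$msi_event_threshold >= 1,
    cfg$discordance_cutoff >= -1, cfg$discordance_cutoff <= 1,
    cfg$msi_min_reads >= 1,
    cfg$n_iter > cfg$burn_in, cfg$burn_in >= 0, cfg$thin >= 1,
    cfg$n_perm >= 1, cfg$gsea_weight >= 0
  )
  class(cfg) <- "adeca_run_config"
  cfg
}

#' @export
print.adeca_run_config <- function(x, ...) {
  cat("adeca run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# shared internal helper: stop with a prefixed, informative message
adeca_abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# emit a structured log line on stderr
adeca_log <- function(fmt, ...) {
  message(sprintf(paste0("[adeca] ", fmt), ...))
}
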