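#' Configuration for the paired-lesion synthetic data generator
#'
#' Defines the cohort emulated by [simulate_case()]: paired adenoma-carcinoma
#' exomes with a known clone structure, lesion-common and lesion-specific
#' mutations, hypermutated and MSI-H cases, planted clonality-shift gene
#' sets, and paired copy-number profiles with tunable concordance. Defaults
#' emulate a 21-case cohort (11 + 10 split across two cancer-type groups)
#' with three hypermutated cases, two of them MSI-H.
#'
#' @param n_cases Number of adenoma-carcinoma pairs (default 21).
#' @param cohort_split Cases `1..cohort_split` belong to cohort "A"
#'   (colorectal-like), the rest to cohort "B" (gastric-like; default 11).
#' @param clones_per_lesion Integer range (length 2) for the number of
#'   clones per lesion including the ancestral clone (default `c(2, 4)`).
#' @param purity_adenoma,purity_carcinoma Tumor-cell fraction of each
#'   lesion, in (0, 1] (default 0.7 each, typical of microdissected
#'   specimens).
#' @param ploidy_adenoma,ploidy_carcinoma Average tumor genome copy number
#'   (default 2).
#' @param mean_depth Mean sequencing depth at mutation loci (default 150).
#' @param depth_dispersion Negative-binomial size parameter of the depth
#'   distribution; smaller is more overdispersed (default 8).
#' @param n_common,n_adenoma_specific,n_carcinoma_specific Mutations per
#'   case in each region class (defaults 40 / 15 / 20).
#' @param cohort_b_specific_multiplier Multiplier on the lesion-specific
#'   counts for cohort-B cases, emulating the dominance of lesion-specific
#'   mutations in gastric pairs (default 2).
#' @param hypermutator_cases Case indices whose common-mutation count is
#'   inflated (default `c(4, 15, 21)`).
#' @param hypermutator_factor Fold inflation of `n_common` in hypermutated
#'   cases (default 20).
#' @param common_clonal_fraction Fraction of common mutations on the
#'   ancestral (fully clonal) clone; the rest sit on shared subclones
#'   (default 0.7).
#' @param adenoma_private_phi,carcinoma_private_phi,shared_sub_phi Ranges
#'   (length 2) for subclone cellular prevalences. Adenoma-private clones
#'   are drawn lower and carcinoma-private clones higher, emulating the
#'   selective sweep that accompanies malignant transformation.
#' @param trajectory_phi_ad,trajectory_phi_ca Optional fixed prevalences of
#'   the shared subclone in adenoma and carcinoma; `NULL` (default) draws
#'   them from `shared_sub_phi`.
#' @param sweep If `TRUE`, the carcinoma descends from a single adenoma
#'   subclone: the shared subclone is fully clonal in carcinoma and
#'   carcinoma-private mutations are clonal, yielding the fewer-clusters /
#'   higher-prevalence "sharp fitness peak" pattern (default `FALSE`).
#' @param seq_error Per-base sequencing error rate used to emit alt reads
#'   for truly absent alleles (default 0.001).
#' @param indel_fraction Fraction of mutations emitted as 1-bp deletions
#'   rather than SNVs (default 0.05).
#' @param spectrum Named length-6 probability vector over the collapsed
#'   substitution classes `C>A, C>G, C>T, T>A, T>C, T>G` used to draw SNV
#'   types. Default puts 0.4 on C>T and spreads the rest uniformly.
#' @param msi_loci Number of microsatellite loci with read-length
#'   histograms (default 300).
#' @param msi_unstable_fraction Fraction of loci truly unstable in MSI-H
#'   cases (default 0.05).
#' @param msi_cases Case indices that are MSI-H (default `c(4, 21)`, i.e.
#'   two of the three hypermutators).
#' @param slippage_shift Repeat-unit contraction of unstable alleles
#'   (default 2).
#' @param msi_depth Mean reads per microsatellite histogram (default 60).
#' @param msi_sd Read-length spread (discretized-Gaussian sd, repeat units)
#'   of a stable locus (default 0.7).
#' @param n_segments Copy-number segments per genome (default 44, tiling 22
#'   chromosomes).
#' @param scna_discordance,scna_discordance_b Fraction of segments with a
#'   lesion-specific copy-number event, for cohort A and B respectively
#'   (defaults 0.1 and 0.3; cohort B is more discordant).
#' @param scna_min_event_size Minimum absolute copy-number difference of a
#'   lesion-specific event (default 1; set 2 or more to emulate large
#'   lesion-specific events).
#' @param n_genes Size of the gene universe (default 400).
#' @param planted_geneset_size Genes in the planted clonality-shift set
#'   (default 20).
#' @param planted_delta_ccf CCF increase from adenoma to carcinoma for
#'   planted-set mutations (default 0.4).
#' @param n_driver_genes Genes in the emitted driver tier list (default 20).
#' @param seed Integer master seed; each case derives its own stream from
#'   it, so a fixed seed gives byte-identical output.
#'
#' @return An object of class `"adeca_sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 2, seed = 7)
#' cfg$purity_adenoma
sim_config <- function(n_cases = 21,
                       cohort_split = 11,
                       clones_per_lesion = c(2L, 4L),
                       purity_adenoma = 0.7,
                       purity_carcinoma = 0.7,
                       ploidy_adenoma = 2,
                       ploidy_carcinoma = 2,
                       mean_depth = 150,
                       depth_dispersion = 8,
                       n_common = 40,
                       n_adenoma_specific = 15,
                       n_carcinoma_specific = 20,
                       cohort_b_specific_multiplier = 2,
                       hypermutator_cases = c(4L, 15L, 21L),
                       hypermutator_factor = 20,
                       common_clonal_fraction = 0.7,
                       adenoma_private_phi = c(0.1, 0.5),
                       carcinoma_private_phi = c(0.4, 1.0),
                       shared_sub_phi = c(0.1, 0.8),
                       trajectory_phi_ad = NULL,
                       trajectory_phi_ca = NULL,
                       sweep = FALSE,
                       seq_error = 0.001,
                       indel_fraction = 0.05,
                       spectrum = c("C>A" = 0.12, "C>G" = 0.12, "C>T" = 0.4,
                                    "T>A" = 0.12, "T>C" = 0.12, "T>G" = 0.12),
                       msi_loci = 300,
                       msi_unstable_fraction = 0.05,
                       msi_cases = c(4L, 21L),
                       slippage_shift = 2,
                       msi_depth = 60,
                       msi_sd = 0.7,
                       n_segments = 44,
                       scna_discordance = 0.1,
                       scna_discordance_b = 0.3,
                       scna_min_event_size = 1,
                       n_genes = 400,
                       planted_geneset_size = 20,
                       planted_delta_ccf = 0.4,
                       n_driver_genes = 20,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$cohort_split <- min(cohort_split, n_cases)
  cfg$hypermutator_cases <- as.integer(hypermutator_cases)
  cfg$msi_cases <- as.integer(msi_cases)
  cfg$seed <- as.integer(seed)

  frac_fields <- c("purity_adenoma", "purity_carcinoma", "msi_unstable_fraction",
                   "scna_discordance", "scna_discordance_b", "seq_error",
                   "indel_fraction", "common_clonal_fraction")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      adeca_abort("sim_config: '%s' must lie in [0, 1], got %s", f, format(v))
  }
  if (cfg$purity_adenoma <= 0 || cfg$purity_carcinoma <= 0)
    adeca_abort("sim_config: purities must be in (0, 1]")
  count_fields <- c("n_cases", "n_common", "n_adenoma_specific",
                    "n_carcinoma_specific", "msi_loci", "n_segments",
                    "n_genes", "planted_geneset_size", "n_driver_genes")
  for (f in count_fields) {
    if (cfg[[f]] < 0) adeca_abort("sim_config: '%s' must be nonnegative", f)
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$planted_geneset_size + cfg$n_driver_genes > cfg$n_genes)
    adeca_abort("sim_config: planted set (%d) plus driver list (%d) exceed the gene universe (%d)",
                cfg$planted_geneset_size, cfg$n_driver_genes, cfg$n_genes)
  if (cfg$planted_geneset_size > cfg$n_common)
    adeca_abort("sim_config: planted set size exceeds common mutations per case")
  if (abs(sum(cfg$spectrum) - 1) > 1e-8 || length(cfg$spectrum) != 6)
    adeca_abort("sim_config: spectrum must be 6 probabilities summing to 1")
  stopifnot(length(cfg$clones_per_lesion) == 2,
            cfg$clones_per_lesion[1] >= 1,
            cfg$clones_per_lesion[2] >= cfg$clones_per_lesion[1],
            cfg$mean_depth > 0, cfg$depth_dispersion > 0,
            cfg$cohort_split >= 0, cfg$cohort_split <= cfg$n_cases,
            cfg$slippage_shift >= 1, cfg$msi_depth > 0, cfg$msi_sd > 0,
            cfg$planted_delta_ccf >= 0, cfg$planted_delta_ccf <= 1)
  class(cfg) <- "adeca_sim_config"
  cfg
}

# gene universe and the reserved planted / driver subsets, deterministic
# in the config alone
sim_gene_universe <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  list(
    genes = genes,
    planted = genes[seq_len(config$planted_geneset_size)],
    drivers = genes[config$planted_geneset_size +
                      seq_len(config$n_driver_genes)]
  )
}

# per-case RNG stream derived from the master seed
sim_case_seed <- function(config, case_index) {
  as.integer((config$seed + 104729 * case_index) %% 2147483647L)
}
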