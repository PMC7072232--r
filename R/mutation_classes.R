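#' Presence call for an allele in one lesion
#'
#' A variant is called present when it has at least `min_alt` supporting
#' reads and a VAF of at least `min_vaf`; absent only when the supporting
#' reads fall below `min_alt` at sufficient depth to assert absence;
#' anything else is indeterminate (insufficient evidence either way).
#'
#' @param alt,depth Alt-supporting reads and total depth (`alt <= depth`).
#' @param config An [run_config()] (thresholds `min_alt`, `min_vaf`,
#'   `min_depth_absent`).
#' @return `"present"`, `"absent"` or `"indeterminate"` (vectorized).
#' @export
#' @examples
#' call_presence(0, 100)   # absent
#' call_presence(30, 100)  # present
#' call_presence(1, 10)    # indeterminate
call_presence <- function(alt, depth, config = run_config()) {
  if (any(depth < 0)) adeca_abort("call_presence: negative depth")
  if (any(alt > depth))
    adeca_abort("call_presence: alt count exceeds depth at index %d",
                which(alt > depth)[1])
  vaf <- ifelse(depth > 0, alt / depth, 0)
  out <- rep("indeterminate", length(alt))
  out[alt >= config$min_alt & vaf >= config$min_vaf] <- "present"
  out[alt < config$min_alt & depth >= config$min_depth_absent] <- "absent"
  out
}

#' Regional class of a mutation from its two presence calls
#'
#' @param presence_adenoma,presence_carcinoma Presence verdicts from
#'   [call_presence()].
#' @return `"common"`, `"adenoma_specific"`, `"carcinoma_specific"` or
#'   `"excluded"` (any indeterminate verdict). A mutation absent in both
#'   lesions is not a somatic call and raises an error.
#' @export
#' @examples
#' classify_region("present", "absent")  # adenoma_specific
classify_region <- function(presence_adenoma, presence_carcinoma) {
  ok <- c("present", "absent", "indeterminate")
  if (!all(presence_adenoma %in% ok) || !all(presence_carcinoma %in% ok))
    adeca_abort("classify_region: verdicts must be present/absent/indeterminate")
  both_absent <- presence_adenoma == "absent" & presence_carcinoma == "absent"
  if (any(both_absent))
    adeca_abort("classify_region: absent in both lesions is not a somatic call (%d row(s))",
                sum(both_absent))
  out <- rep("excluded", length(presence_adenoma))
  out[presence_adenoma == "present" & presence_carcinoma == "present"] <- "common"
  out[presence_adenoma == "present" & presence_carcinoma == "absent"] <- "adenoma_specific"
  out[presence_adenoma == "absent" & presence_carcinoma == "present"] <- "carcinoma_specific"
  out
}

#' Classify all mutations of a case
#'
#' Applies [call_presence()] per lesion and [classify_region()] per
#' mutation.
#'
#' @param mutations MAF-like data frame (columns `ad_alt`, `ad_ref`,
#'   `ca_alt`, `ca_ref`, plus identifiers).
#' @param config An [run_config()].
#' @return The input with added columns `presence_adenoma`,
#'   `presence_carcinoma` and `class`.
#' @export
classify_mutations <- function(mutations, config = run_config()) {
  pa <- call_presence(mutations$ad_alt, mutations$ad_alt + mutations$ad_ref,
                      config)
  pc <- call_presence(mutations$ca_alt, mutations$ca_alt + mutations$ca_ref,
                      config)
  # rows indeterminate in one lesion and absent in the other are excluded
  # (not errors): only a present/present..absent pair is a somatic call
  cls <- rep("excluded", nrow(mutations))
  callable <- !(pa == "absent" & pc == "absent")
  if (any(!callable))
    adeca_log("classify_mutations: %d row(s) absent in both lesions, dropped as non-somatic",
              sum(!callable))
  cls[callable] <- classify_region(pa[callable], pc[callable])
  cls[!callable] <- NA_character_
  n_ex <- sum(cls == "excluded", na.rm = TRUE)
  if (n_ex > 0)
    adeca_log("classify_mutations: %d mutation(s) excluded as indeterminate", n_ex)
  mutations$presence_adenoma <- pa
  mutations$presence_carcinoma <- pc
  mutations$class <- cls
  mutations
}

#' Log-ratio of lesion-specific to lesion-common mutation counts
#'
#' `log2((n_specific + 0.5) / (n_common + 0.5))`; the 0.5 pseudocount
#' (Haldane-Anscombe) keeps zero cells finite while preserving the sign
#' convention: positive values indicate dominance of lesion-specific
#' mutations.
#'
#' @param n_specific,n_common Nonnegative counts, not both zero.
#' @return log2 ratio.
#' @export
#' @examples
#' specific_common_log_ratio(10, 10)  # 0
specific_common_log_ratio <- function(n_specific, n_common) {
  if (any(n_specific < 0) || any(n_common < 0))
    adeca_abort("specific_common_log_ratio: counts must be nonnegative")
  if (any(n_specific + n_common == 0))
    adeca_abort("specific_common_log_ratio: undefined when both counts are zero")
  log2((n_specific + 0.5) / (n_common + 0.5))
}

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# collapse a ref>alt substitution to its pyrimidine-strand class
collapse_substitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  on_purine <- ref %in% c("A", "G")
  r <- ifelse(on_purine, comp[ref], ref)
  a <- ifelse(on_purine, comp[alt], alt)
  paste0(r, ">", a)
}

#' Six-class substitution spectrum
#'
#' Proportions of SNVs over the pyrimidine-strand collapsed classes
#' C>A, C>G, C>T, T>A, T>C, T>G (e.g. a G>T change counts as C>A).
#' Non-SNV rows (indels, multi-base alleles) are ignored.
#'
#' @param mutations Data frame with `ref` and `alt` single-base columns.
#' @return Named numeric vector of six proportions summing to 1, with
#'   attribute `n_snv`; all-zero with `empty = TRUE` attribute when no SNVs.
#' @export
#' @examples
#' spectrum_six(data.frame(ref = "G", alt = "T"))["C>A"]  # 1
spectrum_six <- function(mutations) {
  bases <- c("A", "C", "G", "T")
  is_snv <- mutations$ref %in% bases & mutations$alt %in% bases &
    mutations$ref != mutations$alt
  out <- setNames(numeric(6), SPECTRUM_CLASSES)
  if (!any(is_snv)) {
    attr(out, "empty") <- TRUE
    attr(out, "n_snv") <- 0L
    return(out)
  }
  cls <- collapse_substitution(mutations$ref[is_snv], mutations$alt[is_snv])
  tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
  out[] <- as.numeric(tab) / sum(tab)
  attr(out, "n_snv") <- sum(is_snv)
  out
}

#' Per-case class summary
#'
#' Counts lesion-specific and lesion-common mutations per lesion, the
#' specific/common log-ratio, the six-class spectrum per region class, and
#' the fraction of excluded mutations.
#'
#' @param classified Output of [classify_mutations()] for one case.
#' @return List with `counts` (data frame per lesion), `spectra` (matrix
#'   class x 6), `n_excluded`.
#' @export
class_summary <- function(classified) {
  cls <- classified$class
  kept <- !is.na(cls) & cls != "excluded"
  n_common <- sum(cls[kept] == "common")
  n_ad <- sum(cls[kept] == "adenoma_specific")
  n_ca <- sum(cls[kept] == "carcinoma_specific")
  counts <- data.frame(
    lesion = c("adenoma", "carcinoma"),
    n_specific = c(n_ad, n_ca),
    n_common = n_common,
    log_ratio = c(specific_common_log_ratio(n_ad, n_common),
                  specific_common_log_ratio(n_ca, n_common)),
    stringsAsFactors = FALSE)
  spectra <- t(vapply(
    c("common", "adenoma_specific", "carcinoma_specific"),
    function(k) as.numeric(spectrum_six(classified[kept & cls == k, , drop = FALSE])),
    numeric(6)))
  colnames(spectra) <- SPECTRUM_CLASSES
  list(counts = counts, spectra = spectra,
       n_excluded = sum(cls == "excluded", na.rm = TRUE))
}

#' Case-level gene recurrence by region class
#'
#' Counts, for each gene and region class, the number of *cases* with at
#' least one mutation of that class in the gene (two hits in one case count
#' once).
#'
#' @param classified Classified mutation table across cases (columns
#'   `case`, `gene`, `class`).
#' @return Data frame `gene`, `common`, `adenoma_specific`,
#'   `carcinoma_specific` sorted by total descending.
#' @export
recurrence_by_class <- function(classified) {
  keep <- !is.na(classified$class) & classified$class != "excluded"
  d <- classified[keep, c("case", "gene", "class")]
  d <- unique(d)
  genes <- sort(unique(d$gene))
  out <- data.frame(gene = genes, common = 0L, adenoma_specific = 0L,
                    carcinoma_specific = 0L, stringsAsFactors = FALSE)
  for (k in c("common", "adenoma_specific", "carcinoma_specific")) {
    tab <- table(d$gene[d$class == k])
    out[[k]][match(names(tab), genes)] <- as.integer(tab)
  }
  out[order(-(out$common + out$adenoma_specific + out$carcinoma_specific),
            out$gene), , drop = FALSE]
}
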