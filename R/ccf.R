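#' Mutation multiplicity from observed VAF
#'
#' Estimates the number of mutated copies per tumor cell by inverting the
#' expected-VAF relation `vaf = a*m / (a*q_t + 2*(1-a))` at full
#' prevalence: `m = round(vaf * (a*q_t + 2*(1-a)) / a)`, clamped to
#' `[1, q_t]`.
#'
#' @param vaf Observed variant allele fraction in `[0, 1]`.
#' @param purity Tumor purity `a` in (0, 1].
#' @param q_t Integer tumor copy number at the locus, `>= 1`; a locus with
#'   `q_t = 0` cannot carry the mutation and raises an error.
#' @return Integer multiplicity (vectorized).
#' @export
#' @examples
#' estimate_multiplicity(0.5, 1, 2)  # 1
#' estimate_multiplicity(1.0, 1, 2)  # 2
estimate_multiplicity <- function(vaf, purity, q_t) {
  if (any(vaf < 0 | vaf > 1)) adeca_abort("estimate_multiplicity: vaf outside [0,1]")
  if (any(purity <= 0 | purity > 1)) adeca_abort("estimate_multiplicity: purity outside (0,1]")
  if (any(q_t < 1))
    adeca_abort("estimate_multiplicity: q_t = 0 at a mutated locus is inconsistent")
  m <- round(vaf * (purity * q_t + 2 * (1 - purity)) / purity)
  as.integer(pmax(1, pmin(m, q_t)))
}

#' Cancer cell fraction of a mutation in one lesion
#'
#' Point estimate `ccf = vaf * (a*q_t + 2*(1-a)) / (a*m)` with
#' `vaf = alt/depth`, clipped to `[0, 1]`. The 95% interval and the clonality
#' probability come from the Jeffreys `Beta(alt + 1/2, depth - alt + 1/2)`
#' posterior on the VAF mapped through the same linear transform:
#' `p_clonal` is the posterior mass of `ccf >= clonal_ccf` and the mutation
#' is labelled clonal when that mass reaches `clonal_prob`.
#'
#' Estimates whose unclipped CCF exceeds 1 by more than 0.25 are flagged
#' `inconsistent` (copy model incompatible with the observed VAF).
#'
#' @param alt,depth Read counts (`alt <= depth`; `depth = 0` yields an
#'   undefined, flagged estimate).
#' @param purity Tumor purity in (0, 1].
#' @param q_t Integer tumor copy number (`>= 1`).
#' @param m Multiplicity (`>= 1`); default estimated via
#'   [estimate_multiplicity()].
#' @param config An [run_config()] supplying `clonal_ccf` and `clonal_prob`.
#' @return Data frame with one row per mutation: `ccf`, `ci_lo`, `ci_hi`,
#'   `m`, `q_t`, `p_clonal`, `label`, `inconsistent`.
#' @export
#' @examples
#' compute_ccf(50, 100, purity = 1, q_t = 2, m = 1)$ccf  # 1
compute_ccf <- function(alt, depth, purity, q_t, m = NULL,
                        config = run_config()) {
  if (any(alt > depth)) adeca_abort("compute_ccf: alt exceeds depth")
  if (any(q_t < 1)) adeca_abort("compute_ccf: q_t must be >= 1 at mutated loci")
  n <- length(alt)
  depth <- rep_len(depth, n); purity <- rep_len(purity, n)
  q_t <- rep_len(q_t, n)
  vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  if (is.null(m)) {
    m <- rep(1L, n)
    ok <- !is.na(vaf)
    m[ok] <- estimate_multiplicity(pmin(vaf[ok], 1), purity[ok], q_t[ok])
  } else m <- rep_len(as.integer(m), n)
  if (any(m < 1)) adeca_abort("compute_ccf: multiplicity must be >= 1")

  scale <- (purity * q_t + 2 * (1 - purity)) / (purity * m)
  raw <- vaf * scale
  ccf <- pmin(pmax(raw, 0), 1)
  a_post <- alt + 0.5
  b_post <- depth - alt + 0.5
  ci_lo <- pmin(pmax(qbeta(0.025, a_post, b_post) * scale, 0), 1)
  ci_hi <- pmin(pmax(qbeta(0.975, a_post, b_post) * scale, 0), 1)
  # posterior mass of CCF >= clonal_ccf on the VAF scale
  v_star <- config$clonal_ccf / scale
  p_clonal <- pbeta(pmin(pmax(v_star, 0), 1), a_post, b_post,
                    lower.tail = FALSE)
  undefined <- depth == 0
  p_clonal[undefined] <- NA_real_
  ccf[undefined] <- NA_real_
  ci_lo[undefined] <- NA_real_; ci_hi[undefined] <- NA_real_
  data.frame(
    ccf = ccf, ci_lo = ci_lo, ci_hi = ci_hi, m = m, q_t = q_t,
    p_clonal = p_clonal,
    label = ifelse(is.na(p_clonal), NA_character_,
                   ifelse(p_clonal >= config$clonal_prob, "clonal", "subclonal")),
    inconsistent = !is.na(raw) & raw > 1.25,
    stringsAsFactors = FALSE)
}

# per-lesion CCF table for a classified mutation set; q_t looked up from
# segments at the mutation position (segment containing it, 1-based incl.)
ccf_lesion_table <- function(mutations, segments, purity, lesion,
                             config = run_config()) {
  pre <- if (lesion == "adenoma") "ad" else "ca"
  alt <- mutations[[paste0(pre, "_alt")]]
  depth <- alt + mutations[[paste0(pre, "_ref")]]
  seg <- segments[segments$lesion == lesion, , drop = FALSE]
  q_t <- vapply(seq_len(nrow(mutations)), function(i) {
    hit <- which(seg$chrom == mutations$chrom[i] &
                   seg$start <= mutations$pos[i] & seg$end >= mutations$pos[i])
    if (length(hit) == 0) NA_integer_ else as.integer(seg$abs_cn[hit[1]])
  }, 1L)
  ok <- !is.na(q_t) & q_t >= 1 & depth > 0
  out <- data.frame(key = mutation_key(mutations), lesion = lesion,
                    ccf = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    m = NA_integer_, q_t = q_t, p_clonal = NA_real_,
                    label = NA_character_, inconsistent = NA,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    est <- compute_ccf(alt[ok], depth[ok], purity, q_t[ok], config = config)
    out[ok, c("ccf", "ci_lo", "ci_hi", "m", "q_t", "p_clonal",
              "label", "inconsistent")] <- est
  }
  if (any(!ok))
    adeca_log("ccf: %d mutation(s) without usable copy state/depth in %s",
              sum(!ok), lesion)
  out
}

# canonical mutation key
mutation_key <- function(mutations) {
  paste(mutations$case, mutations$chrom, mutations$pos,
        mutations$ref, mutations$alt, sep = ":")
}

#' Per-lesion CCF estimates for a case
#'
#' @param mutations Classified mutation table of one case.
#' @param segments Segment table of the case (both lesions, `abs_cn`
#'   present).
#' @param purity Named vector `c(adenoma = ..., carcinoma = ...)`.
#' @param config An [run_config()].
#' @return Long data frame (one row per mutation x lesion) with CCF fields;
#'   mutations are estimated only in lesions where they are present.
#' @export
case_ccf <- function(mutations, segments, purity, config = run_config()) {
  rows <- list()
  for (lesion in c("adenoma", "carcinoma")) {
    pcol <- paste0("presence_", lesion)
    sel <- if (pcol %in% names(mutations)) mutations[[pcol]] == "present"
           else rep(TRUE, nrow(mutations))
    if (!any(sel)) next
    rows[[lesion]] <- ccf_lesion_table(mutations[sel, , drop = FALSE],
                                       segments, purity[[lesion]], lesion,
                                       config)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' CCF differences of lesion-common mutations
#'
#' One record per common mutation with both lesion CCFs defined:
#' `delta = ccf_carcinoma - ccf_adenoma`. Positive deltas mark mutations
#' that became more clonal in the carcinoma.
#'
#' @param classified Classified mutation table (column `class`).
#' @param ccf_table Long CCF table from [case_ccf()] (possibly several
#'   cases bound together).
#' @return Data frame `case`, `key`, `gene`, `ccf_adenoma`,
#'   `ccf_carcinoma`, `delta`.
#' @export
delta_ccf_table <- function(classified, ccf_table) {
  common <- classified[!is.na(classified$class) &
                         classified$class == "common", , drop = FALSE]
  if (nrow(common) == 0)
    return(data.frame(case = character(), key = character(),
                      gene = character(), ccf_adenoma = numeric(),
                      ccf_carcinoma = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE))
  key <- mutation_key(common)
  ad <- ccf_table[ccf_table$lesion == "adenoma", ]
  ca <- ccf_table[ccf_table$lesion == "carcinoma", ]
  ccf_ad <- ad$ccf[match(key, ad$key)]
  ccf_ca <- ca$ccf[match(key, ca$key)]
  ok <- !is.na(ccf_ad) & !is.na(ccf_ca)
  if (any(!ok))
    adeca_log("delta_ccf_table: %d common mutation(s) skipped (missing lesion CCF)",
              sum(!ok))
  data.frame(case = common$case[ok], key = key[ok], gene = common$gene[ok],
             ccf_adenoma = ccf_ad[ok], ccf_carcinoma = ccf_ca[ok],
             delta = ccf_ca[ok] - ccf_ad[ok], stringsAsFactors = FALSE)
}

#' Clonality contrast of driver mutations between lesions
#'
#' Restricts to mutations in tier-1/2 driver genes, collects each
#' mutation's clonality likelihood `p_clonal` (and `p_subclonal
#' = 1 - p_clonal`) per lesion, and compares adenoma vs carcinoma driver
#' clonality by Wilcoxon rank-sum test.
#'
#' @param ccf_table Long CCF table ([case_ccf()]) with a `gene` column or
#'   matched `classified` table to supply genes.
#' @param classified Classified mutation table (for gene lookup by key).
#' @param driver_genes Character vector of tier-1/2 driver gene symbols.
#' @return List with `drivers` (per mutation x lesion clonality records),
#'   `p_value` (Wilcoxon, `NA` when either lesion has fewer than 2 driver
#'   mutations), `n_adenoma`, `n_carcinoma`.
#' @export
driver_clonality_contrast <- function(ccf_table, classified, driver_genes) {
  if (length(driver_genes) == 0)
    adeca_abort("driver_clonality_contrast: empty driver list")
  gene_of <- setNames(classified$gene, mutation_key(classified))
  d <- ccf_table[!is.na(ccf_table$p_clonal), , drop = FALSE]
  d$gene <- gene_of[d$key]
  d <- d[!is.na(d$gene) & d$gene %in% driver_genes, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no driver-gene mutations with defined clonality", call. = FALSE)
    return(list(drivers = d, p_value = NA_real_,
                n_adenoma = 0L, n_carcinoma = 0L))
  }
  d$p_subclonal <- 1 - d$p_clonal
  pa <- d$p_clonal[d$lesion == "adenoma"]
  pc <- d$p_clonal[d$lesion == "carcinoma"]
  p <- if (length(pa) < 2 || length(pc) < 2) {
    warning("too few driver mutations for a rank test", call. = FALSE)
    NA_real_
  } else {
    suppressWarnings(wilcox.test(pc, pa, alternative = "two.sided")$p.value)
  }
  list(drivers = d[, c("key", "lesion", "gene", "ccf", "p_clonal",
                       "p_subclonal", "label")],
       p_value = p, n_adenoma = length(pa), n_carcinoma = length(pc))
}
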