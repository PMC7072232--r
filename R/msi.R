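#' Kolmogorov-Smirnov test on two read-length histograms
#'
#' Compares the tumor and normal read-length distributions at one
#' microsatellite locus. The statistic is the supremum distance between
#' the count-weighted empirical CDFs; the p-value uses the asymptotic
#' Kolmogorov tail with effective size `n*m/(n+m)`, or the exact (ties-
#' aware) Smirnov distribution when the pooled read count is below
#' `exact_below`.
#'
#' @param normal,tumor Numeric vectors of read counts named (or paired
#'   with) repeat lengths; pass either named vectors or two-column data
#'   frames `length`, `read_count`.
#' @param min_reads Minimum total reads required in each histogram
#'   (default 20); under-covered loci return `NA` with a message.
#' @param exact_below Pooled-count threshold under which the exact ties-
#'   aware null distribution is used (default 50).
#' @return List with `D`, `p_value`, `n_normal`, `n_tumor`; `D = NA` when
#'   under-covered.
#' @export
#' @examples
#' ks_locus_test(c(`20` = 50, `19` = 50), c(`20` = 50, `18` = 50))$D  # 0.5
ks_locus_test <- function(normal, tumor, min_reads = 20, exact_below = 50) {
  as_hist <- function(h) {
    if (is.data.frame(h)) setNames(h$read_count, h$length)
    else h
  }
  hn <- as_hist(normal); ht <- as_hist(tumor)
  if (any(hn < 0) || any(ht < 0))
    adeca_abort("ks_locus_test: negative histogram counts")
  n <- sum(hn); m <- sum(ht)
  if (n < min_reads || m < min_reads) {
    adeca_log("ks_locus_test: locus under-covered (%d/%d reads), excluded", n, m)
    return(list(D = NA_real_, p_value = NA_real_, n_normal = n, n_tumor = m))
  }
  lens <- sort(unique(c(as.numeric(names(hn)), as.numeric(names(ht)))))
  cdf <- function(h) {
    x <- as.numeric(h[as.character(lens)])
    x[is.na(x)] <- 0
    cumsum(x) / sum(x)
  }
  Fn <- cdf(hn); Ft <- cdf(ht)
  D <- max(abs(Fn - Ft))
  n_eff <- n * m / (n + m)
  p <- if (n + m < exact_below) {
    # exact ties-aware two-sided Smirnov tail on the pooled sample
    pooled <- c(rep(as.numeric(names(hn)), hn), rep(as.numeric(names(ht)), ht))
    1 - psmirnov(D - 1e-12, sizes = c(n, m), z = pooled, two.sided = TRUE,
                 exact = TRUE)
  } else {
    kolmogorov_tail(sqrt(n_eff) * D)
  }
  list(D = D, p_value = min(max(p, 0), 1), n_normal = n, n_tumor = m)
}

# asymptotic two-sided Kolmogorov tail 2*sum (-1)^(k-1) exp(-2 k^2 x^2)
kolmogorov_tail <- function(x) {
  if (x < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' Per-locus MSI tests for one sample
#'
#' Runs [ks_locus_test()] at every locus for the given tumor sample
#' against the matched normal, then applies Benjamini-Hochberg correction
#' across tested loci.
#'
#' @param histograms Long data frame `locus_id`, `sample`, `length`,
#'   `read_count` with samples `normal` and the value of `tumor_sample`.
#' @param tumor_sample Sample name to test (e.g. `"adenoma"`).
#' @param config An [run_config()] (`msi_min_reads`, `fdr_level`).
#' @return Data frame `locus_id`, `D`, `p_value`, `q_value`, `unstable`.
#' @export
msi_locus_tests <- function(histograms, tumor_sample,
                            config = run_config()) {
  loci <- unique(histograms$locus_id)
  res <- lapply(loci, function(id) {
    h <- histograms[histograms$locus_id == id, , drop = FALSE]
    norm <- h[h$sample == "normal", c("length", "read_count")]
    tum <- h[h$sample == tumor_sample, c("length", "read_count")]
    if (nrow(norm) == 0 || nrow(tum) == 0)
      return(data.frame(locus_id = id, D = NA_real_, p_value = NA_real_))
    ks <- suppressMessages(
      ks_locus_test(norm, tum, min_reads = config$msi_min_reads))
    data.frame(locus_id = id, D = ks$D, p_value = ks$p_value)
  })
  out <- do.call(rbind, res)
  tested <- !is.na(out$p_value)
  n_skip <- sum(!tested)
  if (n_skip > 0)
    adeca_log("msi: %d locus/loci under-covered or missing, excluded", n_skip)
  out$q_value <- NA_real_
  out$q_value[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out$unstable <- !is.na(out$q_value) & out$q_value < config$fdr_level
  out
}

#' MSI-H / MSS classification of a lesion
#'
#' Counts loci with significant slippage (`q < fdr_level`) and classifies
#' the lesion MSI-H when the event count reaches the threshold.
#'
#' @param locus_results Output of [msi_locus_tests()].
#' @param config An [run_config()] (`msi_event_threshold`).
#' @return List with `n_events`, `n_tested`, `classification`.
#' @export
msi_classify <- function(locus_results, config = run_config()) {
  if (nrow(locus_results) == 0)
    adeca_abort("msi_classify: no tested loci")
  n_events <- sum(locus_results$unstable, na.rm = TRUE)
  list(n_events = n_events,
       n_tested = sum(!is.na(locus_results$q_value)),
       classification = if (n_events >= config$msi_event_threshold) "MSI-H"
                        else "MSS")
}
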