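#' Aggregate delta-CCF records into a ranked gene list
#'
#' Per-gene score is the mean (or maximum-absolute) CCF change across all
#' of that gene's lesion-common mutations over all cases, sorted
#' descending. Ties are broken by gene symbol so the ranking is
#' deterministic.
#'
#' @param delta_records Data frame from [delta_ccf_table()] (columns
#'   `gene`, `delta`).
#' @param aggregation `"mean"` (default) or `"max_abs"`.
#' @return Data frame `gene`, `score` sorted by decreasing score.
#' @export
#' @examples
#' aggregate_gene_scores(data.frame(gene = "A", delta = c(0.2, 0.4)))$score
aggregate_gene_scores <- function(delta_records,
                                  aggregation = c("mean", "max_abs")) {
  aggregation <- match.arg(aggregation)
  if (nrow(delta_records) == 0)
    adeca_abort("aggregate_gene_scores: no delta-CCF records")
  f <- if (aggregation == "mean") mean
       else function(x) x[which.max(abs(x))]
  sc <- vapply(split(delta_records$delta, delta_records$gene), f, 0)
  out <- data.frame(gene = names(sc), score = as.numeric(sc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted running-sum enrichment score
#'
#' The classical weighted Kolmogorov-Smirnov statistic of preranked GSEA:
#' walking down the ranked list, hits increment the running sum by
#' `|score|^p` normalized by the total hit weight and misses decrement it
#' by `1/(N - k)`; the enrichment score is the signed maximum deviation
#' from zero.
#'
#' @param ranked Data frame `gene`, `score` in ranking order (as produced
#'   by [aggregate_gene_scores()]).
#' @param gene_set Character vector of member genes.
#' @param p Weighting exponent (default 1; `p = 0` gives the unweighted
#'   statistic).
#' @return ES in `[-1, 1]`, or `NA` (with a warning) when the set does not
#'   intersect the ranked universe.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  hit <- ranked$gene %in% gene_set
  N <- nrow(ranked)
  k <- sum(hit)
  if (k == 0) {
    warning("gene set does not intersect the ranked universe", call. = FALSE)
    return(NA_real_)
  }
  w <- abs(ranked$score)^p
  w[hit] <- if (sum(w[hit]) > 0) w[hit] / sum(w[hit]) else 1 / k
  if (k < N) {
    steps <- ifelse(hit, w, -1 / (N - k))
  } else {
    # set covers the whole universe: no miss positions exist, so measure
    # deviation of cumulative hit weight from the uniform baseline
    # (running sum ends at 0; only the weight ordering can deviate)
    steps <- w - 1 / N
  }
  rs <- cumsum(steps)
  # signed maximum deviation; exact ties between the positive and negative
  # extremes resolve to the positive one so the statistic is reproducible
  # across evaluation orders
  mx <- max(rs); mn <- min(rs)
  if (mx + mn >= -1e-9) mx else mn
}

#' Permutation test for clonality-shift gene sets
#'
#' Computes the enrichment score of each set on the observed ranking, then
#' a gene-label permutation null (set membership reassigned uniformly at
#' random, preserving set size). NES divides ES by the mean |null ES| of
#' the same sign; the permutation p-value is two-sided with the +1
#' finite-sample correction, and q-values are Benjamini-Hochberg across
#' sets. Direction is `Ca-Clonal` for positive ES (mutations more clonal
#' in the carcinoma) and `Ad-Clonal` otherwise.
#'
#' @param ranked Ranked gene list ([aggregate_gene_scores()]).
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (at least 100; fewer is refused as
#'   an unstable null).
#' @param p Weighting exponent (default 1).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame: `set`, `size` (in-universe), `ES`, `NES`, `p_value`,
#'   `q_value`, `direction`.
#' @export
permutation_test <- function(ranked, gene_sets, n_perm = 1000, p = 1,
                             seed = 1L) {
  if (n_perm < 100)
    adeca_abort("permutation_test: n_perm below 100 gives an unstable null")
  set.seed(as.integer(seed))
  N <- nrow(ranked)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], ranked$gene)
    k <- length(set)
    if (k == 0)
      return(data.frame(set = nm, size = 0L, ES = NA_real_, NES = NA_real_,
                        p_value = NA_real_, q_value = NA_real_,
                        direction = NA_character_, stringsAsFactors = FALSE))
    es <- enrichment_score(ranked, set, p)
    null_es <- vapply(seq_len(n_perm), function(b)
      enrichment_score(ranked, ranked$gene[sample.int(N, k)], p), 0)
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    pval <- (1 + sum(abs(null_es) >= abs(es))) / (1 + n_perm)
    data.frame(set = nm, size = k, ES = es, NES = nes, p_value = pval,
               q_value = NA_real_,
               direction = if (es > 0) "Ca-Clonal" else "Ad-Clonal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out
}

#' Clonality-change enrichment for a cohort
#'
#' Convenience wrapper: aggregates delta-CCF records (optionally dropping
#' hypermutated cases), ranks genes, and runs the permutation test.
#'
#' @param delta_records [delta_ccf_table()] output across cases.
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param config An [run_config()]; uses `n_perm`, `gsea_weight`,
#'   `score_aggregation`, `exclude_hypermutators`, `seed`.
#' @param hypermutator_cases Case ids to drop when
#'   `config$exclude_hypermutators` is set.
#' @return List with `ranked` and `results`.
#' @export
clonality_enrichment <- function(delta_records, gene_sets,
                                 config = run_config(),
                                 hypermutator_cases = character()) {
  if (config$exclude_hypermutators && length(hypermutator_cases) > 0) {
    delta_records <- delta_records[!delta_records$case %in% hypermutator_cases, ,
                                   drop = FALSE]
    adeca_log("enrichment: hypermutated case(s) excluded: %s",
              paste(hypermutator_cases, collapse = ", "))
  }
  ranked <- aggregate_gene_scores(delta_records, config$score_aggregation)
  results <- permutation_test(ranked, gene_sets, config$n_perm,
                              config$gsea_weight, config$seed)
  list(ranked = ranked, results = results)
}
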