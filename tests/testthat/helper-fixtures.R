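# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# small paired cohort bundle built in memory (no file round-trip)
make_bundle <- function(config) {
  cases <- lapply(seq_len(config$n_cases), function(i)
    simulate_case(config, i))
  uni <- adeca:::sim_gene_universe(config)
  b <- list(
    cases = setNames(lapply(cases, function(cs)
      list(case_id = cs$case_id, mutations = cs$mutations,
           segments = cs$segments, msi = cs$msi, purity = cs$purity,
           ploidy = cs$ploidy, cohort = cs$cohort)),
      vapply(cases, `[[`, "", "case_id")),
    gene_sets = list(PLANTED = uni$planted),
    driver_genes = uni$drivers,
    gene_annotation = cases[[1]]$gene_annotation,
    truth = list(cases = setNames(lapply(cases, function(cs)
      cs$truth[c("hypermutator", "msi_case", "cohort")]),
      vapply(cases, `[[`, "", "case_id"))))
  attr(b, "sim_cases") <- cases
  b
}

# brute-force running-sum enrichment score: independent oracle written as
# an explicit position-by-position loop
es_bruteforce <- function(scores, hit, p = 1) {
  N <- length(scores)
  k <- sum(hit)
  wsum <- sum(abs(scores[hit])^p)
  run <- 0
  run_max <- 0
  run_min <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      inc <- if (wsum > 0) abs(scores[i])^p / wsum else 1 / k
      run <- run + inc
    } else {
      run <- run - 1 / (N - k)
    }
    if (run > run_max) run_max <- run
    if (run < run_min) run_min <- run
  }
  # same tie rule as the implementation: positive extreme wins exact ties
  if (run_max + run_min >= -1e-9) run_max else run_min
}

# all set partitions of 1..n (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) { out[[length(out) + 1]] <<- assign; return() }
    for (c in seq_len(k + 1)) rec(c(assign, c), max(k, c))
  }
  rec(integer(0), 0)
  out
}

# exact DP-mixture posterior co-clustering by enumeration over partitions
# (fixed concentration alpha, uniform grid base measure)
coclust_enumerate <- function(logL_list, alpha) {
  n <- nrow(logL_list[[1]])
  G <- ncol(logL_list[[1]])
  parts <- all_partitions(n)
  log_marg_cluster <- function(rows) {
    sum(vapply(logL_list, function(M) {
      s <- colSums(M[rows, , drop = FALSE])
      mx <- max(s)
      mx + log(mean(exp(s - mx)))
    }, 0))
  }
  logw <- vapply(parts, function(z) {
    K <- max(z)
    lw <- K * log(alpha)
    for (k in seq_len(K)) {
      rows <- which(z == k)
      lw <- lw + lgamma(length(rows)) + log_marg_cluster(rows)
    }
    lw
  }, 0)
  w <- exp(logw - max(logw)); w <- w / sum(w)
  C <- matrix(0, n, n)
  for (p in seq_along(parts)) {
    z <- parts[[p]]
    C <- C + w[p] * outer(z, z, "==")
  }
  C
}
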