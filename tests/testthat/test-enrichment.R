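test_that("gene score aggregation is a deterministic mean with tie order", {
  rec <- data.frame(gene = c("A", "A", "B", "C"),
                    delta = c(0.2, 0.4, 0.3, 0.3))
  r <- aggregate_gene_scores(rec)
  expect_equal(r$score[r$gene == "A"], 0.3)
  # B and C tie at 0.3: lexicographic order
  expect_equal(r$gene, c("A", "B", "C"))
  r2 <- aggregate_gene_scores(rec[c(4, 2, 1, 3), ])
  expect_identical(r, r2)
  rmax <- aggregate_gene_scores(data.frame(gene = "A", delta = c(0.1, -0.6)),
                                aggregation = "max_abs")
  expect_equal(rmax$score, -0.6)
})

test_that("enrichment score equals the brute-force running sum", {
  # top-k set with equal scores attains the maximal ES of 1
  ranked <- data.frame(gene = paste0("g", 1:10), score = c(rep(1, 3), rep(0, 7)))
  expect_equal(enrichment_score(ranked, paste0("g", 1:3)), 1)
  # worked 6-gene example
  ranked6 <- data.frame(gene = paste0("g", 1:6),
                        score = c(.5, .4, .3, .2, .1, .05))
  expect_equal(enrichment_score(ranked6, c("g1", "g3")),
               es_bruteforce(ranked6$score, c(TRUE, FALSE, TRUE, FALSE,
                                              FALSE, FALSE)),
               tolerance = 1e-12)
  # randomized equivalence against the oracle
  set.seed(8)
  for (rep in 1:200) {
    N <- sample(5:50, 1)
    k <- sample(1:min(10, N - 1), 1)
    scores <- sort(round(rnorm(N), 3), decreasing = TRUE)
    ranked <- data.frame(gene = paste0("g", 1:N), score = scores)
    hit <- seq_len(N) %in% sample.int(N, k)
    p <- sample(c(0, 1, 2), 1)
    expect_equal(enrichment_score(ranked, ranked$gene[hit], p = p),
                 es_bruteforce(scores, hit, p = p), tolerance = 1e-12)
  }
  expect_warning(expect_true(is.na(
    enrichment_score(ranked6, c("zz1", "zz2")))), "does not intersect")
})

test_that("ES invariances: scale invariance at p=1, zero-sum running sum", {
  set.seed(9)
  scores <- sort(rnorm(30), decreasing = TRUE)
  ranked <- data.frame(gene = paste0("g", 1:30), score = scores)
  set <- sample(ranked$gene, 8)
  es1 <- enrichment_score(ranked, set, p = 1)
  ranked_scaled <- transform(ranked, score = score * 7.3)
  expect_equal(enrichment_score(ranked_scaled, set, p = 1), es1,
               tolerance = 1e-12)
  # p = 0: invariant to any monotone transform of the scores
  ranked_mono <- transform(ranked, score = exp(score))
  expect_equal(enrichment_score(ranked_mono, set, p = 0),
               enrichment_score(ranked, set, p = 0), tolerance = 1e-12)
  # increments sum to zero: the full running sum ends at 0
  hit <- ranked$gene %in% set
  w <- abs(scores); w <- w / sum(w[hit])
  steps <- ifelse(hit, w, -1 / (30 - 8))
  expect_equal(sum(steps), 0, tolerance = 1e-12)
})

test_that("permutation test recovers a planted set and is reproducible", {
  set.seed(10)
  genes <- sprintf("g%03d", 1:200)
  delta <- rnorm(200, 0, 0.1)
  planted <- genes[1:20]
  delta[1:20] <- delta[1:20] + 0.4
  rec <- data.frame(gene = genes, delta = delta)
  ranked <- aggregate_gene_scores(rec)
  sets <- list(PLANTED = planted,
               RANDOM = sample(genes[21:200], 20))
  res <- permutation_test(ranked, sets, n_perm = 1000, seed = 3)
  expect_lt(res$q_value[res$set == "PLANTED"], 0.05)
  expect_equal(res$direction[res$set == "PLANTED"], "Ca-Clonal")
  expect_gt(res$p_value[res$set == "RANDOM"], 0.05)
  res2 <- permutation_test(ranked, sets, n_perm = 1000, seed = 3)
  expect_identical(res, res2)
  expect_error(permutation_test(ranked, sets, n_perm = 50), "unstable")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(11)
  pvals <- vapply(1:200, function(r) {
    sc <- rnorm(80)
    ranked <- aggregate_gene_scores(
      data.frame(gene = sprintf("h%03d", 1:80), delta = sc))
    permutation_test(ranked, list(S = sample(ranked$gene, 15)),
                     n_perm = 200, seed = r)$p_value
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("hypermutator exclusion removes those cases from the ranking", {
  rec <- data.frame(case = rep(c("c1", "c2"), each = 2),
                    gene = c("A", "B", "A", "B"),
                    delta = c(0.1, 0.2, 0.9, 0.9))
  cfg <- run_config(exclude_hypermutators = TRUE, n_perm = 100)
  out <- quiet(clonality_enrichment(rec, list(S = "A"), cfg,
                                    hypermutator_cases = "c2"))
  expect_equal(out$ranked$score[out$ranked$gene == "A"], 0.1)
})
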