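# chain settings for tests: shorter than the analysis default but long
# enough for the small fixtures used here
test_chain <- function(n_iter = 4000, burn_in = 1000) {
  run_config(n_iter = n_iter, burn_in = burn_in)
}

test_that("a single clone collapses to one cluster at prevalence ~1", {
  mix <- simulate_clone_mixture(1.0, 100, depth = 300, purity = 0.7,
                                seed = 1)
  set.seed(1)
  fit <- cluster_one_sample(
    data.frame(alt = mix$alt, depth = mix$depth, q_t = mix$q_t, m = mix$m),
    0.7, test_chain())
  expect_equal(nrow(fit$clusters), 1)
  expect_gte(fit$clusters$phi_x, 0.97)
  expect_lte(fit$clusters$phi_x, 1.0)
})

test_that("three separated clones are recovered with correct prevalences", {
  phi_true <- c(1.0, 0.6, 0.25)
  mix <- simulate_clone_mixture(phi_true, 60, depth = 200, purity = 0.7,
                                seed = 2)
  set.seed(2)
  fit <- cluster_one_sample(
    data.frame(alt = mix$alt, depth = mix$depth, q_t = mix$q_t, m = mix$m),
    0.7, run_config())
  ari <- mclust::adjustedRandIndex(fit$assignments, mix$clone_true)
  expect_gte(ari, 0.85)
  # prevalence of the modal cluster for each true clone
  for (k in seq_along(phi_true)) {
    rows <- mix$clone_true == k
    cl <- as.integer(names(which.max(table(fit$assignments[rows]))))
    expect_lt(abs(fit$clusters$phi_x[fit$clusters$cluster == cl] -
                    phi_true[k]), 0.05)
  }
})

test_that("cluster summaries are invariant to input order", {
  mix <- simulate_clone_mixture(c(1.0, 0.4), 25, depth = 250, purity = 0.7,
                                seed = 3)
  df <- data.frame(alt = mix$alt, depth = mix$depth, q_t = mix$q_t,
                   m = mix$m)
  set.seed(7)
  a <- cluster_one_sample(df, 0.7, test_chain())
  perm <- sample(nrow(df))
  set.seed(7)
  b <- cluster_one_sample(df[perm, ], 0.7, test_chain())
  expect_equal(nrow(a$clusters), nrow(b$clusters))
  expect_equal(sort(a$clusters$phi_x), sort(b$clusters$phi_x),
               tolerance = 0.03)
  # assignments agree up to the permutation and labelling
  expect_gte(mclust::adjustedRandIndex(a$assignments,
                                       b$assignments[order(perm)]), 0.95)
})

test_that("posterior co-clustering matches exhaustive enumeration", {
  # 6 mutations from 2 prevalences; fixed concentration so the partition
  # posterior is exactly enumerable
  set.seed(4)
  alt <- c(70, 68, 72, 20, 22, 18)
  depth <- rep(200, 6)
  logL <- list(x = adeca:::build_loglik_grid(alt, depth, 0.7, rep(2, 6),
                                             rep(1, 6)))
  exact <- coclust_enumerate(logL, alpha = 1)
  set.seed(4)
  fit <- cluster_one_sample(
    data.frame(alt = alt, depth = depth, q_t = 2, m = 1), 0.7,
    run_config(n_iter = 60000, burn_in = 5000, thin = 2), fix_alpha = 1)
  expect_lt(max(abs(fit$cocluster - exact)), 0.03)
  # exchangeability: near-identical counts co-cluster with the probability
  # the exact posterior assigns (high), and far apart counts essentially
  # never do
  expect_gt(exact[1, 2], 0.8)
  expect_lt(abs(fit$cocluster[1, 2] - exact[1, 2]), 0.03)
  expect_lt(max(fit$cocluster[1:3, 4:6]), 0.05)
})

test_that("mutations sharing a clone co-cluster with high probability", {
  # within a well-populated clone the posterior leaves little mass on
  # splitting a pair of identical-count mutations apart
  mix <- simulate_clone_mixture(c(1.0, 0.4), 30, depth = 250, purity = 0.7,
                                seed = 9)
  df <- data.frame(alt = mix$alt, depth = mix$depth, q_t = mix$q_t,
                   m = mix$m)
  df$alt[2] <- df$alt[1]  # make a pair with identical counts
  set.seed(9)
  fit <- cluster_one_sample(df, 0.7, run_config(n_iter = 20000,
                                                burn_in = 2000))
  expect_gt(fit$cocluster[1, 2], 0.9)
})

test_that("two-sample mode recovers a planted prevalence trajectory", {
  phi <- cbind(c(1.0, 0.3), c(1.0, 1.0))
  mix <- simulate_clone_mixture(phi, 40, depth = 200,
                                purity = c(0.7, 0.7), seed = 5)
  set.seed(5)
  fit <- cluster_two_sample(
    data.frame(ad_alt = mix$ad_alt, ad_depth = mix$ad_depth,
               ca_alt = mix$ca_alt, ca_depth = mix$ca_depth,
               q_t = mix$q_t, m = mix$m),
    c(adenoma = 0.7, carcinoma = 0.7), run_config())
  cl <- fit$clusters
  moving <- which.min(cl$phi_adenoma)
  expect_lt(abs(cl$phi_adenoma[moving] - 0.3), 0.10)
  expect_lt(abs(cl$phi_carcinoma[moving] - 1.0), 0.10)
  expect_gt(cl$phi_carcinoma[moving] - cl$phi_adenoma[moving], 0)
  # ancestral cluster stays at (1, 1)
  anc <- which.max(cl$phi_adenoma)
  expect_lt(abs(cl$phi_adenoma[anc] - 1), 0.10)
  expect_lt(abs(cl$phi_carcinoma[anc] - 1), 0.10)
})

test_that("delta-CCF and two-sample prevalence shifts agree in sign", {
  phi <- cbind(c(1.0, 0.25), c(1.0, 0.9))
  mix <- simulate_clone_mixture(phi, 40, depth = 300,
                                purity = c(0.7, 0.7), seed = 6)
  est_ad <- compute_ccf(mix$ad_alt, mix$ad_depth, 0.7, 2, 1)
  est_ca <- compute_ccf(mix$ca_alt, mix$ca_depth, 0.7, 2, 1)
  delta <- est_ca$ccf - est_ad$ccf
  set.seed(6)
  fit <- cluster_two_sample(
    data.frame(ad_alt = mix$ad_alt, ad_depth = mix$ad_depth,
               ca_alt = mix$ca_alt, ca_depth = mix$ca_depth,
               q_t = mix$q_t, m = mix$m),
    c(adenoma = 0.7, carcinoma = 0.7), run_config())
  cl <- fit$clusters
  dphi <- (cl$phi_carcinoma - cl$phi_adenoma)[fit$assignments]
  moving <- mix$clone_true == 2
  agree <- sign(dphi[moving]) == sign(delta[moving])
  expect_gte(mean(agree), 0.95)
})

test_that("sharpness scores and verdicts follow the defined statistic", {
  ca <- data.frame(cluster = 1, n = 10, phi_x = 1.0)
  ad <- data.frame(cluster = 1:3, n = c(10, 6, 4), phi_x = c(0.8, 0.5, 0.2))
  sh <- sharpness(ad, ca)
  expect_equal(sh$carcinoma$S, 1.0)
  expect_equal(sh$adenoma$S, 0.5 * 0.8 / 3)
  expect_equal(sh$verdict, "carcinoma_sharper")
  expect_equal(sharpness(ad, ad)$verdict, "tie")
})

test_that("selective-sweep cases are called carcinoma-sharper", {
  verdicts <- vapply(1:10, function(s) {
    cfg <- sim_config(n_cases = 1, cohort_split = 1, sweep = TRUE,
                      msi_loci = 0, hypermutator_cases = integer(0),
                      seed = 100 + s)
    cs <- simulate_case(cfg, 1)
    cls <- quiet(classify_mutations(cs$mutations))
    cls$key <- adeca:::mutation_key(cls)
    cc <- quiet(case_ccf(cls, cs$segments, cs$purity))
    set.seed(s)
    res <- quiet(adeca:::run_case_clustering(
      cs, cls, cbind(case = cs$case_id, cc, stringsAsFactors = FALSE),
      test_chain(2500, 500)))
    res$sharp$verdict
  }, "")
  expect_gte(mean(verdicts == "carcinoma_sharper"), 0.8)
})
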