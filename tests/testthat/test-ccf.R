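test_that("multiplicity estimation inverts the VAF relation", {
  expect_equal(estimate_multiplicity(0.5, 1, 2), 1L)
  expect_equal(estimate_multiplicity(1.0, 1, 2), 2L)
  # oracle: argmin over m of |vaf - a*m/(a*q + 2(1-a))|
  oracle_m <- function(vaf, a, q)
    which.min(abs(vaf - a * seq_len(q) / (a * q + 2 * (1 - a))))
  for (vaf in c(0.1, 0.35, 0.65, 0.9)) {
    for (a in c(0.5, 0.8, 1)) {
      for (q in 1:4) {
        expect_equal(estimate_multiplicity(vaf, a, q), oracle_m(vaf, a, q),
                     label = sprintf("vaf=%g a=%g q=%d", vaf, a, q))
      }
    }
  }
  expect_equal(estimate_multiplicity(0.65, 0.8, 3), 2L)
  expect_error(estimate_multiplicity(0.5, 1, 0), "inconsistent")
})

test_that("CCF point estimates match the purity/copy transform", {
  expect_equal(compute_ccf(50, 100, 1, 2, 1)$ccf, 1)
  expect_equal(compute_ccf(25, 100, 0.5, 2, 1)$ccf, 1)  # 0.25 * 2 / 0.5
  e <- compute_ccf(10, 100, 0.8, 2, 1)
  expect_equal(e$ccf, 0.1 * 2 / 0.8)
  expect_equal(e$label, "subclonal")
  # interval contains the point estimate; p_clonal consistent with label
  d <- simulate_mutation_set(200, 0.7, seed = 4)
  est <- compute_ccf(d$alt, d$depth, 0.7, d$q_t)
  expect_true(all(est$ci_lo <= est$ccf + 1e-9 & est$ccf <= est$ci_hi + 1e-9))
  expect_true(all((est$p_clonal >= 0.5) == (est$label == "clonal")))
  expect_true(all(est$m <= pmax(est$q_t, 1)))
})

test_that("CCF estimate is nondecreasing in alt at fixed conditions", {
  alt <- 0:120
  est <- compute_ccf(alt, 150, 0.6, 2, 1)
  expect_true(all(diff(est$ccf) >= -1e-12))
})

test_that("CCF recovery error is dominated by binomial noise", {
  d <- simulate_mutation_set(500, 0.6, mean_depth = 150, q_values = 1:4,
                             seed = 1)
  est <- compute_ccf(d$alt, d$depth, 0.6, d$q_t)
  rmse <- sqrt(mean((est$ccf - d$ccf_true)^2))
  # the plug-in estimator carries pure binomial noise through the CCF
  # transform; at these conditions that floor is just under 0.1
  expect_lt(rmse, 0.11)
  # multiplicity recovered essentially everywhere
  expect_gt(mean(est$m == d$m_true), 0.98)
})

test_that("delta-CCF records cover exactly the common mutations", {
  cfg <- sim_config(n_cases = 1, cohort_split = 1, msi_loci = 0,
                    hypermutator_cases = integer(0), seed = 18)
  cs <- simulate_case(cfg, 1)
  cls <- quiet(classify_mutations(cs$mutations))
  cls$key <- adeca:::mutation_key(cls)
  cc <- quiet(case_ccf(cls, cs$segments, cs$purity))
  dl <- quiet(delta_ccf_table(cls, cc))
  expect_true(all(dl$delta >= -1 & dl$delta <= 1))
  expect_true(all(dl$key %in% cls$key[cls$class == "common"]))
  # deltas equal the difference of the per-lesion estimates
  expect_equal(dl$delta, dl$ccf_carcinoma - dl$ccf_adenoma)
  # planted genes show the configured positive shift on average
  planted <- dl$gene %in% cs$truth$planted_genes
  expect_gt(mean(dl$delta[planted]), mean(dl$delta[!planted]) + 0.2)
})

test_that("cohort CCF ordering matches the lesion biology of the generator", {
  cfg <- sim_config(n_cases = 6, cohort_split = 3, msi_loci = 0,
                    hypermutator_cases = integer(0), seed = 19)
  b <- make_bundle(cfg)
  s <- quiet(run_pipeline(b, run_config(), stages = c("classes", "ccf")))
  key2class <- setNames(s$classes$class, s$classes$key)
  cf <- s$ccf[!is.na(s$ccf$ccf), ]
  cf$class <- key2class[cf$key]
  m <- tapply(cf$ccf, cf$class, mean)
  expect_gt(m[["common"]],
            mean(cf$ccf[cf$class != "common"]))
  expect_gt(m[["carcinoma_specific"]], m[["adenoma_specific"]])
})

test_that("driver clonality contrast detects the planted asymmetry", {
  # 40 driver mutations subclonal in adenoma (phi 0.3), clonal in carcinoma
  set.seed(20)
  n <- 40
  mk_counts <- function(phi, a = 0.7, depth = 200) {
    xi <- a * phi / (a * 2 + 2 * (1 - a))
    rbinom(n, depth, xi)
  }
  classified <- data.frame(
    case = "c1", chrom = 1, pos = seq_len(n), ref = "C", alt = "T",
    gene = paste0("DRV", seq_len(n)), class = "common",
    stringsAsFactors = FALSE)
  key <- adeca:::mutation_key(classified)
  ccf_tab <- rbind(
    compute_ccf(mk_counts(0.3), 200, 0.7, 2, 1),
    compute_ccf(mk_counts(1.0), 200, 0.7, 2, 1))
  ccf_tab$key <- c(key, key)
  ccf_tab$lesion <- rep(c("adenoma", "carcinoma"), each = n)
  res <- driver_clonality_contrast(ccf_tab, classified,
                                   paste0("DRV", seq_len(n)))
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n_adenoma, n)
  # all drivers clonal in both lesions: no detectable difference
  ccf_same <- rbind(compute_ccf(mk_counts(1), 200, 0.7, 2, 1),
                    compute_ccf(mk_counts(1), 200, 0.7, 2, 1))
  ccf_same$key <- c(key, key)
  ccf_same$lesion <- rep(c("adenoma", "carcinoma"), each = n)
  res2 <- driver_clonality_contrast(ccf_same, classified,
                                    paste0("DRV", seq_len(n)))
  expect_gt(res2$p_value, 0.05)
  # degenerate single-driver input warns and returns NA
  expect_warning(
    res3 <- driver_clonality_contrast(ccf_tab[c(1, n + 1), ],
                                      classified[1, , drop = FALSE],
                                      "DRV1"),
    "too few")
  expect_true(is.na(res3$p_value))
})
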