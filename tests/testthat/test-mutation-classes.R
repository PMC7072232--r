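test_that("presence calling follows the alt/vaf/depth thresholds", {
  expect_equal(call_presence(0, 100), "absent")
  expect_equal(call_presence(30, 100), "present")
  expect_equal(call_presence(1, 10), "indeterminate")
  expect_equal(call_presence(3, 150), "indeterminate")  # vaf 0.02 < 0.03
  expect_equal(call_presence(c(5, 2), c(50, 100)),
               c("present", "absent"))
  expect_error(call_presence(10, 5), "exceeds depth")
})

test_that("regional classification maps presence pairs correctly", {
  expect_equal(classify_region("present", "present"), "common")
  expect_equal(classify_region("present", "absent"), "adenoma_specific")
  expect_equal(classify_region("absent", "present"), "carcinoma_specific")
  expect_equal(classify_region("indeterminate", "present"), "excluded")
  expect_error(classify_region("absent", "absent"), "not a somatic call")
})

test_that("log-ratio uses the pseudocount and preserves sign semantics", {
  expect_equal(specific_common_log_ratio(10, 10), 0)
  expect_equal(specific_common_log_ratio(0, 100), log2(0.5 / 100.5))
  expect_error(specific_common_log_ratio(0, 0), "undefined")
  # hypermutated case: common mutations dominate, log-ratio negative
  cfg <- sim_config(n_cases = 1, cohort_split = 1,
                    hypermutator_cases = 1L, msi_loci = 0, seed = 14)
  cs <- simulate_case(cfg, 1)
  cls <- quiet(classify_mutations(cs$mutations))
  s <- class_summary(cls)
  expect_true(all(s$counts$log_ratio < 0))
})

test_that("six-class spectrum collapses strands and recovers the truth", {
  expect_equal(spectrum_six(data.frame(ref = "G", alt = "T"))[["C>A"]], 1)
  twelve <- expand.grid(ref = c("A", "C", "G", "T"),
                        alt = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  twelve <- twelve[twelve$ref != twelve$alt, ]
  expect_equal(as.numeric(spectrum_six(twelve)), rep(1 / 6, 6))
  empty <- spectrum_six(data.frame(ref = "A", alt = "-"))
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty), 0)
  # generator spectrum (0.4 C>T, rest uniform) is recovered
  cfg <- sim_config(n_cases = 1, cohort_split = 1, n_common = 1000,
                    n_adenoma_specific = 0, n_carcinoma_specific = 0,
                    indel_fraction = 0, msi_loci = 0,
                    hypermutator_cases = integer(0), seed = 15)
  cs <- simulate_case(cfg, 1)
  sp <- spectrum_six(cs$mutations)
  expect_lt(abs(sp[["C>T"]] - 0.4), 3 * sqrt(0.4 * 0.6 / 1000))
  expect_equal(sum(sp), 1)
})

test_that("gene recurrence counts cases, not mutations", {
  tab <- data.frame(
    case = c("c1", "c1", "c2", "c3", "c3", "c4"),
    gene = c("TP53L", "TP53L", "TP53L", "TP53L", "APCL", "APCL"),
    class = c("common", "common", "common", "adenoma_specific",
              "common", "excluded"),
    stringsAsFactors = FALSE)
  rec <- recurrence_by_class(tab)
  tp <- rec[rec$gene == "TP53L", ]
  expect_equal(tp$common, 2)            # c1 counted once despite 2 hits
  expect_equal(tp$adenoma_specific, 1)
  expect_equal(rec[rec$gene == "APCL", ]$common, 1)
  expect_false("excluded" %in% names(rec))
  # row permutation invariance
  rec2 <- recurrence_by_class(tab[sample(nrow(tab)), ])
  expect_equal(rec, rec2)
})

test_that("classification recovers generator truth at high depth and VAF", {
  cfg <- sim_config(n_cases = 2, cohort_split = 1, mean_depth = 200,
                    msi_loci = 0, hypermutator_cases = integer(0),
                    seed = 16)
  hits <- 0; total <- 0
  for (i in 1:2) {
    cs <- simulate_case(cfg, i)
    cls <- quiet(classify_mutations(cs$mutations))
    tr <- cs$truth$mutations
    d_ad <- cs$mutations$ad_alt + cs$mutations$ad_ref
    d_ca <- cs$mutations$ca_alt + cs$mutations$ca_ref
    elig <- d_ad >= 80 & d_ca >= 80 &
      (tr$ccf_adenoma == 0 | tr$vaf_adenoma >= 0.1) &
      (tr$ccf_carcinoma == 0 | tr$vaf_carcinoma >= 0.1) &
      !is.na(cls$class) & cls$class != "excluded"
    hits <- hits + sum(cls$class[elig] == tr$class[elig])
    total <- total + sum(elig)
  }
  expect_gt(total, 100)
  expect_equal(hits, total)
  # class counts reconcile: classes partition the non-excluded set
  cs <- simulate_case(cfg, 1)
  cls <- quiet(classify_mutations(cs$mutations))
  s <- class_summary(cls)
  kept <- sum(!is.na(cls$class) & cls$class != "excluded")
  expect_equal(sum(s$counts$n_specific) + s$counts$n_common[1], kept)
})
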