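test_that("copy state and the six-class mapping are exact", {
  expect_equal(copy_state(2), "neutral")
  expect_equal(copy_state(3), "gain")
  expect_equal(copy_state(0), "loss")
  expect_error(copy_state(2.5), "integer")
  expect_equal(classify_gene_scna("gain", "gain"), "Gain-C")
  expect_equal(classify_gene_scna("loss", "loss"), "Loss-C")
  expect_equal(classify_gene_scna("gain", "neutral"), "Gain-Ad")
  expect_equal(classify_gene_scna("neutral", "gain"), "Gain-Ca")
  expect_equal(classify_gene_scna("loss", "neutral"), "Loss-Ad")
  expect_equal(classify_gene_scna("neutral", "loss"), "Loss-Ca")
  expect_equal(classify_gene_scna("neutral", "neutral"), "Neutral")
  expect_equal(classify_gene_scna("gain", "loss"), "Opposite")
  expect_equal(classify_gene_scna("loss", "gain"), "Opposite")
})

test_that("absolute copy number inverts the expected log2 ratio", {
  expect_equal(absolute_cn_from_ratio(0, 1, 2), 2L)
  expect_equal(absolute_cn_from_ratio(1, 1, 2), 4L)
  expect_equal(absolute_cn_from_ratio(0.322, 0.5, 2), 3L)
  # forward/backward consistency across purity and n
  for (a in c(0.4, 0.7, 1)) {
    for (n in 0:6) {
      r <- log2((a * n + 2 * (1 - a)) / 2)
      expect_equal(as.integer(absolute_cn_from_ratio(r, a)), n,
                   label = sprintf("a=%g n=%d", a, n))
    }
  }
})

test_that("gene classes match generator truth and are invariant to splitting", {
  for (disc in c(0, 0.3)) {
    cfg <- sim_config(n_cases = 1, cohort_split = 1, scna_discordance = disc,
                      msi_loci = 0, hypermutator_cases = integer(0),
                      seed = 24)
    cs <- simulate_case(cfg, 1)
    gc <- quiet(gene_scna_classes(cs$segments, cs$gene_annotation))
    tr <- cs$truth$genes_scna
    expect_equal(gc$category, tr$category[match(gc$gene, tr$gene)],
                 label = sprintf("discordance %g", disc))
    if (disc == 0) expect_true(all(gc$category %in% c("Gain-C", "Loss-C",
                                                      "Neutral")))
  }
  # splitting a segment into equal-ratio pieces changes nothing
  cfg <- sim_config(n_cases = 1, cohort_split = 1, msi_loci = 0,
                    hypermutator_cases = integer(0), seed = 25)
  cs <- simulate_case(cfg, 1)
  seg <- cs$segments
  split_rows <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    r <- seg[i, ]
    mid <- floor((r$start + r$end) / 2)
    a <- r; a$end <- mid
    b <- r; b$start <- mid + 1
    rbind(a, b)
  }))
  gc1 <- quiet(gene_scna_classes(seg, cs$gene_annotation))
  gc2 <- quiet(gene_scna_classes(split_rows, cs$gene_annotation))
  expect_equal(gc1, gc2)
})

test_that("category counts partition the classified genes", {
  cfg <- sim_config(n_cases = 1, cohort_split = 1, scna_discordance = 0.4,
                    msi_loci = 0, hypermutator_cases = integer(0), seed = 26)
  cs <- simulate_case(cfg, 1)
  gc <- quiet(gene_scna_classes(cs$segments, cs$gene_annotation))
  tab <- table(gc$category)
  expect_equal(sum(tab), nrow(gc))
  expect_true(all(names(tab) %in% c("Gain-C", "Loss-C", "Gain-Ad", "Gain-Ca",
                                    "Loss-Ad", "Loss-Ca", "Neutral",
                                    "Opposite")))
})

test_that("segment concordance is a length-weighted correlation", {
  seg <- data.frame(lesion = "adenoma", chrom = 1,
                    start = c(1, 101, 201), end = c(100, 200, 300),
                    log2_ratio = c(0.5, -0.3, 0.1))
  # identical profiles: r = 1
  r <- segment_concordance(seg, seg)
  expect_equal(r$r, 1)
  expect_true(r$concordant)
  # negated profile: r = -1, discordant
  neg <- transform(seg, log2_ratio = -log2_ratio)
  r2 <- segment_concordance(seg, neg)
  expect_equal(r2$r, -1)
  expect_false(r2$concordant)
  # no overlap: NA
  far <- transform(seg, chrom = 9)
  expect_true(is.na(segment_concordance(seg, far)$r))
  # length weighting: long concordant segment dominates short noise
  a <- data.frame(lesion = "x", chrom = 1, start = c(1, 1e6),
                  end = c(1e6 - 1, 1e6 + 99),
                  log2_ratio = c(1, 0.2))
  b <- data.frame(lesion = "y", chrom = 1, start = c(1, 1e6),
                  end = c(1e6 - 1, 1e6 + 99),
                  log2_ratio = c(0.9, -0.8))
  expect_gt(segment_concordance(a, b)$r, 0.9)
})

test_that("high-discordance fixtures are called discordant", {
  rs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cases = 1, cohort_split = 1, scna_discordance = 0.5,
                      scna_min_event_size = 2, msi_loci = 0,
                      hypermutator_cases = integer(0), seed = s)
    cs <- simulate_case(cfg, 1)
    segment_concordance(cs$segments[cs$segments$lesion == "adenoma", ],
                        cs$segments[cs$segments$lesion == "carcinoma", ])$r
  }, 0)
  expect_gte(mean(rs < 0.5), 0.8)
})
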