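#' Simulate one paired adenoma-carcinoma case
#'
#' Draws a clone tree (one ancestral clone fully clonal in both lesions, a
#' shared subclone, and lesion-private subclones), assigns lesion-common
#' mutations to the ancestral or shared clones and lesion-specific mutations
#' to private clones, then emits read counts, copy-number segments and
#' microsatellite read-length histograms, together with the complete ground
#' truth.
#'
#' Read counts follow the purity/copy-number model used throughout the
#' package: for a mutation with multiplicity `m` on a locus of tumor copy
#' number `q_t` in a lesion of purity `a`, the expected variant allele
#' fraction is `a*m*phi / (a*q_t + 2*(1-a))` where `phi` is the cellular
#' prevalence of the carrying clone. Alt reads are binomial at that rate;
#' depth is negative-binomial. Truly absent alleles still emit alt reads at
#' the sequencing error rate, so presence calling has a realistic
#' false-positive floor.
#'
#' @param config An [sim_config()] object.
#' @param case_index Case number in `1:config$n_cases`.
#' @return A list of class `"adeca_case"` with elements `case_id`, `cohort`,
#'   `mutations` (MAF-like data frame), `segments` (SEG-like data frame),
#'   `msi` (long histogram data frame, `NULL` if `msi_loci == 0`), `purity`,
#'   `ploidy`, and `truth` (per-mutation clone/CCF/class truth, per-locus
#'   MSI truth, per-gene copy-state truth, clone table, flags).
#' @export
#' @examples
#' cs <- simulate_case(sim_config(n_cases = 1, msi_loci = 20, seed = 3), 1)
#' table(cs$truth$mutations$class)
simulate_case <- function(config, case_index) {
  if (!inherits(config, "adeca_sim_config"))
    adeca_abort("simulate_case: 'config' must come from sim_config()")
  if (case_index < 1 || case_index > config$n_cases)
    adeca_abort("simulate_case: case_index %d outside 1..%d",
                case_index, config$n_cases)
  set.seed(sim_case_seed(config, case_index))

  case_id <- sprintf("case%02d", case_index)
  cohort <- if (case_index <= config$cohort_split) "A" else "B"
  hyper <- case_index %in% config$hypermutator_cases
  msi_case <- case_index %in% config$msi_cases
  alpha <- c(adenoma = config$purity_adenoma,
             carcinoma = config$purity_carcinoma)

  n_common <- config$n_common * if (hyper) config$hypermutator_factor else 1
  mult <- if (cohort == "B") config$cohort_b_specific_multiplier else 1
  n_ad_sp <- as.integer(round(config$n_adenoma_specific * mult))
  n_ca_sp <- as.integer(round(config$n_carcinoma_specific * mult))

  clones <- sim_clone_tree(config)
  seg <- sim_segments(config, cohort, alpha)
  seg$table <- cbind(case = case_id, seg$table, stringsAsFactors = FALSE)
  uni <- sim_gene_universe(config)
  gene_ann <- sim_gene_annotation(config)

  mut <- sim_mutations(config, case_id, n_common, n_ad_sp, n_ca_sp,
                       clones, seg, uni, gene_ann, alpha)

  msi <- if (config$msi_loci > 0) {
    m <- sim_msi_histograms(config, msi_case, alpha)
    m$table <- cbind(case = case_id, m$table, stringsAsFactors = FALSE)
    m
  } else NULL

  gene_truth <- sim_gene_scna_truth(seg, gene_ann)

  out <- list(
    case_id = case_id,
    cohort = cohort,
    mutations = mut$table,
    segments = seg$table,
    msi = if (is.null(msi)) NULL else msi$table,
    purity = alpha,
    ploidy = c(adenoma = config$ploidy_adenoma,
               carcinoma = config$ploidy_carcinoma),
    gene_annotation = gene_ann,
    truth = list(
      mutations = mut$truth,
      clones = clones,
      msi = if (is.null(msi)) NULL else msi$truth,
      genes_scna = gene_truth,
      planted_genes = uni$planted,
      driver_genes = uni$drivers,
      hypermutator = hyper,
      msi_case = msi_case,
      cohort = cohort
    )
  )
  class(out) <- "adeca_case"
  out
}

# clone tree: ancestral + one shared subclone + lesion-private subclones
sim_clone_tree <- function(config) {
  rng <- config$clones_per_lesion
  k_ad <- sample(rng[1]:rng[2], 1)
  k_ca <- if (config$sweep) 2L else sample(rng[1]:rng[2], 1)

  phi_shared_ad <- if (!is.null(config$trajectory_phi_ad)) config$trajectory_phi_ad
                   else runif(1, config$shared_sub_phi[1], config$shared_sub_phi[2])
  phi_shared_ca <- if (!is.null(config$trajectory_phi_ca)) config$trajectory_phi_ca
                   else if (config$sweep) 1.0
                   else runif(1, config$shared_sub_phi[1], config$shared_sub_phi[2])

  n_priv_ad <- max(k_ad - 2L, 1L)
  n_priv_ca <- max(k_ca - 2L, 1L)
  phi_priv_ad <- runif(n_priv_ad, config$adenoma_private_phi[1],
                       config$adenoma_private_phi[2])
  phi_priv_ca <- if (config$sweep) rep(1.0, n_priv_ca)
                 else runif(n_priv_ca, config$carcinoma_private_phi[1],
                            config$carcinoma_private_phi[2])

  data.frame(
    clone = c("ancestral", "shared1",
              paste0("adpriv", seq_len(n_priv_ad)),
              paste0("capriv", seq_len(n_priv_ca))),
    phi_adenoma = c(1, phi_shared_ad, phi_priv_ad, rep(0, n_priv_ca)),
    phi_carcinoma = c(1, phi_shared_ca, rep(0, n_priv_ad), phi_priv_ca),
    stringsAsFactors = FALSE
  )
}

# copy-number segments tiling 22 chromosomes of 1e8 bp; shared breakpoints,
# lesion-specific events on a `scna_discordance` fraction of segments
sim_segments <- function(config, cohort, alpha) {
  n_chrom <- 22L
  chrom_len <- 1e8
  per_chrom <- pmax(1L, diff(round(seq(0, config$n_segments,
                                       length.out = n_chrom + 1))))
  disc <- if (cohort == "B") config$scna_discordance_b else config$scna_discordance
  cn_levels <- 0:6
  cn_w <- c(0.02, 0.08, 0.60, 0.15, 0.08, 0.04, 0.03)

  rows <- list()
  truth_rows <- list()
  for (ch in seq_len(n_chrom)) {
    k <- per_chrom[ch]
    brk <- if (k > 1) sort(sample.int(chrom_len - 1, k - 1)) else integer(0)
    start <- c(1, brk + 1)
    end <- c(brk, chrom_len)
    q_base <- sample(cn_levels, k, replace = TRUE, prob = cn_w)
    q_ad <- q_base
    q_ca <- q_base
    is_disc <- runif(k) < disc
    for (i in which(is_disc)) {
      lesion <- sample(c("adenoma", "carcinoma"), 1)
      pool <- cn_levels[abs(cn_levels - q_base[i]) >= config$scna_min_event_size]
      new_q <- if (length(pool) == 1) pool else sample(pool, 1)
      if (lesion == "adenoma") q_ad[i] <- new_q else q_ca[i] <- new_q
    }
    for (lesion in c("adenoma", "carcinoma")) {
      q <- if (lesion == "adenoma") q_ad else q_ca
      a <- alpha[[lesion]]
      r <- log2((a * q + 2 * (1 - a)) / 2) + rnorm(k, 0, 0.05)
      rows[[length(rows) + 1]] <- data.frame(
        lesion = lesion, chrom = ch, start = start, end = end,
        n_bins = as.integer((end - start + 1) / 1000),
        log2_ratio = round(r, 4), abs_cn = q, stringsAsFactors = FALSE)
    }
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      chrom = ch, start = start, end = end, q_ad = q_ad, q_ca = q_ca,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth_rows))
}

# fixed toy gene annotation: genes placed uniformly on the tiled genome
sim_gene_annotation <- function(config) {
  chrom <- sample.int(22L, config$n_genes, replace = TRUE)
  start <- sample.int(1e8 - 10000L, config$n_genes, replace = TRUE)
  data.frame(gene = sim_gene_universe(config)$genes,
             chrom = chrom, start = start, end = start + 9999L,
             stringsAsFactors = FALSE)
}

# tumor copy number of the segment containing a position
sim_lookup_q <- function(seg_truth, chrom, pos) {
  hit <- seg_truth$chrom == chrom & seg_truth$start <= pos & seg_truth$end >= pos
  i <- which(hit)[1]
  c(q_ad = seg_truth$q_ad[i], q_ca = seg_truth$q_ca[i])
}

sim_draw_substitution <- function(config, n) {
  classes <- names(config$spectrum)
  cls <- sample(classes, n, replace = TRUE, prob = config$spectrum)
  ref_py <- substr(cls, 1, 1)
  alt_py <- substr(cls, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- runif(n) < 0.5
  data.frame(class6 = cls,
             ref = ifelse(flip, comp[ref_py], ref_py),
             alt = ifelse(flip, comp[alt_py], alt_py),
             stringsAsFactors = FALSE)
}

sim_mutations <- function(config, case_id, n_common, n_ad_sp, n_ca_sp,
                          clones, seg, uni, gene_ann, alpha) {
  n_tot <- n_common + n_ad_sp + n_ca_sp
  class_vec <- rep(c("common", "adenoma_specific", "carcinoma_specific"),
                   c(n_common, n_ad_sp, n_ca_sp))

  # gene assignment: each planted gene carries exactly one common mutation
  other_genes <- setdiff(uni$genes, uni$planted)
  n_other_common <- n_common - config$planted_geneset_size
  pick <- function(pool, n) sample(pool, n, replace = n > length(pool))
  genes <- c(uni$planted,
             pick(other_genes, n_other_common),
             pick(uni$genes, n_ad_sp),
             pick(uni$genes, n_ca_sp))
  planted <- c(rep(TRUE, config$planted_geneset_size),
               rep(FALSE, n_tot - config$planted_geneset_size))

  # clone assignment
  sub_ad <- clones$clone[startsWith(clones$clone, "adpriv")]
  sub_ca <- clones$clone[startsWith(clones$clone, "capriv")]
  clone_of <- character(n_tot)
  is_common <- class_vec == "common"
  clone_of[is_common] <- ifelse(
    runif(sum(is_common)) < config$common_clonal_fraction, "ancestral", "shared1")
  clone_of[planted] <- "planted"
  clone_of[class_vec == "adenoma_specific"] <- pick(sub_ad, n_ad_sp)
  clone_of[class_vec == "carcinoma_specific"] <- pick(sub_ca, n_ca_sp)

  phi_ad <- numeric(n_tot)
  phi_ca <- numeric(n_tot)
  idx <- match(clone_of, clones$clone)
  known <- !is.na(idx)
  phi_ad[known] <- clones$phi_adenoma[idx[known]]
  phi_ca[known] <- clones$phi_carcinoma[idx[known]]
  if (any(planted)) {
    d <- config$planted_delta_ccf
    base <- runif(sum(planted), 0.15, max(0.15, 1 - d))
    phi_ad[planted] <- base
    phi_ca[planted] <- pmin(base + d, 1)
  }

  # genomic placement and copy state; require q >= 1 in present lesions
  gi <- match(genes, gene_ann$gene)
  pos <- gene_ann$start[gi] + sample.int(10000L, n_tot, replace = TRUE) - 1L
  chrom <- gene_ann$chrom[gi]
  q_ad <- integer(n_tot); q_ca <- integer(n_tot)
  for (i in seq_len(n_tot)) {
    q <- sim_lookup_q(seg$truth, chrom[i], pos[i])
    tries <- 0
    while (((phi_ad[i] > 0 && q[["q_ad"]] < 1) ||
            (phi_ca[i] > 0 && q[["q_ca"]] < 1)) && tries < 50) {
      g <- sample(uni$genes, 1)
      gi2 <- match(g, gene_ann$gene)
      genes[i] <- g
      chrom[i] <- gene_ann$chrom[gi2]
      pos[i] <- gene_ann$start[gi2] + sample.int(10000L, 1) - 1L
      q <- sim_lookup_q(seg$truth, chrom[i], pos[i])
      tries <- tries + 1
    }
    q_ad[i] <- q[["q_ad"]]; q_ca[i] <- q[["q_ca"]]
  }
  # unique keys: bump colliding positions
  key <- paste(chrom, pos, sep = ":")
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- pos[dup] + 1L
    key <- paste(chrom, pos, sep = ":")
  }

  # substitution / indel types
  is_indel <- runif(n_tot) < config$indel_fraction
  sub <- sim_draw_substitution(config, n_tot)
  ref <- ifelse(is_indel, "A", sub$ref)
  alt <- ifelse(is_indel, "-", sub$alt)
  class6 <- ifelse(is_indel, "", sub$class6)

  # multiplicity: clonal mutations may predate amplification (m in 1..q);
  # subclonal mutations carry one copy
  present_ad <- phi_ad > 0
  present_ca <- phi_ca > 0
  qmin <- pmin(ifelse(present_ad, q_ad, Inf), ifelse(present_ca, q_ca, Inf))
  qmin[!is.finite(qmin)] <- 1
  m_base <- rep(1L, n_tot)
  clonal <- clone_of == "ancestral"
  m_base[clonal] <- vapply(pmax(qmin[clonal], 1),
                           function(q) sample.int(max(q, 1), 1), 1L)
  m_ad <- pmax(pmin(m_base, q_ad), 1L)
  m_ca <- pmax(pmin(m_base, q_ca), 1L)

  draw_counts <- function(phi, q, m, a) {
    d <- pmax(rnbinom(n_tot, mu = config$mean_depth,
                      size = config$depth_dispersion), 1L)
    xi <- ifelse(phi > 0, pmin(a * m * phi / (a * q + 2 * (1 - a)), 1),
                 config$seq_error)
    altc <- rbinom(n_tot, d, xi)
    list(alt = altc, ref = d - altc, xi = ifelse(phi > 0, xi, 0))
  }
  ad <- draw_counts(phi_ad, q_ad, m_ad, alpha[["adenoma"]])
  ca <- draw_counts(phi_ca, q_ca, m_ca, alpha[["carcinoma"]])

  tab <- data.frame(
    case = case_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = genes, context6 = class6,
    ad_alt = ad$alt, ad_ref = ad$ref, ca_alt = ca$alt, ca_ref = ca$ref,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    case = case_id, key = paste(case_id, chrom, pos, ref, alt, sep = ":"),
    gene = genes, clone = clone_of, class = class_vec,
    ccf_adenoma = phi_ad, ccf_carcinoma = phi_ca,
    q_adenoma = q_ad, q_carcinoma = q_ca,
    m_adenoma = m_ad, m_carcinoma = m_ca,
    vaf_adenoma = ad$xi, vaf_carcinoma = ca$xi,
    planted = planted, is_indel = is_indel,
    stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

# discretized-Gaussian read-length histograms per microsatellite locus;
# unstable loci mix in a contracted allele at a fraction equal to purity
sim_msi_histograms <- function(config, msi_case, alpha) {
  n <- config$msi_loci
  ref_len <- sample(10:30, n, replace = TRUE)
  unstable <- if (msi_case) runif(n) < config$msi_unstable_fraction
              else rep(FALSE, n)
  locus_id <- sprintf("MS%05d", seq_len(n))

  hist_probs <- function(center, support) {
    p <- exp(-((support - center)^2) / (2 * config$msi_sd^2))
    p / sum(p)
  }
  rows <- vector("list", n * 3)
  ri <- 0
  for (i in seq_len(n)) {
    support <- seq(ref_len[i] - config$slippage_shift - 4, ref_len[i] + 4)
    support <- support[support >= 1]
    p_norm <- hist_probs(ref_len[i], support)
    p_shift <- hist_probs(ref_len[i] - config$slippage_shift, support)
    emit <- function(sample_name, p) {
      nreads <- max(rpois(1, config$msi_depth), 1)
      cnt <- as.vector(rmultinom(1, nreads, p))
      keep <- cnt > 0
      data.frame(locus_id = locus_id[i], sample = sample_name,
                 ref_length = ref_len[i],
                 length = support[keep], read_count = cnt[keep],
                 stringsAsFactors = FALSE)
    }
    ri <- ri + 1; rows[[ri]] <- emit("normal", p_norm)
    for (lesion in c("adenoma", "carcinoma")) {
      a <- alpha[[lesion]]
      p <- if (unstable[i]) (1 - a) * p_norm + a * p_shift else p_norm
      ri <- ri + 1; rows[[ri]] <- emit(lesion, p)
    }
  }
  list(table = do.call(rbind, rows[seq_len(ri)]),
       truth = data.frame(locus_id = locus_id, ref_length = ref_len,
                          unstable = unstable, stringsAsFactors = FALSE))
}

# true per-gene copy states and six-class category from the segment truth
sim_gene_scna_truth <- function(seg, gene_ann) {
  mid <- as.integer((gene_ann$start + gene_ann$end) / 2)
  q <- t(vapply(seq_len(nrow(gene_ann)), function(i)
    sim_lookup_q(seg$truth, gene_ann$chrom[i], mid[i]), c(q_ad = 0, q_ca = 0)))
  state_ad <- vapply(q[, "q_ad"], copy_state, "")
  state_ca <- vapply(q[, "q_ca"], copy_state, "")
  data.frame(gene = gene_ann$gene,
             q_adenoma = q[, "q_ad"], q_carcinoma = q[, "q_ca"],
             state_adenoma = state_ad, state_carcinoma = state_ca,
             category = mapply(classify_gene_scna, state_ad, state_ca,
                               USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Simulate a flat set of mutations with known CCFs
#'
#' A low-level generator used to validate the CCF estimator in isolation:
#' draws mutations with known copy number, multiplicity and cellular
#' prevalence and emits binomial read counts at the model-implied VAF.
#' Clonal mutations (prevalence 1) may carry multiplicity above 1; subclonal
#' mutations carry one mutated copy.
#'
#' @param n Number of mutations.
#' @param purity Tumor purity in (0, 1].
#' @param mean_depth,depth_dispersion Negative-binomial depth model.
#' @param q_values Integer pool of tumor copy numbers sampled uniformly.
#' @param clonal_fraction Fraction of mutations with true CCF 1.
#' @param subclonal_phi Range of subclonal true CCFs.
#' @param seed Integer seed.
#' @return Data frame with `alt`, `depth`, `q_t`, `m_true`, `ccf_true`,
#'   `vaf_true`.
#' @export
simulate_mutation_set <- function(n, purity, mean_depth = 150,
                                  depth_dispersion = 8, q_values = 1:4,
                                  clonal_fraction = 0.6,
                                  subclonal_phi = c(0.1, 0.8),
                                  seed = 1L) {
  set.seed(as.integer(seed))
  q_t <- sample(q_values, n, replace = TRUE)
  clonal <- runif(n) < clonal_fraction
  phi <- ifelse(clonal, 1, runif(n, subclonal_phi[1], subclonal_phi[2]))
  m <- ifelse(clonal, vapply(q_t, function(q) sample.int(q, 1), 1L), 1L)
  xi <- pmin(purity * m * phi / (purity * q_t + 2 * (1 - purity)), 1)
  depth <- pmax(rnbinom(n, mu = mean_depth, size = depth_dispersion), 1L)
  alt <- rbinom(n, depth, xi)
  data.frame(alt = alt, depth = depth, q_t = q_t, m_true = m,
             ccf_true = phi, vaf_true = xi)
}

#' Simulate a clone mixture for clustering validation
#'
#' Generates mutations grouped into clones with fixed cellular prevalences
#' (optionally per lesion) and binomial read counts, for validating the
#' prevalence clustering in one-sample and two-sample modes.
#'
#' @param phi Numeric vector (one-sample) or 2-column matrix (two-sample;
#'   columns adenoma, carcinoma) of clone prevalences.
#' @param n_per_clone Mutations per clone (recycled).
#' @param depth Fixed sequencing depth.
#' @param purity Tumor purity; length 1 or one per lesion.
#' @param q_t Tumor copy number at all loci (default 2).
#' @param m Multiplicity at all loci (default 1).
#' @param seed Integer seed.
#' @return Data frame with one row per mutation: `clone_true`, `q_t`, `m`,
#'   and per-lesion `alt`/`depth` columns (`alt`, or `ad_alt`/`ca_alt`).
#' @export
simulate_clone_mixture <- function(phi, n_per_clone, depth = 200,
                                   purity = 0.7, q_t = 2L, m = 1L,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  phi <- if (is.matrix(phi)) phi else matrix(phi, ncol = 1)
  n_lesions <- ncol(phi)
  k <- nrow(phi)
  n_per_clone <- rep_len(n_per_clone, k)
  purity <- rep_len(purity, n_lesions)
  clone <- rep(seq_len(k), n_per_clone)
  n <- length(clone)
  out <- data.frame(clone_true = clone, q_t = q_t, m = m)
  lesion_names <- if (n_lesions == 2) c("ad", "ca") else "x"
  for (l in seq_len(n_lesions)) {
    a <- purity[l]
    xi <- pmin(a * m * phi[clone, l] / (a * q_t + 2 * (1 - a)), 1)
    altc <- rbinom(n, depth, xi)
    if (n_lesions == 1) {
      out$alt <- altc; out$depth <- depth
    } else {
      out[[paste0(lesion_names[l], "_alt")]] <- altc
      out[[paste0(lesion_names[l], "_depth")]] <- depth
    }
  }
  out
}
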