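#' Copy state of an absolute copy number
#'
#' Gains are `n > 2`, losses `n < 2`, and `n = 2` is neutral.
#'
#' @param n Integer absolute copy number, `>= 0`.
#' @return `"gain"`, `"neutral"` or `"loss"`.
#' @export
#' @examples
#' copy_state(3)  # "gain"
#' copy_state(0)  # "loss"
copy_state <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != round(n))
    adeca_abort("copy_state: absolute copy number must be a single nonnegative integer, got %s",
                format(n))
  if (n > 2) "gain" else if (n < 2) "loss" else "neutral"
}

#' Absolute copy number from a log2 depth ratio
#'
#' Inverts the purity/ploidy mixture model of the depth ratio: a segment of
#' tumor copy number `n` in a specimen of purity `a` and tumor ploidy `psi`
#' has expected ratio `(a*n + 2*(1-a)) / (a*psi + 2*(1-a))` relative to the
#' diploid normal, here parameterized against 2 so that `r = 0` maps to
#' `n = 2` in a pure diploid tumor. Used only when segments lack an
#' `abs_cn` column.
#'
#' @param r Log2 copy ratio.
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Tumor ploidy (unused in the 2-reference parameterization;
#'   kept for interface symmetry and checked positive).
#' @return Integer copy number, clamped at 0. Values that would be below
#'   -0.5 before clamping carry attribute `inconsistent = TRUE`.
#' @export
#' @examples
#' absolute_cn_from_ratio(0, 1, 2)  # 2
#' absolute_cn_from_ratio(1, 1, 2)  # 4
absolute_cn_from_ratio <- function(r, purity, ploidy = 2) {
  if (purity <= 0 || purity > 1)
    adeca_abort("absolute_cn_from_ratio: purity must be in (0, 1]")
  if (ploidy <= 0)
    adeca_abort("absolute_cn_from_ratio: ploidy must be positive")
  raw <- (2^r * 2 - 2 * (1 - purity)) / purity
  n <- pmax(as.integer(round(raw)), 0L)
  if (any(raw < -0.5)) attr(n, "inconsistent") <- TRUE
  n
}

#' Six-class categorization of a gene's copy-number change
#'
#' Maps the (adenoma state, carcinoma state) pair to the change category
#' along the adenoma-carcinoma sequence: concordant gains/losses
#' (`Gain-C` / `Loss-C`), lesion-specific gains and losses (`Gain-Ad`,
#' `Gain-Ca`, `Loss-Ad`, `Loss-Ca`), `Neutral`, and the rare
#' opposite-direction pair reported separately as `Opposite`.
#'
#' @param state_ad,state_ca `"gain"`, `"neutral"` or `"loss"`.
#' @return Category string.
#' @export
#' @examples
#' classify_gene_scna("gain", "gain")     # "Gain-C"
#' classify_gene_scna("neutral", "gain")  # "Gain-Ca"
classify_gene_scna <- function(state_ad, state_ca) {
  states <- c("gain", "neutral", "loss")
  if (!(state_ad %in% states) || !(state_ca %in% states))
    adeca_abort("classify_gene_scna: states must be gain/neutral/loss")
  key <- paste(state_ad, state_ca, sep = "/")
  switch(key,
         "gain/gain" = "Gain-C",
         "loss/loss" = "Loss-C",
         "gain/neutral" = "Gain-Ad",
         "neutral/gain" = "Gain-Ca",
         "loss/neutral" = "Loss-Ad",
         "neutral/loss" = "Loss-Ca",
         "neutral/neutral" = "Neutral",
         "Opposite")
}

#' Gene-level SCNA change classes for one case
#'
#' Assigns each gene the copy state of the segment covering its midpoint in
#' each lesion, then applies the six-class mapping. Genes not covered by a
#' segment in both lesions are excluded (and logged).
#'
#' @param segments Segment data frame with columns `lesion`, `chrom`,
#'   `start`, `end` and `abs_cn` (1-based inclusive coordinates). If
#'   `abs_cn` is absent it is derived from `log2_ratio` via
#'   [absolute_cn_from_ratio()] using `purity`/`ploidy`.
#' @param gene_annotation Data frame with `gene`, `chrom`, `start`, `end`.
#' @param purity,ploidy Optional named vectors (`adenoma`, `carcinoma`)
#'   used only when `abs_cn` must be derived.
#' @return Data frame: `gene`, `state_adenoma`, `state_carcinoma`,
#'   `category`.
#' @export
gene_scna_classes <- function(segments, gene_annotation,
                              purity = NULL, ploidy = NULL) {
  if (!"abs_cn" %in% names(segments) || all(is.na(segments$abs_cn))) {
    if (is.null(purity))
      adeca_abort("gene_scna_classes: segments lack abs_cn and no purity given")
    segments$abs_cn <- NA_integer_
    for (lesion in c("adenoma", "carcinoma")) {
      sel <- segments$lesion == lesion
      segments$abs_cn[sel] <- absolute_cn_from_ratio(
        segments$log2_ratio[sel], purity[[lesion]],
        if (is.null(ploidy)) 2 else ploidy[[lesion]])
    }
  }
  mid <- as.integer((gene_annotation$start + gene_annotation$end) / 2)
  state_for <- function(lesion) {
    seg <- segments[segments$lesion == lesion, , drop = FALSE]
    vapply(seq_along(mid), function(i) {
      hit <- which(seg$chrom == gene_annotation$chrom[i] &
                     seg$start <= mid[i] & seg$end >= mid[i])
      if (length(hit) == 0) NA_character_
      else copy_state(seg$abs_cn[hit[1]])
    }, "")
  }
  st_ad <- state_for("adenoma")
  st_ca <- state_for("carcinoma")
  keep <- !is.na(st_ad) & !is.na(st_ca)
  if (any(!keep))
    adeca_log("gene_scna_classes: %d gene(s) not covered in both lesions, excluded",
              sum(!keep))
  data.frame(
    gene = gene_annotation$gene[keep],
    state_adenoma = st_ad[keep],
    state_carcinoma = st_ca[keep],
    category = mapply(classify_gene_scna, st_ad[keep], st_ca[keep],
                      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Segment-level copy-ratio concordance between lesions
#'
#' Intersects the two lesions' segment sets into disjoint intervals and
#' computes the length-weighted Pearson correlation of their log2 ratios.
#' Pairs with correlation below the cutoff are called discordant.
#'
#' @param seg_ad,seg_ca Segment data frames for one lesion each, columns
#'   `chrom`, `start`, `end`, `log2_ratio`.
#' @param cutoff Correlation below which the pair is discordant
#'   (default 0.5).
#' @return List with `r` (weighted correlation, `NA` if no overlap or
#'   degenerate), `concordant` (logical), `n_intervals`.
#' @export
segment_concordance <- function(seg_ad, seg_ca, cutoff = 0.5) {
  pieces <- list()
  for (ch in intersect(unique(seg_ad$chrom), unique(seg_ca$chrom))) {
    a <- seg_ad[seg_ad$chrom == ch, , drop = FALSE]
    b <- seg_ca[seg_ca$chrom == ch, , drop = FALSE]
    ira <- IRanges::IRanges(start = a$start, end = a$end)
    irb <- IRanges::IRanges(start = b$start, end = b$end)
    ov <- IRanges::findOverlaps(ira, irb)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    inter <- IRanges::pintersect(ira[qh], irb[sh])
    pieces[[length(pieces) + 1]] <- data.frame(
      width = IRanges::width(inter),
      r_ad = a$log2_ratio[qh], r_ca = b$log2_ratio[sh])
  }
  if (length(pieces) == 0)
    return(list(r = NA_real_, concordant = NA, n_intervals = 0L))
  d <- do.call(rbind, pieces)
  d <- d[d$width > 0, , drop = FALSE]
  w <- d$width / sum(d$width)
  mx <- sum(w * d$r_ad); my <- sum(w * d$r_ca)
  vx <- sum(w * (d$r_ad - mx)^2); vy <- sum(w * (d$r_ca - my)^2)
  r <- if (vx <= 0 || vy <= 0) NA_real_
       else sum(w * (d$r_ad - mx) * (d$r_ca - my)) / sqrt(vx * vy)
  list(r = r, concordant = if (is.na(r)) NA else r >= cutoff,
       n_intervals = nrow(d))
}
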