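#' Run the full paired-lesion analysis over a cohort
#'
#' Executes the stages in dependency order for every case — presence
#' calling and regional classification, per-lesion CCF estimation,
#' delta-CCF for common mutations, per-lesion prevalence clustering with
#' the sharpness comparison, two-sample clustering of common mutations,
#' MSI calling, and gene-level SCNA classification with segment
#' concordance — then cohort-level enrichment, driver clonality contrast
#' and location tests. A failing stage isolates the affected case (logged)
#' rather than aborting the run.
#'
#' @param bundle A bundle from [read_case_bundle()], or a list with the
#'   same shape built in memory.
#' @param config An [run_config()].
#' @param stages Character subset of
#'   `c("classes", "ccf", "cluster", "enrich", "msi", "scna")`; disabled
#'   stages are marked skipped in the summary.
#' @return List of class `"adeca_cohort_summary"` with elements `classes`,
#'   `class_counts`, `ccf`, `delta_ccf`, `clusters`, `sharpness`,
#'   `enrichment`, `driver_contrast`, `msi`, `scna`, `concordance`,
#'   `contrasts`, `skipped`, `config`.
#' @export
run_pipeline <- function(bundle, config = run_config(),
                         stages = c("classes", "ccf", "cluster", "enrich",
                                    "msi", "scna")) {
  if (length(bundle$cases) < 1) adeca_abort("run_pipeline: no cases")
  set.seed(config$seed)
  all_stages <- c("classes", "ccf", "cluster", "enrich", "msi", "scna")
  skipped <- lapply(setdiff(all_stages, stages), function(s) "disabled in config")
  names(skipped) <- setdiff(all_stages, stages)

  acc <- list(classes = list(), class_counts = list(), ccf = list(),
              delta = list(), clusters = list(), sharp = list(),
              msi = list(), scna = list(), conc = list())
  failed_cases <- character()

  for (cs in bundle$cases) {
    res <- tryCatch({
      one <- list()
      cls <- classify_mutations(cs$mutations, config)
      cls$key <- mutation_key(cls)
      one$classes <- cls
      summ <- class_summary(cls)
      summ$counts <- cbind(case = cs$case_id, summ$counts,
                           stringsAsFactors = FALSE)
      one$class_counts <- summ$counts

      if ("ccf" %in% stages) {
        segs <- prepare_segments(cs, config)
        cc <- case_ccf(cls, segs, cs$purity, config)
        one$ccf <- cbind(case = cs$case_id, cc, stringsAsFactors = FALSE)
        one$delta <- delta_ccf_table(cls, cc)
      }
      if ("cluster" %in% stages && "ccf" %in% stages) {
        one <- c(one, run_case_clustering(cs, cls, one$ccf, config))
      }
      if ("msi" %in% stages && !is.null(cs$msi) && nrow(cs$msi) > 0) {
        rows <- lapply(c("adenoma", "carcinoma"), function(lesion) {
          lt <- msi_locus_tests(cs$msi, lesion, config)
          v <- msi_classify(lt, config)
          data.frame(case = cs$case_id, lesion = lesion,
                     n_events = v$n_events, n_tested = v$n_tested,
                     classification = v$classification,
                     stringsAsFactors = FALSE)
        })
        one$msi <- do.call(rbind, rows)
      }
      if ("scna" %in% stages && !is.null(bundle$gene_annotation)) {
        segs <- prepare_segments(cs, config)
        gc <- gene_scna_classes(segs, bundle$gene_annotation,
                                cs$purity, cs$ploidy)
        one$scna <- cbind(case = cs$case_id, gc, stringsAsFactors = FALSE)
        sc <- segment_concordance(
          segs[segs$lesion == "adenoma", ],
          segs[segs$lesion == "carcinoma", ],
          config$discordance_cutoff)
        one$conc <- data.frame(case = cs$case_id, r = sc$r,
                               concordant = sc$concordant,
                               stringsAsFactors = FALSE)
      }
      one
    }, error = function(e) {
      adeca_log("case %s failed: %s", cs$case_id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) { failed_cases <- c(failed_cases, cs$case_id); next }
    for (nm in names(res)) acc[[nm]][[cs$case_id]] <- res[[nm]]
  }

  bind <- function(lst) if (length(lst) == 0) NULL
                        else do.call(rbind, c(unname(lst), list(make.row.names = FALSE)))
  out <- list(
    classes = bind(acc$classes),
    class_counts = bind(acc$class_counts),
    ccf = bind(acc$ccf),
    delta_ccf = bind(acc$delta),
    clusters = bind(acc$clusters),
    sharpness = bind(acc$sharp),
    msi = bind(acc$msi),
    scna = bind(acc$scna),
    concordance = bind(acc$conc),
    skipped = skipped,
    failed_cases = failed_cases,
    config = config
  )

  if ("enrich" %in% stages && !is.null(out$delta_ccf) &&
      nrow(out$delta_ccf) > 0 && !is.null(bundle$gene_sets)) {
    hyper <- if (!is.null(bundle$truth))
      names(bundle$truth$cases)[vapply(bundle$truth$cases,
                                       function(x) isTRUE(x$hypermutator), NA)]
      else character()
    enr <- clonality_enrichment(out$delta_ccf, bundle$gene_sets, config, hyper)
    out$enrichment <- enr$results
    out$ranked_genes <- enr$ranked
  } else if ("enrich" %in% stages) {
    out$skipped$enrich <- "no delta-CCF records or gene sets available"
  }

  if (!is.null(out$ccf) && !is.null(bundle$driver_genes) &&
      !is.null(out$classes)) {
    out$driver_contrast <- tryCatch(
      driver_clonality_contrast(out$ccf, out$classes, bundle$driver_genes),
      warning = function(w) { adeca_log("driver contrast: %s", conditionMessage(w)); NULL },
      error = function(e) { adeca_log("driver contrast: %s", conditionMessage(e)); NULL })
  }

  cohorts <- vapply(bundle$cases, function(cs)
    as.character(if (is.null(cs$cohort) || is.na(cs$cohort)) "A" else cs$cohort), "")
  out$contrasts <- tryCatch(
    cohort_contrasts(out, setNames(cohorts, names(bundle$cases))),
    error = function(e) NULL)

  class(out) <- "adeca_cohort_summary"
  out
}

# ensure segments carry absolute copy numbers, deriving them from the
# log2 ratio when the SEG input lacks abs_cn
prepare_segments <- function(cs, config) {
  segs <- cs$segments
  if (!"abs_cn" %in% names(segs) || all(is.na(segs$abs_cn))) {
    segs$abs_cn <- NA_integer_
    for (lesion in c("adenoma", "carcinoma")) {
      sel <- segs$lesion == lesion
      segs$abs_cn[sel] <- absolute_cn_from_ratio(
        segs$log2_ratio[sel], cs$purity[[lesion]], cs$ploidy[[lesion]])
    }
  }
  segs
}

# per-case clustering stages: one-sample per lesion, sharpness, and
# two-sample on common mutations
run_case_clustering <- function(cs, cls, ccf_tab, config) {
  out <- list()
  per_lesion <- list()
  for (lesion in c("adenoma", "carcinoma")) {
    sub <- ccf_tab[ccf_tab$lesion == lesion & !is.na(ccf_tab$ccf), ]
    pre <- if (lesion == "adenoma") "ad" else "ca"
    idx <- match(sub$key, cls$key)
    df <- data.frame(alt = cls[[paste0(pre, "_alt")]][idx],
                     depth = cls[[paste0(pre, "_alt")]][idx] +
                       cls[[paste0(pre, "_ref")]][idx],
                     q_t = sub$q_t, m = sub$m)
    if (nrow(df) < 2) next
    fit <- cluster_one_sample(df, cs$purity[[lesion]], config)
    per_lesion[[lesion]] <- fit
    cl <- fit$clusters
    out$clusters <- rbind(out$clusters, data.frame(
      case = cs$case_id, mode = "one_sample", lesion = lesion,
      cluster = cl$cluster, n = cl$n, phi = cl$phi_x,
      phi_lo = cl$phi_lo_x, phi_hi = cl$phi_hi_x,
      phi_adenoma = NA_real_, phi_carcinoma = NA_real_,
      stringsAsFactors = FALSE))
  }
  if (length(per_lesion) == 2) {
    sh <- sharpness(per_lesion$adenoma$clusters, per_lesion$carcinoma$clusters)
    out$sharp <- data.frame(
      case = cs$case_id,
      k_adenoma = sh$adenoma$k, k_carcinoma = sh$carcinoma$k,
      S_adenoma = sh$adenoma$S, S_carcinoma = sh$carcinoma$S,
      verdict = sh$verdict, stringsAsFactors = FALSE)
  }
  common <- cls[!is.na(cls$class) & cls$class == "common", ]
  if (nrow(common) >= 2) {
    ad <- ccf_tab[ccf_tab$lesion == "adenoma", ]
    ca <- ccf_tab[ccf_tab$lesion == "carcinoma", ]
    ia <- match(common$key, ad$key); ic <- match(common$key, ca$key)
    ok <- !is.na(ia) & !is.na(ic) & !is.na(ad$q_t[ia]) & !is.na(ca$q_t[ic])
    df <- data.frame(
      ad_alt = common$ad_alt[ok],
      ad_depth = common$ad_alt[ok] + common$ad_ref[ok],
      ca_alt = common$ca_alt[ok],
      ca_depth = common$ca_alt[ok] + common$ca_ref[ok],
      q_ad = ad$q_t[ia][ok], q_ca = ca$q_t[ic][ok],
      m_ad = ad$m[ia][ok], m_ca = ca$m[ic][ok])
    if (nrow(df) >= 2) {
      fit2 <- cluster_two_sample(df, cs$purity, config)
      cl <- fit2$clusters
      out$clusters <- rbind(out$clusters, data.frame(
        case = cs$case_id, mode = "two_sample", lesion = "both",
        cluster = cl$cluster, n = cl$n, phi = NA_real_,
        phi_lo = NA_real_, phi_hi = NA_real_,
        phi_adenoma = cl$phi_adenoma, phi_carcinoma = cl$phi_carcinoma,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Cohort-level location tests
#'
#' Descriptive statistics mirroring standard cohort reporting: a paired
#' t-test of adenoma vs carcinoma specific-mutation counts within each
#' cohort, Welch's t-test comparing specific/common log-ratios between
#' cohorts, and Welch t-tests of CCF between region classes
#' (common vs specific; carcinoma-specific vs adenoma-specific). These are
#' plain location tests for reporting, not part of the method core.
#'
#' @param summary A partial or complete [run_pipeline()] summary (uses
#'   `class_counts`, `classes`, `ccf`).
#' @param cohorts Named character vector, case id to cohort label.
#' @return Data frame `test`, `statistic`, `df`, `p_value`, `n`; tests
#'   with insufficient group sizes produce `NA` rows with a warning.
#' @export
cohort_contrasts <- function(summary, cohorts) {
  rows <- list()
  # degenerate inputs (e.g. constant paired differences) yield an NA row
  safe_t <- function(...) tryCatch(t.test(...), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NULL
  })
  add <- function(name, ht, n) {
    rows[[length(rows) + 1]] <<- if (is.null(ht))
      data.frame(test = name, statistic = NA_real_, df = NA_real_,
                 p_value = NA_real_, n = n, stringsAsFactors = FALSE)
    else
      data.frame(test = name, statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value, n = n,
                 stringsAsFactors = FALSE)
  }
  cc <- summary$class_counts
  if (!is.null(cc)) {
    for (ch in unique(cohorts)) {
      ids <- names(cohorts)[cohorts == ch]
      sub <- cc[cc$case %in% ids, ]
      ad <- sub$n_specific[sub$lesion == "adenoma"]
      ca <- sub$n_specific[sub$lesion == "carcinoma"]
      nm <- sprintf("paired_t_specific_ad_vs_ca_cohort_%s", ch)
      if (length(ad) >= 2 && length(ad) == length(ca)) {
        add(nm, safe_t(ad, ca, paired = TRUE), length(ad))
      } else {
        warning(sprintf("cohort %s too small for a paired test", ch),
                call. = FALSE)
        add(nm, NULL, length(ad))
      }
    }
    labs <- unique(cohorts)
    if (length(labs) == 2) {
      lr <- lapply(labs, function(ch) {
        ids <- names(cohorts)[cohorts == ch]
        cc$log_ratio[cc$case %in% ids]
      })
      nm <- "welch_t_log_ratio_between_cohorts"
      if (all(lengths(lr) >= 2)) add(nm, safe_t(lr[[1]], lr[[2]]), sum(lengths(lr)))
      else { warning("a cohort is too small for the Welch test", call. = FALSE)
             add(nm, NULL, sum(lengths(lr))) }
    }
  }
  if (!is.null(summary$ccf) && !is.null(summary$classes)) {
    cls <- summary$classes
    key2class <- setNames(cls$class, cls$key)
    cf <- summary$ccf[!is.na(summary$ccf$ccf), ]
    cf$class <- key2class[cf$key]
    common <- cf$ccf[!is.na(cf$class) & cf$class == "common"]
    spec <- cf$ccf[!is.na(cf$class) & cf$class != "common"]
    ad_sp <- cf$ccf[!is.na(cf$class) & cf$class == "adenoma_specific"]
    ca_sp <- cf$ccf[!is.na(cf$class) & cf$class == "carcinoma_specific"]
    if (length(common) >= 2 && length(spec) >= 2)
      add("t_ccf_common_vs_specific", safe_t(common, spec),
          length(common) + length(spec))
    if (length(ad_sp) >= 2 && length(ca_sp) >= 2)
      add("t_ccf_carcinoma_specific_vs_adenoma_specific",
          safe_t(ca_sp, ad_sp), length(ad_sp) + length(ca_sp))
  }
  do.call(rbind, rows)
}

#' @export
print.adeca_cohort_summary <- function(x, ...) {
  cat("adeca cohort summary\n")
  if (!is.null(x$class_counts))
    cat(sprintf("  cases analysed: %d\n",
                length(unique(x$class_counts$case))))
  if (length(x$failed_cases) > 0)
    cat("  failed cases:", paste(x$failed_cases, collapse = ", "), "\n")
  for (nm in c("classes", "ccf", "clusters", "enrichment", "msi", "scna"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-12s %d rows\n", nm, nrow(x[[nm]])))
  for (nm in names(x$skipped))
    cat(sprintf("  %-12s skipped (%s)\n", nm, x$skipped[[nm]]))
  invisible(x)
}

#' Serialize a cohort summary to result files
#'
#' Writes the per-stage TSVs and a JSON overview via [write_results()].
#'
#' @param summary An `"adeca_cohort_summary"`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_cohort_summary <- function(summary, dir) {
  stage_tables <- summary[vapply(summary, is.data.frame, NA)]
  stage_tables$summary <- list(
    n_cases = if (!is.null(summary$class_counts))
      length(unique(summary$class_counts$case)) else 0,
    failed_cases = summary$failed_cases,
    skipped = summary$skipped,
    config = unclass(summary$config))
  write_results(stage_tables, dir)
}
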