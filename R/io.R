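MUTATION_COLUMNS <- c("case", "chrom", "pos", "ref", "alt", "gene",
                      "context6", "ad_alt", "ad_ref", "ca_alt", "ca_ref")
SEGMENT_COLUMNS <- c("case", "lesion", "chrom", "start", "end", "n_bins",
                     "log2_ratio", "abs_cn")
HISTOGRAM_COLUMNS <- c("case", "locus_id", "sample", "ref_length",
                       "length", "read_count")

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    adeca_abort("%s: missing required column(s): %s", file,
                paste(missing, collapse = ", "))
  df
}

#' Read a MAF-like mutation table
#'
#' Tab-separated, one row per somatic variant with per-lesion alt/ref read
#' counts. Negative counts and malformed rows are reported with their row
#' numbers.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_mutations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(d, MUTATION_COLUMNS, path)
  for (col in c("ad_alt", "ad_ref", "ca_alt", "ca_ref", "pos")) {
    bad <- which(is.na(d[[col]]) | d[[col]] < 0)
    if (length(bad) > 0)
      adeca_abort("%s: negative or missing '%s' at row(s) %s", path, col,
                  paste(head(bad, 5), collapse = ", "))
  }
  d
}

#' Read a SEG-format segment table
#'
#' Tab-separated with 1-based inclusive coordinates; rows where
#' `start >= end` are rejected.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_segments <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(d, setdiff(SEGMENT_COLUMNS, "abs_cn"), path)
  bad <- which(d$start >= d$end)
  if (length(bad) > 0)
    adeca_abort("%s: start >= end at row(s) %s", path,
                paste(head(bad, 5), collapse = ", "))
  if (!"abs_cn" %in% names(d)) d$abs_cn <- NA_integer_
  d
}

#' Read per-microsatellite read-length histograms
#' @param path File path.
#' @return Validated long data frame.
#' @export
read_msi_histograms <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(d, HISTOGRAM_COLUMNS, path)
  bad <- which(is.na(d$read_count) | d$read_count < 0)
  if (length(bad) > 0)
    adeca_abort("%s: negative read_count at row(s) %s", path,
                paste(head(bad, 5), collapse = ", "))
  d
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated format: set name, description, then member
#' genes.
#'
#' @param path File path.
#' @return Named list of character vectors, with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 3
  if (any(short))
    adeca_abort("%s: GMT line(s) with fewer than 3 fields: %s", path,
                paste(head(which(short), 5), collapse = ", "))
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2),
                                         names(sets))
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a driver-gene tier list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored. Symbols are opaque, case-sensitive strings.
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_driver_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture bundle
#'
#' Simulates every case of the configuration and writes the full set of
#' pipeline inputs plus the ground truth: `mutations.tsv` (MAF-like),
#' `segments.seg`, `msi_histograms.tsv`, `purity_ploidy.tsv`,
#' `gene_annotation.tsv`, `gene_sets.gmt` (the planted set plus random
#' decoy sets), `driver_genes.txt`, `truth.json` and `sim_config.json`.
#' All files are plain text and parse back losslessly through the readers.
#'
#' @param config An [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cases <- lapply(seq_len(config$n_cases), function(i)
    simulate_case(config, i))

  muts <- do.call(rbind, lapply(cases, `[[`, "mutations"))
  segs <- do.call(rbind, lapply(cases, `[[`, "segments"))
  msis <- do.call(rbind, lapply(cases, `[[`, "msi"))
  pp <- do.call(rbind, lapply(cases, function(cs)
    data.frame(case = cs$case_id, lesion = c("adenoma", "carcinoma"),
               purity = as.numeric(cs$purity),
               ploidy = as.numeric(cs$ploidy),
               cohort = cs$cohort, stringsAsFactors = FALSE)))

  uni <- sim_gene_universe(config)
  set.seed(config$seed)
  decoy_pool <- setdiff(uni$genes, c(uni$planted, uni$drivers))
  sets <- c(list(PLANTED_CLONALITY_SHIFT = uni$planted),
            setNames(lapply(1:5, function(i)
              sample(decoy_pool, min(20, length(decoy_pool)))),
              paste0("RANDOM_SET_", 1:5)))
  descs <- c(PLANTED_CLONALITY_SHIFT = "synthetic clonality-shift set",
             setNames(rep("synthetic decoy set", 5),
                      paste0("RANDOM_SET_", 1:5)))

  truth <- list(
    planted_genes = uni$planted,
    driver_genes = uni$drivers,
    cases = setNames(lapply(cases, function(cs) {
      tr <- cs$truth
      list(mutations = tr$mutations, clones = tr$clones, msi = tr$msi,
           genes_scna = tr$genes_scna, hypermutator = tr$hypermutator,
           msi_case = tr$msi_case, cohort = tr$cohort)
    }), vapply(cases, `[[`, "", "case_id")))

  paths <- c(
    mutations = write_tsv(muts, file.path(dir, "mutations.tsv")),
    segments = write_tsv(segs, file.path(dir, "segments.seg")),
    purity_ploidy = write_tsv(pp, file.path(dir, "purity_ploidy.tsv")),
    gene_annotation = write_tsv(cases[[1]]$gene_annotation,
                                file.path(dir, "gene_annotation.tsv")))
  if (!is.null(msis))
    paths["msi"] <- write_tsv(msis, file.path(dir, "msi_histograms.tsv"))
  write_gmt(sets, file.path(dir, "gene_sets.gmt"), descs)
  paths["gene_sets"] <- file.path(dir, "gene_sets.gmt")
  writeLines(uni$drivers, file.path(dir, "driver_genes.txt"))
  paths["drivers"] <- file.path(dir, "driver_genes.txt")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(config), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths["config"] <- file.path(dir, "sim_config.json")
  invisible(paths)
}

#' Read a case bundle directory
#'
#' Loads everything [write_fixture_bundle()] writes (or equivalently
#' structured real inputs) and splits it into validated per-case bundles.
#'
#' @param dir Directory containing the bundle files.
#' @return List with `cases` (per-case list: `case_id`, `mutations`,
#'   `segments`, `msi`, `purity`, `ploidy`, `cohort`), plus shared
#'   `gene_sets`, `driver_genes`, `gene_annotation`, and `truth` when
#'   `truth.json` is present.
#' @export
read_case_bundle <- function(dir) {
  fp <- function(x) file.path(dir, x)
  for (f in c("mutations.tsv", "segments.seg", "purity_ploidy.tsv"))
    if (!file.exists(fp(f))) adeca_abort("read_case_bundle: missing %s", fp(f))
  muts <- read_mutations(fp("mutations.tsv"))
  segs <- read_segments(fp("segments.seg"))
  pp <- read.delim(fp("purity_ploidy.tsv"), stringsAsFactors = FALSE)
  require_columns(pp, c("case", "lesion", "purity", "ploidy"),
                  fp("purity_ploidy.tsv"))
  if (any(pp$purity <= 0 | pp$purity > 1))
    adeca_abort("purity_ploidy.tsv: purity outside (0, 1]")
  if (any(pp$ploidy <= 0))
    adeca_abort("purity_ploidy.tsv: ploidy must be positive")
  msi <- if (file.exists(fp("msi_histograms.tsv")))
    read_msi_histograms(fp("msi_histograms.tsv")) else NULL

  case_ids <- unique(pp$case)
  cases <- setNames(lapply(case_ids, function(id) {
    prow <- pp[pp$case == id, ]
    list(case_id = id,
         mutations = muts[muts$case == id, , drop = FALSE],
         segments = segs[segs$case == id, , drop = FALSE],
         msi = if (is.null(msi)) NULL
               else msi[msi$case == id, , drop = FALSE],
         purity = setNames(prow$purity, prow$lesion),
         ploidy = setNames(prow$ploidy, prow$lesion),
         cohort = if ("cohort" %in% names(prow)) prow$cohort[1] else NA)
  }), case_ids)

  list(
    cases = cases,
    gene_sets = if (file.exists(fp("gene_sets.gmt")))
      read_gmt(fp("gene_sets.gmt")) else NULL,
    driver_genes = if (file.exists(fp("driver_genes.txt")))
      read_driver_list(fp("driver_genes.txt")) else NULL,
    gene_annotation = if (file.exists(fp("gene_annotation.tsv")))
      read.delim(fp("gene_annotation.tsv"), stringsAsFactors = FALSE)
      else NULL,
    truth = if (file.exists(fp("truth.json")))
      jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
      else NULL)
}

#' Write per-stage result tables and a JSON summary
#'
#' Emits one tidy TSV per analysis stage present in `results` plus a
#' machine-readable `summary.json`; absent stages are skipped. Empty
#' result tables still produce headered files.
#'
#' @param results Named list of data frames (e.g. `classes`, `ccf`,
#'   `clusters`, `enrichment`, `msi`, `scna`) plus an optional `summary`
#'   list serialized as JSON.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      paths[nm] <- write_tsv(results[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  if (!is.null(results$summary) && !is.data.frame(results$summary)) {
    jsonlite::write_json(results$summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    paths["summary"] <- file.path(dir, "summary.json")
  }
  invisible(paths)
}
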