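PHI_GRID <- seq(0.01, 1.00, by = 0.01)

# n x G matrix of binomial log-likelihoods over the prevalence grid
build_loglik_grid <- function(alt, depth, purity, q_t, m,
                              grid = PHI_GRID) {
  xi <- outer(purity * m / (purity * q_t + 2 * (1 - purity)), grid)
  xi <- pmin(pmax(xi, 1e-6), 1 - 1e-6)
  matrix(dbinom(rep(alt, length(grid)), rep(depth, length(grid)),
                as.vector(xi), log = TRUE),
         nrow = length(alt))
}

# posterior over the grid for a set of mutations assumed one cluster
grid_posterior <- function(logL_rows) {
  s <- colSums(logL_rows)
  p <- exp(s - max(s))
  p / sum(p)
}

grid_summary <- function(post, grid = PHI_GRID) {
  cdf <- cumsum(post)
  c(mean = sum(post * grid),
    lo = grid[which(cdf >= 0.025)[1]],
    hi = grid[which(cdf >= 0.975)[1]])
}

# shared driver for both clustering modes; logL is a list of matrices
run_dp_clustering <- function(logL, config, fix_alpha = NA_real_,
                              min_cluster_size = 2L) {
  n <- nrow(logL[[1]])
  fixed <- !is.na(fix_alpha)
  fit <- .dp_binom_gibbs(logL, config$n_iter, config$burn_in, config$thin,
                         if (fixed) fix_alpha else 1.0, fixed)
  co <- fit$cocluster

  # consensus assignments: average-linkage on 1 - co-clustering, cut at 0.5
  assign <- if (n == 1) 1L else {
    hc <- hclust(as.dist(1 - co), method = "average")
    cutree(hc, h = 0.5)
  }

  # convergence heuristic: trace of K should be stationary across halves
  kt <- fit$k_trace
  if (length(kt) >= 20) {
    half <- length(kt) %/% 2
    if (abs(mean(kt[seq_len(half)]) - mean(kt[-seq_len(half)])) > 1)
      warning("cluster-count trace non-stationary; interpret results with caution",
              call. = FALSE)
  }

  phi_of_cluster <- function(assign) {
    ids <- sort(unique(assign))
    do.call(rbind, lapply(ids, function(k) {
      rows <- which(assign == k)
      vapply(logL, function(M)
        grid_summary(grid_posterior(M[rows, , drop = FALSE]))[["mean"]],
        0)
    }))
  }

  # merge singleton clusters into the nearest cluster by prevalence
  sizes <- table(assign)
  while (any(sizes < min_cluster_size) && length(sizes) > 1) {
    phis <- phi_of_cluster(assign)
    ids <- sort(unique(assign))
    small <- ids[which.min(sizes)]
    others <- setdiff(ids, small)
    d <- vapply(others, function(o)
      sum((phis[match(o, ids), ] - phis[match(small, ids), ])^2), 0)
    assign[assign == small] <- others[which.min(d)]
    sizes <- table(assign)
  }
  assign <- as.integer(factor(assign, levels = sort(unique(assign))))

  lesions <- names(logL)
  ids <- sort(unique(assign))
  summ <- do.call(rbind, lapply(ids, function(k) {
    rows <- which(assign == k)
    res <- data.frame(cluster = k, n = length(rows))
    for (l in seq_along(logL)) {
      gs <- grid_summary(grid_posterior(logL[[l]][rows, , drop = FALSE]))
      res[[paste0("phi_", lesions[l])]] <- gs[["mean"]]
      res[[paste0("phi_lo_", lesions[l])]] <- gs[["lo"]]
      res[[paste0("phi_hi_", lesions[l])]] <- gs[["hi"]]
    }
    res
  }))
  # order clusters by decreasing prevalence in the first lesion
  ord <- order(-summ[[paste0("phi_", lesions[1])]])
  relabel <- match(assign, summ$cluster[ord])
  summ <- summ[ord, , drop = FALSE]
  summ$cluster <- seq_len(nrow(summ))
  rownames(summ) <- NULL

  list(clusters = summ, assignments = relabel, cocluster = co,
       k_trace = kt, alpha_last = fit$alpha_last)
}

#' Cluster mutations by cellular prevalence (one lesion)
#'
#' Dirichlet-process binomial mixture over a prevalence grid
#' (phi in 0.01..1.00 step 0.01, uniform base measure): the likelihood of a
#' mutation at prevalence phi is `Binomial(depth, xi(phi))` with
#' `xi(phi) = purity*m*phi / (purity*q_t + 2*(1-purity))`. A collapsed
#' Gibbs sampler (concentration resampled under a Gamma(1,1) prior) yields
#' the posterior pairwise co-clustering matrix; consensus clusters cut the
#' average-linkage tree of `1 - coclustering` at 0.5. Singleton clusters
#' are merged into the prevalence-nearest cluster.
#'
#' @param mutations Data frame with columns `alt`, `depth`, `q_t` and `m`.
#' @param purity Tumor purity in (0, 1].
#' @param config An [run_config()] (chain settings `n_iter`, `burn_in`,
#'   `thin`).
#' @param fix_alpha Fix the DP concentration at this value instead of
#'   resampling (used for exact-enumeration validation); `NA` resamples.
#' @param min_cluster_size Smallest reportable cluster (default 2).
#' @return List with `clusters` (id, size, `phi_x` posterior mean and 95%
#'   interval), `assignments`, `cocluster`, `k_trace`.
#' @export
cluster_one_sample <- function(mutations, purity, config = run_config(),
                               fix_alpha = NA_real_, min_cluster_size = 2L) {
  if (nrow(mutations) < 2)
    adeca_abort("cluster_one_sample: need at least 2 mutations")
  if (any(is.na(mutations$q_t)) || any(mutations$q_t < 1))
    adeca_abort("cluster_one_sample: all mutations need a defined copy state (q_t >= 1)")
  logL <- list(x = build_loglik_grid(mutations$alt, mutations$depth, purity,
                                     mutations$q_t, mutations$m))
  run_dp_clustering(logL, config, fix_alpha, min_cluster_size)
}

#' Jointly cluster lesion-common mutations across both lesions
#'
#' Same model as [cluster_one_sample()] with shared cluster assignments and
#' an independent per-lesion prevalence for every cluster; the likelihood
#' is the product of the two lesions' binomial terms.
#'
#' @param mutations Data frame with per-lesion counts `ad_alt`, `ad_depth`,
#'   `ca_alt`, `ca_depth`, and copy state `q_ad`, `q_ca`, `m_ad`, `m_ca`
#'   (columns `q_t`/`m` are recycled to both lesions if the per-lesion ones
#'   are absent).
#' @param purity Named vector `c(adenoma = ..., carcinoma = ...)`.
#' @inheritParams cluster_one_sample
#' @return As [cluster_one_sample()], with `phi_adenoma` / `phi_carcinoma`
#'   summaries per cluster.
#' @export
cluster_two_sample <- function(mutations, purity, config = run_config(),
                               fix_alpha = NA_real_, min_cluster_size = 2L) {
  if (nrow(mutations) < 2)
    adeca_abort("cluster_two_sample: need at least 2 common mutations")
  q_ad <- if ("q_ad" %in% names(mutations)) mutations$q_ad else mutations$q_t
  q_ca <- if ("q_ca" %in% names(mutations)) mutations$q_ca else mutations$q_t
  m_ad <- if ("m_ad" %in% names(mutations)) mutations$m_ad else mutations$m
  m_ca <- if ("m_ca" %in% names(mutations)) mutations$m_ca else mutations$m
  logL <- list(
    adenoma = build_loglik_grid(mutations$ad_alt, mutations$ad_depth,
                                purity[["adenoma"]], q_ad, m_ad),
    carcinoma = build_loglik_grid(mutations$ca_alt, mutations$ca_depth,
                                  purity[["carcinoma"]], q_ca, m_ca))
  run_dp_clustering(logL, config, fix_alpha, min_cluster_size)
}

#' Fitness-peak sharpness of a lesion's clonal structure
#'
#' A lesion whose mutations concentrate in few, high-prevalence clusters
#' sits on a sharper fitness peak. Sharpness is concretized as
#' `S = f_modal * phi_modal / k`, where `k` is the number of clusters,
#' `f_modal` the fraction of mutations in the largest cluster and
#' `phi_modal` that cluster's prevalence.
#'
#' @param clusters_adenoma,clusters_carcinoma Cluster summary data frames
#'   from [cluster_one_sample()] run per lesion (columns `n` and `phi_x`).
#' @param tie_margin Absolute sharpness difference below which the pair is
#'   a tie (default 0.01).
#' @return List with per-lesion `k`, `f_modal`, `phi_modal`, `S`, and
#'   `verdict` in `carcinoma_sharper` / `adenoma_sharper` / `tie`.
#' @export
sharpness <- function(clusters_adenoma, clusters_carcinoma,
                      tie_margin = 0.01) {
  one <- function(cl) {
    k <- nrow(cl)
    modal <- which.max(cl$n + 1e-9 * cl$phi_x)  # ties to higher prevalence
    f <- cl$n[modal] / sum(cl$n)
    phi <- cl$phi_x[modal]
    list(k = k, f_modal = f, phi_modal = phi, S = f * phi / k)
  }
  ad <- one(clusters_adenoma)
  ca <- one(clusters_carcinoma)
  dS <- ca$S - ad$S
  verdict <- if (abs(dS) < tie_margin) "tie"
             else if (dS > 0) "carcinoma_sharper" else "adenoma_sharper"
  list(adenoma = ad, carcinoma = ca, delta_S = dS, verdict = verdict)
}
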