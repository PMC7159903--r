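# Binomial-CDF biogeographic enrichment between two site groups.

#' Exact lower-tail binomial CDF
#'
#' `P(X <= k)` for `X ~ Binomial(n, p)`, inclusive of `k`. This is the
#' biogeographic enrichment score: for a gene cluster found in `n` MAGs of
#' which `k` come from site 1, a small value means the cluster is seen at
#' site 1 far less often than the site-1 share `p` of the MAG collection
#' predicts (site-2 enrichment), and a value near 1 means the opposite.
#'
#' @param k number of site-1 MAGs containing the cluster (vectorized).
#' @param n total number of MAGs containing the cluster.
#' @param p expected site-1 proportion, strictly in (0, 1).
#' @return lower-tail probabilities in (0, 1].
#' @examples
#' binom_cdf(0, 7, 13/22)  # 0.00191752
#' @export
binom_cdf <- function(k, n, p) {
  if (any(n < 0) || any(k < 0) || any(k > n)) {
    pg_domain_error("require integers 0 <= k <= n")
  }
  if (any(k != floor(k)) || any(n != floor(n))) {
    pg_domain_error("k and n must be integers")
  }
  if (any(p <= 0) || any(p >= 1)) {
    pg_domain_error("p must lie strictly in (0, 1)")
  }
  pbinom(k, n, p)
}

#' Score gene clusters for biogeographic enrichment
#'
#' Tallies, for each cluster, the MAGs containing it (`N`) and how many of
#' those are from site 1 (`k`), then scores the cluster with the inclusive
#' lower-tail binomial CDF at the expected site-1 proportion `p`. To avoid
#' bias from low-frequency clusters, only clusters found in at least
#' `min_site2_mags` site-2 MAGs or at least `min_site1_mags` site-1 MAGs
#' are scored (defaults 7 and 12). Calls: `cdf < cdf_lo` = site-2 enriched,
#' `cdf > cdf_hi` = site-1 enriched.
#'
#' @param mat a [build_matrix()] result.
#' @param site_labels named character vector bin_id -> site label.
#' @param config a [pipeline_config()]; `config$p = NULL` computes p as the
#'   site-1 share of the bins.
#' @return a data.table (class `pg_biogeo`) with one row per scored
#'   cluster: `cluster_id`, `N`, `k`, `p`, `cdf` (8 decimals in the TSV
#'   output), `call`; attribute `n_excluded` counts filtered clusters.
#' @export
score_clusters <- function(mat, site_labels, config = pipeline_config()) {
  sites <- site_labels[colnames(mat)]
  if (anyNA(sites)) {
    pg_integrity_error("bins without site label",
                       ids = colnames(mat)[is.na(sites)])
  }
  extra <- setdiff(unique(sites), c(config$site1, config$site2))
  if (length(extra)) {
    pg_config_error(sprintf("unknown site label(s): %s",
                            paste(extra, collapse = ", ")))
  }
  is1 <- sites == config$site1
  n1 <- sum(is1); n2 <- sum(!is1)
  if (n1 == 0L || n2 == 0L) pg_config_error("both site groups must be present")
  p <- config$p %||% (n1 / (n1 + n2))
  if (p <= 0 || p >= 1) pg_config_error("p must lie strictly in (0, 1)")

  k <- as.integer(mat %*% is1)
  N <- as.integer(cluster_frequency(mat))
  k2 <- N - k
  keep <- (k2 >= config$min_site2_mags) | (k >= config$min_site1_mags)
  res <- data.table(
    cluster_id = rownames(mat)[keep],
    N = N[keep], k = k[keep], p = p,
    cdf = binom_cdf(k[keep], N[keep], p)
  )
  res[, call := ifelse(cdf < config$cdf_lo, paste0(config$site2, "-enriched"),
                ifelse(cdf > config$cdf_hi, paste0(config$site1, "-enriched"),
                       "none"))]
  structure(res, n_excluded = sum(!keep), p = p,
            class = c("pg_biogeo", class(res)))
}

#' Compare CDF scores of one COG category against all other scored clusters
#'
#' Welch two-sample two-sided t-test of the binomial CDF values of scored
#' clusters annotated with `category` versus all remaining scored clusters.
#' A one-sample alternative (`against = "half"`) tests the category mean
#' against the neutral value 0.5.
#'
#' @param scores a [score_clusters()] result.
#' @param annotations data.table with `cluster_id`, `cog_category`.
#' @param category COG category letter.
#' @param against `"complement"` (default, two-sample) or `"half"`
#'   (one-sample against mu = 0.5).
#' @return list with `t`, `p_value`, `mean_category`, `mean_other`,
#'   `n_category`, `n_other`.
#' @export
category_cdf_ttest <- function(scores, annotations, category,
                               against = c("complement", "half")) {
  against <- match.arg(against)
  ann <- as.data.table(annotations)
  in_cat <- unique(ann[cog_category == category, cluster_id])
  x <- scores$cdf[scores$cluster_id %in% in_cat]
  y <- scores$cdf[!scores$cluster_id %in% in_cat]
  if (length(x) < 2L) {
    pg_domain_error(sprintf(
      "category '%s' has %d scored cluster(s); need >= 2", category, length(x)))
  }
  if (against == "half") {
    tt <- t.test(x, mu = 0.5)
    return(list(t = unname(tt$statistic), p_value = tt$p.value,
                mean_category = mean(x), mean_other = 0.5,
                n_category = length(x), n_other = 0L))
  }
  if (length(y) < 2L) {
    pg_domain_error("complement has fewer than 2 scored clusters")
  }
  if (identical(sort(x), sort(y)) ||
      (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))) {
    return(list(t = 0, p_value = 1, mean_category = mean(x),
                mean_other = mean(y), n_category = length(x),
                n_other = length(y)))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_category = mean(x), mean_other = mean(y),
       n_category = length(x), n_other = length(y))
}

#' Optional Benjamini-Hochberg adjustment of two-sided fold P values
#'
#' The raw CDF cutoffs are the primary interface (no multiplicity
#' correction, matching the scoring design); this helper adds a BH-adjusted
#' column over the folded two-sided P `2 * min(cdf, 1 - cdf + P(X = k))`
#' for users who want one.
#'
#' @param scores a [score_clusters()] result.
#' @return the scores with `p_two_sided` and `bh_fdr` columns appended.
#' @export
biogeo_bh <- function(scores) {
  upper <- 1 - scores$cdf +
    stats::dbinom(scores$k, scores$N, scores$p)
  p2 <- pmin(1, 2 * pmin(scores$cdf, upper))
  out <- copy(as.data.table(scores))
  out[, `:=`(p_two_sided = p2, bh_fdr = stats::p.adjust(p2, "BH"))]
  out
}
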