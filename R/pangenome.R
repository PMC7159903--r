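# Pangenome structure: presence/absence matrix, frequency spectrum,
# containment, genome clustering, rarefaction, and the completeness-aware
# core posterior.

#' Build the gene-cluster presence/absence matrix
#'
#' Occupancy is `TRUE` when a bin carries at least one gene call of the
#' cluster; paralogous duplicates collapse to a single presence. All bins of
#' the dataset appear as columns (even if empty); rows are the observed
#' clusters, ordered lexicographically.
#'
#' @param ds a [pg_dataset()].
#' @return a `pg_matrix`: logical matrix (clusters x bins) with attribute
#'   `frequency` (per-cluster count of containing bins).
#' @export
build_matrix <- function(ds) {
  stopifnot(inherits(ds, "pg_dataset"))
  bins <- sort(ds$bins$bin_id)
  cl <- sort(unique(ds$gene_calls$cluster_id))
  m <- matrix(FALSE, nrow = length(cl), ncol = length(bins),
              dimnames = list(cl, bins))
  if (nrow(ds$gene_calls)) {
    m[cbind(match(ds$gene_calls$cluster_id, cl),
            match(ds$gene_calls$bin_id, bins))] <- TRUE
  }
  structure(m, frequency = rowSums(m), class = c("pg_matrix", class(m)))
}

#' @export
print.pg_matrix <- function(x, ...) {
  cat(sprintf("<pg_matrix> %d clusters x %d bins; core (freq = M): %d\n",
              nrow(x), ncol(x), sum(attr(x, "frequency") == ncol(x))))
  invisible(x)
}

cluster_frequency <- function(mat) {
  attr(mat, "frequency") %||% rowSums(mat)
}

#' Cluster frequency spectrum
#'
#' Counts of clusters per frequency 1..M (number of bins containing the
#' cluster); sums to the total cluster count.
#'
#' @param mat a [build_matrix()] result.
#' @return data.table with columns `frequency` and `n_clusters`.
#' @export
frequency_spectrum <- function(mat) {
  M <- ncol(mat)
  f <- cluster_frequency(mat)
  data.table(frequency = seq_len(M),
             n_clusters = tabulate(f, nbins = M))
}

#' Asymmetric gene-content containment between bins
#'
#' `C[A, B]` is the fraction of A's clusters also present in B. The matrix
#' is asymmetric when genomes differ in gene-cluster count, which is the
#' point of the statistic: a small genome can be fully contained in a large
#' one without the converse.
#'
#' @param mat a [build_matrix()] result.
#' @return numeric M x M matrix with unit diagonal.
#' @export
containment <- function(mat) {
  sizes <- colSums(mat)
  if (any(sizes == 0)) {
    pg_integrity_error(
      sprintf("bins with zero clusters have undefined containment: %s",
              paste(colnames(mat)[sizes == 0], collapse = ", ")),
      ids = colnames(mat)[sizes == 0])
  }
  inter <- crossprod(mat * 1L)  # |clusters(A) intersect clusters(B)|
  C <- inter / sizes            # divide each row A by |clusters(A)|
  dimnames(C) <- list(colnames(mat), colnames(mat))
  C
}

#' Hierarchical clustering of genomes on gene-content distance
#'
#' Symmetrizes containment into the distance
#' `d(A, B) = 1 - (C[A,B] + C[B,A]) / 2` and applies average-linkage
#' agglomeration. Bins are ordered lexicographically before clustering so
#' ties break deterministically.
#'
#' @param C containment matrix from [containment()].
#' @return an [stats::hclust] object.
#' @export
cluster_genomes <- function(C) {
  if (nrow(C) < 2L) pg_domain_error("need at least 2 bins to cluster")
  ord <- order(rownames(C))
  C <- C[ord, ord]
  d <- 1 - (C + t(C)) / 2
  hclust(as.dist(d), method = "average")
}

#' Export a genome dendrogram to Newick
#'
#' @param hc an [stats::hclust] from [cluster_genomes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Pangenome rarefaction (accumulation and core-decay curves)
#'
#' For each of `n_perm` random orderings of the bins, tracks the cumulative
#' union (total clusters) and intersection (core clusters) after observing
#' 1..M bins, and averages over orderings. An ever-growing total curve is
#' the operational signature of an open pangenome.
#'
#' @param mat a [build_matrix()] result.
#' @param n_perm number of random orderings (>= 1); when `M!` does not
#'   exceed `n_perm`, all orderings are enumerated and the means are exact.
#' @param seed integer seed (unused in the exhaustive regime).
#' @return data.table with `n_bins`, `mean_total`, `mean_core`.
#' @export
rarefaction <- function(mat, n_perm = 100L, seed = 1L) {
  if (n_perm < 1L) pg_domain_error("n_perm must be >= 1")
  M <- ncol(mat)
  exhaustive <- factorial(M) <= n_perm
  ords <- if (exhaustive) all_permutations(M)
  if (exhaustive) n_perm <- length(ords)
  set.seed(seed)
  tot <- core <- matrix(0, n_perm, M)
  for (i in seq_len(n_perm)) {
    ord <- if (exhaustive) ords[[i]] else sample.int(M)
    cum_u <- rep(FALSE, nrow(mat))
    cum_i <- rep(TRUE, nrow(mat))
    for (j in seq_len(M)) {
      col <- mat[, ord[j]]
      cum_u <- cum_u | col
      cum_i <- cum_i & col
      tot[i, j] <- sum(cum_u)
      core[i, j] <- sum(cum_i)
    }
  }
  data.table(n_bins = seq_len(M),
             mean_total = colMeans(tot),
             mean_core = colMeans(core))
}

#' Completeness-aware posterior probability of core membership
#'
#' A cluster observed in `n_obs` of `M` incomplete MAGs may still be core:
#' each MAG detects a truly present gene only with probability equal to its
#' completeness. The posterior P(truly present in all M | observed in n_obs)
#' is estimated by Monte Carlo: draw a true presence count t from the prior
#' (flat over 1..M by default), a uniformly random subset of that size, and
#' Bernoulli detection per member; condition on the observed count.
#'
#' @param n_obs observed frequency (scalar or vector, each in 0..M).
#' @param completeness numeric vector of per-MAG detection probabilities in
#'   (0, 1].
#' @param prior `"flat"` (uniform over true counts 1..M) or `"all_core"`
#'   (t = M with probability 1; useful for calibration checks).
#' @param n_sims Monte Carlo draws.
#' @param seed integer seed.
#' @return data.table with `n_obs`, `posterior`, `mc_se` (binomial standard
#'   error), `n_matching` (simulations with that observed count; posterior
#'   is `NA` when zero), and the prior tag.
#' @export
core_posterior <- function(n_obs, completeness, prior = c("flat", "all_core"),
                           n_sims = 100000L, seed = 1L) {
  prior <- match.arg(prior)
  M <- length(completeness)
  if (any(completeness <= 0 | completeness > 1)) {
    pg_domain_error("completeness values must lie in (0, 1]")
  }
  if (any(n_obs < 0 | n_obs > M)) {
    pg_domain_error("n_obs must lie in 0..M")
  }
  set.seed(seed)
  t_draw <- if (prior == "flat") sample.int(M, n_sims, replace = TRUE)
            else rep(M, n_sims)
  # membership: for each sim, a uniform random subset of size t
  u <- matrix(runif(n_sims * M), n_sims, M)
  rk <- t(apply(u, 1L, rank, ties.method = "first"))
  member <- rk <= t_draw
  det <- member & (matrix(runif(n_sims * M), n_sims, M) <
                     matrix(completeness, n_sims, M, byrow = TRUE))
  obs_count <- rowSums(det)
  res <- lapply(n_obs, function(n0) {
    sel <- obs_count == n0
    n_match <- sum(sel)
    if (n_match == 0L) {
      return(data.table(n_obs = n0, posterior = NA_real_, mc_se = NA_real_,
                        n_matching = 0L, prior = prior))
    }
    p <- mean(t_draw[sel] == M)
    data.table(n_obs = n0, posterior = p,
               mc_se = sqrt(p * (1 - p) / n_match),
               n_matching = n_match, prior = prior)
  })
  rbindlist(res)
}
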