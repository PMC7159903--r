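# COG-category composition across gene frequency, with a permutation null.

.COG_LETTERS <- c(LETTERS, "N/A")

#' COG-category profile by gene frequency
#'
#' For each (category, frequency) pair, the number of clusters at that
#' frequency carrying the category and its proportion among all clusters at
#' that frequency. Clusters with several annotations contribute to each of
#' their categories, so proportions at a frequency may sum to more than 1;
#' unannotated clusters are carried as category `"N/A"`.
#'
#' @param mat a [build_matrix()] result.
#' @param annotations data.table with `cluster_id`, `cog_category` (one row
#'   per annotation); clusters absent from it are treated as `"N/A"`.
#' @return a `pg_category_profile`: data.table with `cog_category`,
#'   `frequency`, `count`, `proportion`, plus attributes `freq_totals` and
#'   `cluster_cats` (per-cluster category list used by the permutation null).
#' @export
category_profile <- function(mat, annotations) {
  ann <- as.data.table(annotations)
  check_columns(ann, "annotations", c("cluster_id", "cog_category"))
  bad <- setdiff(unique(ann$cog_category), .COG_LETTERS)
  if (length(bad)) {
    pg_format_error(sprintf("unknown COG category letter(s): %s",
                            paste(bad, collapse = ", ")),
                    column = "cog_category")
  }
  f <- cluster_frequency(mat)
  cl <- rownames(mat)
  cats <- split(ann$cog_category, factor(ann$cluster_id, levels = cl))
  cats <- lapply(cats, unique)
  cats[lengths(cats) == 0L] <- list("N/A")
  M <- ncol(mat)
  freq_totals <- tabulate(f, nbins = M)
  long <- data.table(cog_category = unlist(cats, use.names = FALSE),
                     frequency = rep(f, lengths(cats)))
  prof <- long[, .(count = .N), by = .(cog_category, frequency)]
  prof[, proportion := count / freq_totals[frequency]]
  setorder(prof, cog_category, frequency)
  structure(prof, freq_totals = freq_totals, cluster_cats = cats,
            cluster_freq = f, M = M,
            class = c("pg_category_profile", class(prof)))
}

# counts matrix (category x frequency) given a frequency vector and the
# fixed per-cluster category sets
profile_counts <- function(cats_idx, n_cat, f, M) {
  m <- matrix(0L, n_cat, M)
  tab <- tabulate((rep(f, lengths(cats_idx$per_cluster)) - 1L) * n_cat +
                    cats_idx$flat, nbins = n_cat * M)
  m[] <- tab
  m
}

#' Permutation enrichment of COG categories by frequency
#'
#' Null model: category label-sets are shuffled across clusters while each
#' cluster keeps its frequency, so marginal category abundances and the
#' frequency spectrum are both preserved. The one-sided empirical P for a
#' (category, frequency) cell is
#' `(1 + #permutations with count >= observed) / (n_perm + 1)`: small values
#' flag over-representation, values near 1 under-representation.
#'
#' When the number of clusters is small enough that all `n!` permutations
#' fit within `n_perm`, the null is enumerated exhaustively and the P value
#' is the exact permutation probability `#{count >= observed} / n!` (the
#' identity permutation is part of the enumeration, so no add-one
#' correction applies).
#'
#' @param profile a [category_profile()] result.
#' @param n_perm number of permutations (>= 99, except that the exhaustive
#'   regime accepts any positive bound covering `n!`).
#' @param seed integer seed (unused in the exhaustive regime).
#' @return a `pg_enrichment`: data.table `cog_category`, `frequency`,
#'   `observed`, `p_value`, with `n_perm` and `seed` attributes.
#' @export
permutation_enrichment <- function(profile, n_perm = 999L, seed = 1L) {
  cats <- attr(profile, "cluster_cats")
  f <- attr(profile, "cluster_freq")
  M <- attr(profile, "M")
  n <- length(f)
  exhaustive <- factorial(n) <= n_perm
  if (!exhaustive && n_perm < 99L) pg_domain_error("n_perm must be >= 99")
  levs <- sort(unique(unlist(cats, use.names = FALSE)))
  n_cat <- length(levs)
  per_cluster <- lapply(cats, function(x) match(x, levs))
  flat <- unlist(per_cluster, use.names = FALSE)
  lens <- lengths(per_cluster)
  obs <- profile_counts(list(per_cluster = per_cluster, flat = flat),
                        n_cat, f, M)
  ords <- if (exhaustive) all_permutations(n)
  n_draw <- if (exhaustive) length(ords) else n_perm
  set.seed(seed)
  ge <- matrix(0L, n_cat, M)
  for (b in seq_len(n_draw)) {
    fp <- f[if (exhaustive) ords[[b]] else sample.int(n)]
    cnt <- matrix(tabulate((rep(fp, lens) - 1L) * n_cat + flat,
                           nbins = n_cat * M), n_cat, M)
    ge <- ge + (cnt >= obs)
  }
  p <- if (exhaustive) ge / n_draw else (1 + ge) / (n_perm + 1)
  out <- data.table(
    cog_category = rep(levs, M),
    frequency = rep(seq_len(M), each = n_cat),
    observed = as.integer(obs),
    p_value = as.numeric(p)
  )
  structure(out, n_perm = n_draw, seed = seed, exhaustive = exhaustive,
            null_model = "category labels permuted, frequencies fixed",
            class = c("pg_enrichment", class(out)))
}

#' Hierarchical clustering of categories on their enrichment profiles
#'
#' Average-linkage clustering of categories using Euclidean distance
#' between their vectors of permutation P values across frequencies.
#'
#' @param enrichment a [permutation_enrichment()] result.
#' @return an [stats::hclust] object.
#' @export
category_cluster_dendrogram <- function(enrichment) {
  wide <- data.table::dcast(as.data.table(enrichment),
                            cog_category ~ frequency, value.var = "p_value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$cog_category
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2L) pg_domain_error("need at least 2 categories to cluster")
  hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Compare a category's proportions between two frequency bands
#'
#' Welch two-sample t-test of the per-frequency proportions of one category
#' between two disjoint frequency bands (e.g., frequencies < 15 vs >= 15).
#' Frequencies with no clusters at all are dropped from both bands.
#'
#' @param profile a [category_profile()] result.
#' @param band_a,band_b disjoint integer vectors of frequencies.
#' @param category category letter (or `"N/A"`).
#' @return list with `t`, `p_value`, `mean_a`, `mean_b`, `df`.
#' @export
frequency_band_test <- function(profile, band_a, band_b, category) {
  if (length(intersect(band_a, band_b))) {
    pg_domain_error("frequency bands must be disjoint")
  }
  totals <- attr(profile, "freq_totals")
  props <- function(band) {
    band <- band[band >= 1 & band <= length(totals) & totals[band] > 0]
    if (length(band) < 2L) {
      pg_domain_error("each band needs >= 2 represented frequencies")
    }
    pr <- as.data.table(profile)[cog_category == category]
    x <- setNames(pr$proportion, pr$frequency)[as.character(band)]
    ifelse(is.na(x), 0, x)  # frequencies where the category is absent
  }
  a <- props(band_a); b <- props(band_b)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, p_value = 1, mean_a = mean(a), mean_b = mean(b),
                df = length(a) + length(b) - 2))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), df = unname(tt$parameter))
}
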