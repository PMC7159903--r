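make_profile <- function(categories, freqs, M = max(freqs)) {
  # categories: list per cluster (character vectors); freqs: int per cluster
  n <- length(freqs)
  ids <- sprintf("c%04d", seq_len(n))
  m <- matrix_from_freqs(freqs, M, cluster_ids = ids)
  ann <- data.table::data.table(
    cluster_id = rep(ids, lengths(categories)),
    cog_category = unlist(categories))
  ann <- ann[ann$cog_category != "N/A", ]
  category_profile(m, ann)
}

test_that("category_profile counts and proportions are correct", {
  set.seed(1)
  # 10 clusters all category J at one frequency
  p1 <- make_profile(rep(list("J"), 10), rep(3L, 10), M = 3)
  p1 <- as.data.frame(p1)
  expect_equal(p1$proportion[p1$cog_category == "J" & p1$frequency == 3], 1)

  # 4 singleton clusters {M, M, T, N/A}
  p2 <- make_profile(list("M", "M", "T", "N/A"), rep(1L, 4), M = 2)
  p2 <- as.data.frame(p2)
  expect_equal(p2$proportion[p2$cog_category == "M" & p2$frequency == 1], 0.5)
  expect_equal(p2$count[p2$cog_category == "N/A" & p2$frequency == 1], 1L)

  # a cluster annotated {E, P} contributes to both categories
  p3 <- make_profile(list(c("E", "P"), "E"), c(2L, 2L), M = 2)
  p3 <- as.data.frame(p3)
  expect_equal(p3$count[p3$cog_category == "E" & p3$frequency == 2], 2L)
  expect_equal(p3$count[p3$cog_category == "P" & p3$frequency == 2], 1L)
  # proportions at that frequency sum above 1 under multi-annotation
  expect_gt(sum(p3$proportion[p3$frequency == 2]), 1)

  # unknown letters are rejected with the letters named
  m <- matrix_from_freqs(c(1L, 2L), 2)
  ann <- data.table::data.table(cluster_id = rownames(m),
                                cog_category = c("J", "ZZ"))
  err <- expect_error(category_profile(m, ann),
                      class = "pangevo_format_error")
  expect_match(conditionMessage(err), "ZZ")

  # input order invariance
  set.seed(2)
  f <- sample(1:4, 50, replace = TRUE)
  cats <- replicate(50, sample(c("J", "K", "L"), 1), simplify = FALSE)
  pa <- make_profile(cats, f, M = 4)
  ord <- sample.int(50)
  m_b <- matrix_from_freqs(f, 4)  # same freqs, same ids by construction
  pb <- make_profile(cats[ord], f[ord], M = 4)
  expect_equal(as.data.frame(pa)[order(pa$cog_category, pa$frequency),
                                 c("cog_category", "frequency", "count")],
               as.data.frame(pb)[order(pb$cog_category, pb$frequency),
                                 c("cog_category", "frequency", "count")],
               ignore_attr = TRUE)
})

test_that("permutation enrichment: degenerate and exhaustive cases", {
  set.seed(3)
  # a single category everywhere: permutation cannot change any count
  p <- make_profile(rep(list("J"), 8), sample(1:3, 8, replace = TRUE), M = 3)
  e <- permutation_enrichment(p, n_perm = 99L, seed = 1L)
  expect_true(all(e$p_value == 1))

  # 3 clusters, 2 categories: exhaustive enumeration equals the exact
  # permutation probability computed by hand over all 3! orderings
  p3 <- make_profile(list("J", "J", "K"), c(1L, 1L, 2L), M = 2)
  e3 <- as.data.frame(permutation_enrichment(p3, n_perm = 10L, seed = 1L))
  expect_true(attr(permutation_enrichment(p3, n_perm = 10L), "exhaustive"))
  # cell (J, freq 1): observed 2. Over the 6 permutations of labels
  # (J,J,K), counts of J at freq 1 are 2 when K sits at freq 2 (2 perms)
  # and 1 otherwise (4 perms) -> P(count >= 2) = 2/6
  expect_equal(e3$p_value[e3$cog_category == "J" & e3$frequency == 1], 2 / 6)
  # cell (K, freq 2): observed 1; counts are 1 (2 perms) or 0 (4 perms)
  expect_equal(e3$p_value[e3$cog_category == "K" & e3$frequency == 2], 2 / 6)
  # cell (K, freq 1): observed 0 -> all permutations tie or exceed
  expect_equal(e3$p_value[e3$cog_category == "K" & e3$frequency == 1], 1)

  # Monte Carlo agrees with the exhaustive probabilities
  e_mc <- as.data.frame(permutation_enrichment(p3, n_perm = 4999L, seed = 2L))
  expect_equal(e_mc$p_value[e_mc$cog_category == "J" & e_mc$frequency == 1],
               2 / 6, tolerance = 0.05)
})

test_that("an implanted low-frequency category is detected with power", {
  set.seed(4)
  n <- 2000L
  f <- sample(1:22, n, replace = TRUE,
              prob = c(6, rep(1, 20), 4) / 30)   # U-ish spectrum
  base <- c("J", "K", "L", "M", "S")
  cats <- sample(base, n, replace = TRUE)
  # implant: 3x over-representation of M among singletons
  single <- which(f == 1L)
  boost <- sample(single, round(length(single) * 0.4))
  cats[boost] <- "M"
  prof <- make_profile(as.list(cats), f, M = 22)
  e <- as.data.frame(permutation_enrichment(prof, n_perm = 9999L, seed = 5L))
  expect_lt(e$p_value[e$cog_category == "M" & e$frequency == 1], 0.01)
})

test_that("permutation P values are uniform under a random assignment", {
  set.seed(6)
  # ~16 clusters per (category, frequency) cell: enough spread in the count
  # statistic that tie-induced conservativeness stays negligible
  ps <- replicate(200, {
    n <- 400L
    f <- sample.int(5L, n, replace = TRUE)
    cats <- sample(c("J", "K", "L", "M", "S"), n, replace = TRUE)
    prof <- make_profile(as.list(cats), f, M = 5)
    e <- as.data.frame(permutation_enrichment(
      prof, n_perm = 999L, seed = sample.int(1e6, 1L)))
    e$p_value[e$cog_category == "J" & e$frequency == 3]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("category dendrogram clusters identical profiles first", {
  # build an enrichment table directly
  mk <- function(tab) {
    structure(data.table::as.data.table(tab),
              class = c("pg_enrichment", class(data.table::data.table())))
  }
  e <- mk(expand.grid(cog_category = c("A", "B", "C"),
                      frequency = 1:3, stringsAsFactors = FALSE))
  e$observed <- 0L
  # profiles: A = (0.5, 0.4, 0.6), C = (0.6, 0.6, 0.6), B orthogonal
  e$p_value <- c(0.5, 0.99, 0.6, 0.4, 0.99, 0.6, 0.6, 0.99, 0.6)
  hc <- category_cluster_dendrogram(e)
  expect_equal(hc$height[1], sqrt(sum(c(0.1, 0.2, 0)^2)), tolerance = 1e-12)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("A", "C"))  # B is the orthogonal profile
  # merge heights from the oracle
  m <- matrix(e$p_value, nrow = 3,
              dimnames = list(c("A", "B", "C"), NULL))
  d <- as.matrix(stats::dist(m))
  oracle <- oracle_upgma_cophenetic(d)
  coph <- as.matrix(stats::cophenetic(hc))
  expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-12)
  # permuting category order preserves topology
  e2 <- e[c(2, 3, 1, 5, 6, 4, 8, 9, 7)]
  hc2 <- category_cluster_dendrogram(mk(e2))
  coph2 <- as.matrix(stats::cophenetic(hc2))
  expect_equal(coph2[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-12)
})

test_that("frequency band tests match the closed-form Welch computation", {
  set.seed(7)
  # identical proportions in both bands
  p <- make_profile(rep(list("J"), 12), rep(1:6, each = 2), M = 6)
  r <- frequency_band_test(p, 1:3, 4:6, "J")
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  # a constructed profile with proportions 0.1 vs 0.3 (+ tiny jitter)
  prof <- structure(
    data.table::data.table(
      cog_category = "J", frequency = 1:6,
      count = c(1, 1, 1, 3, 3, 3),
      proportion = c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3) +
        c(1, -1, 0, 1, -1, 0) * 1e-6),
    freq_totals = rep(10L, 6), M = 6L,
    class = c("pg_category_profile", "data.table", "data.frame"))
  r2 <- frequency_band_test(prof, 1:3, 4:6, "J")
  o <- oracle_welch(c(0.1 + 1e-6, 0.1 - 1e-6, 0.1),
                    c(0.3 + 1e-6, 0.3 - 1e-6, 0.3))
  expect_equal(r2$t, o$t, tolerance = 1e-10)
  expect_equal(r2$p_value, o$p, tolerance = 1e-10)
  expect_lt(r2$p_value, 0.001)

  # swapping bands negates t, preserves P
  r3 <- frequency_band_test(prof, 4:6, 1:3, "J")
  expect_equal(r3$t, -r2$t, tolerance = 1e-12)
  expect_equal(r3$p_value, r2$p_value, tolerance = 1e-12)

  expect_error(frequency_band_test(prof, 1:3, 3:6, "J"),
               class = "pangevo_domain_error")
  expect_error(frequency_band_test(prof, 1, 2:6, "J"),
               class = "pangevo_domain_error")
})
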