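make_snv_ds <- function(contig_lens, counts, bin_id = "B1",
                        coverage = 50, n_bins = 1L) {
  # counts: SNVs per contig, placed at distinct positions
  nb <- max(n_bins, 1L)
  bins <- data.table::data.table(
    bin_id = sprintf("B%d", seq_len(nb)), site = "Axial",
    completeness = 0.9, redundancy = 0.01, total_length_bp = 0L)
  contigs <- data.table::data.table(
    contig_id = sprintf("%s_c%03d", bin_id, seq_along(contig_lens)),
    bin_id = bin_id, length_bp = as.integer(contig_lens),
    mean_coverage = coverage)
  bins <- bins[bins$bin_id %in% unique(contigs$bin_id), ]
  bins$total_length_bp <- sum(contig_lens)
  snvs <- data.table::data.table(
    contig_id = rep(contigs$contig_id, counts),
    pos0 = unlist(lapply(seq_along(counts), function(i)
      seq_len(counts[i]) - 1L), use.names = FALSE),
    ref = "A", alt = "C")
  if (nrow(snvs) == 0L) snvs <- snvs[0]
  gene_calls <- data.table::data.table(
    gene_id = paste0(contigs$contig_id, "_g1"),
    bin_id = contigs$bin_id, contig_id = contigs$contig_id,
    start0 = 0L, stop0 = 300L, strand = "+",
    cluster_id = sprintf("GC_%03d", seq_along(contig_lens)))
  clusters <- data.table::data.table(
    cluster_id = unique(gene_calls$cluster_id),
    cog_function = "x", cog_category = "J")
  pg_dataset(bins, contigs, gene_calls, clusters, snvs = snvs)
}

test_that("snv_density is SNVs per kbp with integrity checking", {
  ds0 <- make_snv_ds(c(2000, 3000), c(0L, 0L))
  expect_equal(snv_density(ds0$snvs, ds0$contigs)$density_per_kbp, 0)

  ds1 <- make_snv_ds(c(750000, 750000), c(100L, 50L))
  d1 <- snv_density(ds1$snvs, ds1$contigs)
  expect_equal(d1$density_per_kbp, 0.1)     # 150 SNVs over 1.5 Mbp

  ds2 <- make_snv_ds(c(1000000), c(2000L))
  expect_equal(snv_density(ds2$snvs, ds2$contigs)$density_per_kbp, 2.0)

  bad <- data.table::copy(ds1$snvs)
  bad[1, contig_id := "ghost"]
  expect_error(snv_density(bad, ds1$contigs),
               class = "pangevo_integrity_error")
})

test_that("contig_sweep_test matches the Poisson closed forms and oracle", {
  expect_equal(contig_sweep_test(0, 1000, 0, 1e6)$p_value, 1)
  r1 <- contig_sweep_test(0, 1000, 1000, 1e6)
  expect_equal(r1$n_c, 1)
  expect_equal(r1$p_value, exp(-1), tolerance = 1e-12)
  r2 <- contig_sweep_test(0, 1000, 10000, 1e6)
  expect_equal(r2$n_c, 10)
  expect_equal(r2$p_value, exp(-10), tolerance = 1e-12)
  expect_error(contig_sweep_test(0, 2e6, 10, 1e6),
               class = "pangevo_domain_error")
  expect_error(contig_sweep_test(-1, 10, 10, 100),
               class = "pangevo_domain_error")

  # oracle equivalence over the stated grid
  set.seed(31)
  for (i in 1:400) {
    n_c <- runif(1, 0, 50)
    x <- sample(0:200, 1)
    # l_c/L chosen so the expected count equals n_c
    expect_lt(abs(contig_sweep_test(x, n_c, 50, 50)$p_value -
                    oracle_ppois(x, n_c)), 1e-12)
  }
})

test_that("expected counts are conserved within bins", {
  sim <- shared_sim()
  cs <- contig_sweeps(sim$dataset)
  agg <- cs[, .(sum_nc = sum(n_c), sum_x = sum(x), N = N[1]), by = bin_id]
  expect_equal(agg$sum_nc, as.numeric(agg$N), tolerance = 1e-9)
  expect_equal(agg$sum_x, agg$N)
  expect_true(all(cs$p_value > 0 & cs$p_value <= 1))
})

test_that("gene P values are inherited, flagged, and audited", {
  # two genes on one contig share its P value; large n_c deficit flags
  ds <- make_snv_ds(c(30000, 970000), c(0L, 30000L))
  cs <- contig_sweeps(ds)
  gc2 <- rbind(ds$gene_calls,
               data.table::data.table(
                 gene_id = "B1_c001_g2", bin_id = "B1",
                 contig_id = "B1_c001", start0 = 400L, stop0 = 700L,
                 strand = "+", cluster_id = "GC_900"))
  gp <- gene_sweep_pvalues(cs, gc2, ds$contigs)
  on_c1 <- gp[gp$contig_id == "B1_c001", ]
  expect_equal(nrow(on_c1), 2L)
  expect_equal(on_c1$p_value[1], on_c1$p_value[2])
  # n_c = 30000 * 30000/1e6 = 900 on an SNV-free contig
  expect_true(all(on_c1$flagged))
  expect_true(all(on_c1$snv_free))

  # closed form e^-30 < 1e-10
  ds30 <- make_snv_ds(c(30000, 970000), c(0L, 1000L))
  cs30 <- contig_sweeps(ds30)
  expect_equal(cs30$n_c[cs30$contig_id == "B1_c001"], 30)
  gp30 <- gene_sweep_pvalues(cs30, ds30$gene_calls, ds30$contigs)
  expect_equal(gp30$p_value[gp30$contig_id == "B1_c001"], exp(-30),
               tolerance = 1e-9)
  expect_true(gp30$flagged[gp30$contig_id == "B1_c001"])

  # x = n_c (large): P near 0.5 by the Poisson median property
  ds_med <- make_snv_ds(c(100000, 900000), c(100L, 900L))
  cs_med <- contig_sweeps(ds_med)
  p_med <- cs_med$p_value[cs_med$contig_id == "B1_c001"]
  expect_lt(abs(p_med - 0.5), 0.2)
  expect_false(p_med < 1e-10)

  # orphan gene
  gc_orphan <- data.table::copy(ds$gene_calls)
  gc_orphan[1, contig_id := "ghost"]
  expect_error(gene_sweep_pvalues(cs, gc_orphan, ds$contigs),
               class = "pangevo_integrity_error")
})

test_that("sweep summaries by frequency capture the recovery structure", {
  # all P = 1: all proportions zero
  ds <- make_snv_ds(c(5000, 5000), c(0L, 0L))
  cs <- contig_sweeps(ds)
  gp <- gene_sweep_pvalues(cs, ds$gene_calls, ds$contigs)
  m <- matrix_from_sets(list(B1 = unique(ds$gene_calls$cluster_id)))
  ss <- sweep_summary_by_frequency(gp, m)
  expect_true(all(ss$prop_flagged == 0))

  # simulated world: swept singleton islands dominate the flagged fraction
  sim <- shared_sim()
  mat <- build_matrix(sim$dataset)
  cs2 <- contig_sweeps(sim$dataset)
  gp2 <- gene_sweep_pvalues(cs2, sim$dataset$gene_calls,
                            sim$dataset$contigs)
  ss2 <- sweep_summary_by_frequency(gp2, mat)
  expect_gt(ss2$prop_flagged[ss2$frequency == 1],
            ss2$prop_flagged[ss2$frequency == 22])
})

test_that("a uniform null yields no flags and calibrated P values", {
  # 2,000 contigs, fixed density, no sweeps
  cfg <- sim_config(seed = 32L, n_clusters = 4000L, core_fraction = 0.3,
                    singleton_fraction = 0.3,
                    contig_length_bp = 20000L,
                    snv_density_range = c(2, 2), n_swept = 0L)
  pan <- generate_pangenome(cfg)
  sv <- generate_snvs(pan$dataset, pan$truth, cfg)
  ds <- pg_dataset(pan$dataset$bins, pan$dataset$contigs,
                   pan$dataset$gene_calls, pan$dataset$clusters,
                   snvs = sv$snvs)
  cs <- contig_sweeps(ds)
  expect_gt(nrow(cs), 1000L)
  gp <- gene_sweep_pvalues(cs, ds$gene_calls, ds$contigs)
  expect_equal(sum(gp$flagged), 0L)

  # KS distance between the observed P values and the discretized null
  grid <- sort(unique(cs$p_value))
  F_emp <- ecdf(cs$p_value)(grid)
  F_null <- vapply(grid, function(t) {
    kq <- qpois(t, cs$n_c)
    kq <- kq - (ppois(kq, cs$n_c) > t + 1e-12)
    mean(ifelse(kq < 0, 0, ppois(kq, cs$n_c)))
  }, numeric(1))
  expect_lt(max(abs(F_emp - F_null)), 0.02)
})

test_that("coverage by frequency is flat when coverage is unbiased", {
  ds <- make_snv_ds(c(5000, 5000), c(0L, 0L), coverage = 50)
  m <- matrix_from_sets(list(B1 = unique(ds$gene_calls$cluster_id)))
  cf <- coverage_by_frequency(ds$contigs, ds$gene_calls, m)
  expect_true(all(cf$mean_coverage == 50))

  # two frequency classes with coverages {10,10} and {100,100}
  sets <- list(A = c("g1", "g2"), B = c("g1", "g2", "g3", "g4"))
  m2 <- matrix_from_sets(sets)
  contigs <- data.table::data.table(
    contig_id = c("A_c1", "B_c1"), bin_id = c("A", "B"),
    length_bp = 10000L, mean_coverage = c(10, 100))
  gcs <- data.table::data.table(
    gene_id = sprintf("g%d_%d", c(1, 2, 3, 4, 1, 2), c(1, 1, 1, 1, 2, 2)),
    bin_id = c("B", "B", "B", "B", "A", "A"),
    contig_id = c("B_c1", "B_c1", "B_c1", "B_c1", "A_c1", "A_c1"),
    start0 = 0L, stop0 = 300L, strand = "+",
    cluster_id = c("g1", "g2", "g3", "g4", "g1", "g2"))
  cf2 <- coverage_by_frequency(contigs, gcs, m2)
  expect_equal(cf2$mean_coverage[cf2$frequency == 1], 100)  # g3,g4 on B only
  expect_equal(cf2$mean_coverage[cf2$frequency == 2], 55)   # g1,g2 on both

  # no coverage column: message + empty result
  c_nocov <- data.table::copy(contigs)
  c_nocov[, mean_coverage := NA_real_]
  expect_message(out <- coverage_by_frequency(c_nocov, gcs, m2), "skipped")
  expect_equal(nrow(out), 0L)

  # simulated world: no monotone coverage trend across frequencies
  sim <- shared_sim()
  mat <- build_matrix(sim$dataset)
  f <- attr(mat, "frequency")
  gc <- sim$dataset$gene_calls
  gene_f <- f[match(gc$cluster_id, rownames(mat))]
  gene_cov <- sim$dataset$contigs$mean_coverage[
    match(gc$contig_id, sim$dataset$contigs$contig_id)]
  rho <- cor(gene_f, gene_cov, method = "spearman")
  expect_lt(abs(rho), 0.2)
})
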