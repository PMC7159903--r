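# SNV density and Poisson sweep detection.
#
# Under neutral scattering of a bin's N SNVs over its L bp, a contig of
# length l_c receives Poisson(n_c) SNVs with n_c = N * l_c / L. The
# inclusive lower-tail CDF at the observed count is the gene-specific sweep
# P value: a strong deficit (P below a threshold, default 1e-10) marks a
# candidate sweep.

#' Per-bin SNV density
#'
#' @param snvs SNV records (`contig_id`, `pos0`, ...).
#' @param contigs contig table (`contig_id`, `bin_id`, `length_bp`).
#' @param min_contig_bp contigs shorter than this are excluded from both
#'   the numerator and the denominator.
#' @return data.table `bin_id`, `n_snv`, `length_bp`, `density_per_kbp`
#'   (1000 * SNVs / bp).
#' @export
snv_density <- function(snvs, contigs, min_contig_bp = 1000L) {
  contigs <- as.data.table(contigs)
  snvs <- as.data.table(snvs)
  bad <- setdiff(unique(snvs$contig_id), contigs$contig_id)
  if (length(bad)) {
    pg_integrity_error(sprintf("SNVs on unknown contigs: %s",
                               paste(head(bad, 5), collapse = ", ")),
                       ids = bad)
  }
  keep <- contigs[length_bp >= min_contig_bp]
  if (!nrow(keep)) pg_domain_error("no contigs pass the length filter")
  cnt <- snvs[contig_id %in% keep$contig_id, .(n_snv = .N), by = contig_id]
  per_contig <- merge(keep, cnt, by = "contig_id", all.x = TRUE)
  per_contig[is.na(n_snv), n_snv := 0L]
  out <- per_contig[, .(n_snv = sum(n_snv), length_bp = sum(length_bp)),
                    by = bin_id]
  out[, density_per_kbp := 1000 * n_snv / length_bp]
  setorder(out, bin_id)
  out[]
}

#' Poisson sweep test for one contig
#'
#' @param x observed SNV count on the contig.
#' @param l_c contig length (bp).
#' @param N total SNV count of the bin.
#' @param L total length of the bin (bp); must be >= `l_c`.
#' @return list with `n_c` (expected count) and `p_value` (inclusive
#'   lower-tail Poisson CDF; 1 when N = 0 and x = 0).
#' @export
contig_sweep_test <- function(x, l_c, N, L) {
  if (any(l_c > L)) pg_domain_error("contig longer than its bin (l_c > L)")
  if (any(x < 0) || any(N < 0) || any(l_c <= 0) || any(L <= 0)) {
    pg_domain_error("counts must be >= 0 and lengths > 0")
  }
  n_c <- as.numeric(N) * as.numeric(l_c) / as.numeric(L)
  list(n_c = n_c, p_value = ppois(x, n_c))
}

#' Poisson sweep scan over all contigs of a dataset
#'
#' Applies [contig_sweep_test()] per contig, with N and L accumulated per
#' bin over the contigs passing the length filter (so the expected counts
#' n_c sum exactly to N within each bin).
#'
#' @param ds a [pg_dataset()] with SNV records.
#' @param min_contig_bp minimum contig length (bp) for inclusion.
#' @return data.table: `contig_id`, `bin_id`, `length_bp`, `x`, `n_c`,
#'   `p_value`, `snv_free`.
#' @export
contig_sweeps <- function(ds, min_contig_bp = 1000L) {
  stopifnot(inherits(ds, "pg_dataset"))
  if (is.null(ds$snvs)) pg_format_error("dataset has no SNV records")
  contigs <- ds$contigs[length_bp >= min_contig_bp]
  if (!nrow(contigs)) pg_domain_error("no contigs pass the length filter")
  cnt <- ds$snvs[, .(x = .N), by = contig_id]
  tab <- merge(contigs[, .(contig_id, bin_id, length_bp)], cnt,
               by = "contig_id", all.x = TRUE)
  tab[is.na(x), x := 0L]
  tab[, `:=`(N = sum(x), L = sum(as.numeric(length_bp))), by = bin_id]
  st <- contig_sweep_test(tab$x, tab$length_bp, tab$N, tab$L)
  tab[, `:=`(n_c = st$n_c, p_value = st$p_value, snv_free = x == 0L)]
  setorder(tab, bin_id, contig_id)
  tab[, .(contig_id, bin_id, length_bp, x, N, L, n_c, p_value, snv_free)]
}

#' Gene-level sweep P values
#'
#' Each gene inherits the Poisson P value of its containing contig and is
#' flagged when the P value falls below `p_cutoff` (default 1e-10). Genes
#' on contigs excluded by the length filter are dropped; genes on contigs
#' absent from the sweep table altogether raise an integrity error.
#'
#' @param sweeps a [contig_sweeps()] result.
#' @param gene_calls gene-call table of the dataset.
#' @param all_contigs full contig table (to distinguish filtered from
#'   unknown contigs); defaults to the sweep table itself.
#' @param p_cutoff flag threshold.
#' @return data.table `gene_id`, `cluster_id`, `contig_id`, `bin_id`,
#'   `p_value`, `snv_free`, `flagged`.
#' @export
gene_sweep_pvalues <- function(sweeps, gene_calls, all_contigs = NULL,
                               p_cutoff = 1e-10) {
  gc <- as.data.table(gene_calls)
  known <- if (is.null(all_contigs)) sweeps$contig_id
           else as.data.table(all_contigs)$contig_id
  orphan <- setdiff(unique(gc$contig_id), known)
  if (length(orphan)) {
    pg_integrity_error(sprintf("genes on unknown contigs: %s",
                               paste(head(orphan, 5), collapse = ", ")),
                       ids = orphan)
  }
  out <- merge(gc[, .(gene_id, cluster_id, contig_id, bin_id)],
               as.data.table(sweeps)[, .(contig_id, p_value, snv_free)],
               by = "contig_id")
  out[, flagged := p_value < p_cutoff]
  setorder(out, gene_id)
  out[, .(gene_id, cluster_id, contig_id, bin_id, p_value, snv_free, flagged)]
}

#' Sweep summary by pangenome frequency
#'
#' Per frequency class: the fraction of genes flagged as sweep candidates
#' and the fraction on SNV-free contigs.
#'
#' @param gene_pvalues a [gene_sweep_pvalues()] result.
#' @param mat a [build_matrix()] result supplying cluster frequencies.
#' @return data.table `frequency`, `n_genes`, `prop_flagged`,
#'   `prop_snv_free`.
#' @export
sweep_summary_by_frequency <- function(gene_pvalues, mat) {
  f <- cluster_frequency(mat)
  gp <- copy(as.data.table(gene_pvalues))
  gp[, frequency := f[match(cluster_id, rownames(mat))]]
  gp <- gp[!is.na(frequency)]
  out <- gp[, .(n_genes = .N,
                prop_flagged = mean(flagged),
                prop_snv_free = mean(snv_free)), by = frequency]
  setorder(out, frequency)
  out[]
}

#' Mean contig coverage by pangenome frequency
#'
#' Diagnostic against assembly/binning artifacts: if low-frequency genes
#' simply sat on poorly covered contigs, apparent accessory genes could be
#' coverage dropouts. Reports mean and SD of the containing contig's mean
#' coverage per frequency class.
#'
#' @param contigs contig table with `mean_coverage`.
#' @param gene_calls gene-call table.
#' @param mat a [build_matrix()] result.
#' @return data.table `frequency`, `n_genes`, `mean_coverage`,
#'   `sd_coverage`.
#' @export
coverage_by_frequency <- function(contigs, gene_calls, mat) {
  contigs <- as.data.table(contigs)
  if (!"mean_coverage" %in% names(contigs) ||
      all(is.na(contigs$mean_coverage))) {
    message("coverage_by_frequency: no coverage available; skipped")
    return(data.table(frequency = integer(), n_genes = integer(),
                      mean_coverage = numeric(), sd_coverage = numeric()))
  }
  f <- cluster_frequency(mat)
  gc <- as.data.table(gene_calls)
  gc[, frequency := f[match(cluster_id, rownames(mat))]]
  gc[, cov := contigs$mean_coverage[match(contig_id, contigs$contig_id)]]
  gc <- gc[!is.na(frequency) & !is.na(cov)]
  out <- gc[, .(n_genes = .N, mean_coverage = mean(cov),
                sd_coverage = sd(cov)), by = frequency]
  setorder(out, frequency)
  out[]
}
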