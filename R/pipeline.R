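# End-to-end pipeline: chains the analysis stages over a dataset and writes
# all stage outputs with provenance (seed + config hash).

#' Run the full analysis pipeline
#'
#' Stages, in order: presence/absence matrix and frequency spectrum;
#' containment, genome dendrogram and rarefaction; completeness-aware core
#' posterior; COG category profile and permutation enrichment;
#' biogeographic binomial scoring; pN/pS (skipped without codon variants /
#' sequences); SNV density and Poisson sweeps (skipped without SNVs).
#' Outputs are TSV tables plus a `run_info.json` echoing the configuration,
#' its hash and the seed; no timestamps are written, so reruns with the
#' same inputs and seed are byte-identical.
#'
#' @param ds a [pg_dataset()].
#' @param config a [pipeline_config()].
#' @param verbose log one line per stage.
#' @return invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(ds, "pg_dataset"), inherits(config, "pg_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  wr <- function(tab, name) {
    fwrite(as.data.table(tab), file.path(out_dir, name), sep = "\t",
           na = "NA", quote = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pg_error("pangevo_stage_error",
               sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## pangenome structure
  mat <- stage("matrix", build_matrix(ds))
  results$matrix <- mat
  pg_log("matrix", sprintf("%d clusters x %d bins", nrow(mat), ncol(mat)),
         verbose = verbose)
  mat_out <- data.table(cluster_id = rownames(mat),
                        as.data.table(1L * unclass(mat)[, , drop = FALSE]))
  wr(mat_out, "matrix.tsv")
  results$spectrum <- stage("spectrum", frequency_spectrum(mat))
  wr(results$spectrum, "frequency_spectrum.tsv")

  C <- stage("containment", containment(mat))
  results$containment <- C
  wr(data.table(bin_id = rownames(C), as.data.table(C)), "containment.tsv")
  if (ncol(mat) >= 2L) {
    hc <- stage("dendrogram", cluster_genomes(C))
    results$dendrogram <- hc
    write_dendrogram(hc, file.path(out_dir, "genome_dendrogram.nwk"))
  }
  results$rarefaction <- stage("rarefaction",
    rarefaction(mat, n_perm = 100L, seed = stage_seed(config$seed, "rarefaction")))
  wr(results$rarefaction, "rarefaction.tsv")

  comp <- setNames(ds$bins$completeness, ds$bins$bin_id)[colnames(mat)]
  results$core_posterior <- stage("core_posterior",
    core_posterior(seq(0L, ncol(mat)), comp, prior = "flat",
                   n_sims = config$n_sims,
                   seed = stage_seed(config$seed, "core_posterior")))
  wr(results$core_posterior, "core_posterior.tsv")
  pg_log("core_posterior", sprintf("%d Monte Carlo draws", config$n_sims),
         verbose = verbose)

  ## functional enrichment
  prof <- stage("category_profile", category_profile(mat, ds$clusters))
  results$category_profile <- prof
  wr(prof, "category_profile.tsv")
  enr <- stage("enrichment",
    permutation_enrichment(prof, n_perm = config$n_perm,
                           seed = stage_seed(config$seed, "enrichment")))
  results$enrichment <- enr
  wr(enr, "enrichment.tsv")
  pg_log("enrichment", sprintf("%d permutations", config$n_perm),
         verbose = verbose)

  ## biogeography
  sites <- setNames(ds$bins$site, ds$bins$bin_id)
  scores <- stage("biogeo", score_clusters(mat, sites, config))
  results$biogeo <- scores
  sc_out <- copy(as.data.table(scores))
  sc_out[, cdf := sprintf("%.8f", cdf)]
  wr(sc_out, "biogeo_scores.tsv")
  pg_log("biogeo", sprintf("%d scored, %d excluded by the inclusion filter",
                           nrow(scores), attr(scores, "n_excluded")),
         verbose = verbose)

  ## selection
  if (!is.null(ds$sequences) && !is.null(ds$codon_variants)) {
    pp <- stage("pnps", pnps_all(ds))
    results$pnps <- pp
    wr(pp, "pnps.tsv")
    f <- cluster_frequency(mat)
    freq_of_gene <- f[match(
      ds$gene_calls$cluster_id[match(pp$gene_id, ds$gene_calls$gene_id)],
      rownames(mat))]
    results$pnps_by_frequency <- stage("pnps_groups",
      pnps_group_stats(pp, setNames(freq_of_gene, pp$gene_id)))
    wr(results$pnps_by_frequency, "pnps_by_frequency.tsv")
    pg_log("pnps", sprintf("%d ORFs, %d with finite ratio", nrow(pp),
                           sum(pp$status %in% c("ok", "zero"))),
           verbose = verbose)
  } else {
    pg_log("pnps", "skipped (no codon variants / sequences)", verbose = verbose)
  }

  ## sweeps
  if (!is.null(ds$snvs)) {
    results$snv_density <- stage("snv_density",
      snv_density(ds$snvs, ds$contigs, config$min_contig_bp))
    wr(results$snv_density, "snv_density.tsv")
    cs <- stage("contig_sweeps", contig_sweeps(ds, config$min_contig_bp))
    results$contig_sweeps <- cs
    wr(cs, "contig_sweeps.tsv")
    gp <- stage("gene_sweeps",
      gene_sweep_pvalues(cs, ds$gene_calls, all_contigs = ds$contigs,
                         p_cutoff = config$sweep_p_cutoff))
    results$gene_sweeps <- gp
    wr(gp, "gene_sweeps.tsv")
    results$sweep_summary <- stage("sweep_summary",
      sweep_summary_by_frequency(gp, mat))
    wr(results$sweep_summary, "sweep_summary.tsv")
    pg_log("sweeps", sprintf("%d contigs tested, %d genes flagged",
                             nrow(cs), sum(gp$flagged)), verbose = verbose)
  } else {
    pg_log("sweeps", "skipped (no SNV records)", verbose = verbose)
  }
  results$coverage_by_frequency <- stage("coverage",
    coverage_by_frequency(ds$contigs, ds$gene_calls, mat))
  wr(results$coverage_by_frequency, "coverage_by_frequency.tsv")

  info <- list(
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    stages = names(results)
  )
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
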