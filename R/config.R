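# Configuration objects for the simulator and the pipeline.

#' Simulation configuration
#'
#' Defaults state the world the analysis assumes: 22 MAGs (13 "Axial",
#' 9 "MCR"), a U-shaped cluster frequency spectrum of roughly 10^4 clusters,
#' per-MAG completeness Uniform(0.70, 0.97), per-MAG SNV densities
#' log-uniform on 0.1-10 per kbp, a set of MCR-biased clusters, per-class
#' pN/pS targets, and swept contigs with density multiplier 0.
#'
#' @param n_axial,n_mcr number of MAGs per site group.
#' @param n_clusters total number of gene clusters in the true pangenome.
#' @param core_fraction fraction of clusters truly present in every MAG.
#' @param singleton_fraction fraction truly present in exactly one MAG.
#' @param accessory_decay geometric decay rate of the accessory frequency
#'   spectrum on frequencies 2..(M-1); larger = more low-frequency clusters.
#' @param completeness_range range of per-MAG detection probability.
#' @param redundancy_range range of per-MAG redundancy fraction.
#' @param n_biased number of MCR-biased clusters (truly present in all MCR
#'   MAGs and at most `biased_max_axial` Axial MAGs, before dropout).
#' @param biased_max_axial maximum true Axial presence of a biased cluster.
#' @param cog_categories COG category letters used for annotation
#'   (plus `"N/A"` for unannotated clusters).
#' @param cog_base_prob baseline annotation probabilities, same length as
#'   `cog_categories`; need not sum to 1 (normalized internally).
#' @param cog_enriched_category,cog_enriched_band,cog_enrich_factor one
#'   category whose probability is multiplied by `cog_enrich_factor` for
#'   clusters in `cog_enriched_band` (`"singleton"` or `"core"`); emulates
#'   the concentration of poorly characterized genes at low frequency.
#' @param multi_annot_prob probability a cluster carries two annotations.
#' @param orf_codons_range range of ORF lengths in codons.
#' @param gene_spacing_bp intergenic gap used when placing genes on contigs.
#' @param contig_length_bp target contig length in bp.
#' @param snv_density_range per-MAG SNV density range (per kbp); densities
#'   are drawn log-uniformly between the bounds.
#' @param n_swept number of swept contigs (chosen among contigs carrying a
#'   singleton gene when possible).
#' @param swept_multiplier SNV density multiplier on swept contigs.
#' @param pnps_targets named numeric vector of per-class target pN/pS; names
#'   are selection classes assigned to clusters by frequency band
#'   (`core` = frequency M, `singleton` = frequency 1, `accessory` rest).
#' @param mean_variants_per_orf mean single-codon-variant count per ORF
#'   (Poisson); variant generation respects the class target.
#' @param seed integer global seed; stage substreams are derived from it.
#' @return a `pg_sim_config` list.
#' @export
sim_config <- function(n_axial = 13L, n_mcr = 9L,
                       n_clusters = 10000L,
                       core_fraction = 0.10,
                       singleton_fraction = 0.35,
                       accessory_decay = 0.20,
                       completeness_range = c(0.70, 0.97),
                       redundancy_range = c(0.00, 0.05),
                       n_biased = 50L,
                       biased_max_axial = 1L,
                       cog_categories = c("J", "K", "L", "C", "E", "F", "G",
                                          "H", "I", "P", "M", "N", "T", "U",
                                          "O", "S", "N/A"),
                       cog_base_prob = NULL,
                       cog_enriched_category = "S",
                       cog_enriched_band = "singleton",
                       cog_enrich_factor = 2.0,
                       multi_annot_prob = 0.05,
                       orf_codons_range = c(100L, 400L),
                       gene_spacing_bp = 100L,
                       contig_length_bp = 40000L,
                       snv_density_range = c(0.1, 10),
                       n_swept = 20L,
                       swept_multiplier = 0,
                       pnps_targets = c(core = 0.15, accessory = 0.25,
                                        singleton = 0.35),
                       mean_variants_per_orf = 30,
                       seed = 42L) {
  if (n_axial < 1L || n_mcr < 1L) {
    pg_config_error("need at least 1 MAG per site")
  }
  assert_prob(core_fraction, "core_fraction")
  assert_prob(singleton_fraction, "singleton_fraction")
  if (core_fraction + singleton_fraction > 1) {
    pg_config_error("core_fraction + singleton_fraction must be <= 1")
  }
  if (any(completeness_range <= 0) || any(completeness_range > 1)) {
    pg_config_error("completeness must lie in (0, 1]")
  }
  if (any(snv_density_range < 0) || swept_multiplier < 0) {
    pg_config_error("SNV densities and multipliers must be >= 0")
  }
  if (is.null(cog_base_prob)) {
    cog_base_prob <- rep(1, length(cog_categories))
    names(cog_base_prob) <- cog_categories
    cog_base_prob[c("J", "E", "S", "N/A")] <- c(2, 2, 3, 4)
  }
  if (length(cog_base_prob) != length(cog_categories)) {
    pg_config_error("cog_base_prob must match cog_categories in length")
  }
  structure(list(
    n_axial = as.integer(n_axial), n_mcr = as.integer(n_mcr),
    n_clusters = as.integer(n_clusters),
    core_fraction = core_fraction,
    singleton_fraction = singleton_fraction,
    accessory_decay = accessory_decay,
    completeness_range = completeness_range,
    redundancy_range = redundancy_range,
    n_biased = as.integer(n_biased),
    biased_max_axial = as.integer(biased_max_axial),
    cog_categories = cog_categories,
    cog_base_prob = cog_base_prob,
    cog_enriched_category = cog_enriched_category,
    cog_enriched_band = cog_enriched_band,
    cog_enrich_factor = cog_enrich_factor,
    multi_annot_prob = multi_annot_prob,
    orf_codons_range = as.integer(orf_codons_range),
    gene_spacing_bp = as.integer(gene_spacing_bp),
    contig_length_bp = as.integer(contig_length_bp),
    snv_density_range = snv_density_range,
    n_swept = as.integer(n_swept),
    swept_multiplier = swept_multiplier,
    pnps_targets = pnps_targets,
    mean_variants_per_orf = mean_variants_per_orf,
    seed = as.integer(seed)
  ), class = "pg_sim_config")
}

#' Pipeline configuration
#'
#' @param site1,site2 site labels; `site1` is the group whose proportion
#'   enters the binomial null (the "Axial" role).
#' @param p expected site-1 proportion under the biogeographic null;
#'   `NULL` (default) computes n_site1 / (n_site1 + n_site2) from the input
#'   bins, which reproduces 13/22 on the reference design.
#' @param min_site2_mags,min_site1_mags inclusion filter: a cluster is
#'   scored when found in at least `min_site2_mags` site-2 MAGs or at least
#'   `min_site1_mags` site-1 MAGs (defaults 7 and 12).
#' @param cdf_lo,cdf_hi significance cutoffs on the binomial CDF: below
#'   `cdf_lo` = site-2 enriched, above `cdf_hi` = site-1 enriched.
#' @param sweep_p_cutoff Poisson P value below which a gene is flagged as a
#'   gene-specific sweep candidate.
#' @param min_contig_bp contigs shorter than this are excluded from the
#'   sweep analysis.
#' @param freq_band_cutoff frequency (number of MAGs) splitting "low" from
#'   "high" frequency bands in category band tests.
#' @param n_perm permutations for the COG enrichment null.
#' @param n_sims Monte Carlo draws for the core posterior.
#' @param seed integer global seed.
#' @param out_dir output directory for [run_pipeline()].
#' @return a `pg_config` list.
#' @export
pipeline_config <- function(site1 = "Axial", site2 = "MCR",
                            p = NULL,
                            min_site2_mags = 7L, min_site1_mags = 12L,
                            cdf_lo = 0.05, cdf_hi = 0.95,
                            sweep_p_cutoff = 1e-10,
                            min_contig_bp = 1000L,
                            freq_band_cutoff = 15L,
                            n_perm = 999L,
                            n_sims = 100000L,
                            seed = 42L,
                            out_dir = "pangevo_out") {
  if (!is.null(p)) {
    if (!is.numeric(p) || p <= 0 || p >= 1) {
      pg_config_error("p must lie strictly in (0, 1)")
    }
  }
  assert_prob(cdf_lo, "cdf_lo"); assert_prob(cdf_hi, "cdf_hi")
  if (cdf_lo >= cdf_hi) pg_config_error("cdf_lo must be < cdf_hi")
  if (sweep_p_cutoff <= 0 || sweep_p_cutoff >= 1) {
    pg_config_error("sweep_p_cutoff must lie in (0, 1)")
  }
  if (n_perm < 1L || n_sims < 1L) pg_config_error("n_perm and n_sims must be >= 1")
  if (!is.numeric(seed) || is.na(seed) || seed != floor(seed)) {
    pg_config_error("seed must be an integer")
  }
  structure(list(
    site1 = site1, site2 = site2, p = p,
    min_site2_mags = as.integer(min_site2_mags),
    min_site1_mags = as.integer(min_site1_mags),
    cdf_lo = cdf_lo, cdf_hi = cdf_hi,
    sweep_p_cutoff = sweep_p_cutoff,
    min_contig_bp = as.integer(min_contig_bp),
    freq_band_cutoff = as.integer(freq_band_cutoff),
    n_perm = as.integer(n_perm),
    n_sims = as.integer(n_sims),
    seed = as.integer(seed),
    out_dir = out_dir
  ), class = "pg_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' The file holds any subset of the arguments of [pipeline_config()];
#' unknown keys raise a configuration error.
#' @param path JSON file.
#' @return a `pg_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    pg_config_error(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}
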