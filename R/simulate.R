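# Synthetic-data generator.
#
# The generator states a world with the statistical structure the analysis
# assumes: a U-shaped cluster frequency spectrum over 22 MAGs split across
# two vent sites, incomplete genome recovery acting as per-MAG Bernoulli
# dropout, site-biased clusters, class-targeted pN/pS regimes, and per-MAG
# SNV densities with optional swept (SNV-free) contigs. Everything is
# deterministic given the seed; stages draw from derived substreams.

.SENSE_CODONS <- local({
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
})

bin_ids_for <- function(cfg) {
  c(sprintf("AX_%02d", seq_len(cfg$n_axial)),
    sprintf("MCR_%02d", seq_len(cfg$n_mcr)))
}

# truncated-geometric pmf on frequencies 2..(M-1) for accessory clusters
accessory_pmf <- function(M, decay) {
  f <- 2:(M - 1)
  w <- (1 - decay)^(f - 2)
  w / sum(w)
}

#' Generate a synthetic pangenome dataset with its ground truth
#'
#' Draws true cluster presence across MAGs from a core/accessory/singleton
#' mixture plus a set of MCR-biased clusters, applies completeness dropout
#' (a cluster is observed in a MAG with probability equal to that MAG's
#' completeness), places the observed gene calls on non-overlapping contigs,
#' assigns COG annotations, and synthesizes one in-frame reference coding
#' sequence per cluster (shared by its gene calls).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `dataset` (a [pg_dataset()], without SNVs or
#'   codon variants — see [generate_snvs()] and [generate_codon_variants()])
#'   and `truth` (list of `clusters`, `genes` data.tables; `contigs` truth
#'   is added by [generate_snvs()]).
#' @export
generate_pangenome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "pg_sim_config"))
  set.seed(stage_seed(cfg$seed, "pangenome"))
  M <- cfg$n_axial + cfg$n_mcr
  bins_id <- bin_ids_for(cfg)
  site <- rep(c("Axial", "MCR"), c(cfg$n_axial, cfg$n_mcr))
  completeness <- runif(M, cfg$completeness_range[1], cfg$completeness_range[2])
  redundancy <- runif(M, cfg$redundancy_range[1], cfg$redundancy_range[2])

  ## ---- true presence ----
  n_core <- round(cfg$n_clusters * cfg$core_fraction)
  n_single <- round(cfg$n_clusters * cfg$singleton_fraction)
  n_biased <- min(cfg$n_biased, cfg$n_clusters - n_core - n_single)
  n_acc <- cfg$n_clusters - n_core - n_single - n_biased
  if (n_acc < 0) pg_config_error("class fractions exceed cluster budget")
  cluster_id <- sprintf("GC_%05d", seq_len(cfg$n_clusters))
  class <- rep(c("core", "accessory", "biased", "singleton"),
               c(n_core, n_acc, n_biased, n_single))

  mcr_idx <- which(site == "MCR")
  ax_idx <- which(site == "Axial")
  presence <- vector("list", cfg$n_clusters)
  ci <- 0L
  for (i in seq_len(n_core)) presence[[ci + i]] <- seq_len(M)
  ci <- ci + n_core
  if (n_acc > 0) {
    pmf <- accessory_pmf(M, cfg$accessory_decay)
    fs <- sample(2:(M - 1), n_acc, replace = TRUE, prob = pmf)
    for (i in seq_len(n_acc)) presence[[ci + i]] <- sample.int(M, fs[i])
  }
  ci <- ci + n_acc
  for (i in seq_len(n_biased)) {
    n_ax <- sample.int(cfg$biased_max_axial + 1L, 1L) - 1L
    presence[[ci + i]] <- c(mcr_idx, sample(ax_idx, n_ax))
  }
  ci <- ci + n_biased
  for (i in seq_len(n_single)) presence[[ci + i]] <- sample.int(M, 1L)

  ## ---- completeness dropout ----
  observed <- lapply(presence, function(mem) {
    mem[runif(length(mem)) < completeness[mem]]
  })
  true_freq <- lengths(presence)
  obs_freq <- lengths(observed)

  ## ---- COG annotation (per cluster; frequency-band-dependent mix) ----
  cats <- cfg$cog_categories
  base_p <- cfg$cog_base_prob / sum(cfg$cog_base_prob)
  band <- ifelse(true_freq == M, "core",
                 ifelse(true_freq == 1L, "singleton", "accessory"))
  boost_i <- match(cfg$cog_enriched_category, cats)
  draw_cat <- function(in_band) {
    p <- base_p
    if (!is.na(boost_i) && in_band) {
      p[boost_i] <- p[boost_i] * cfg$cog_enrich_factor
      p <- p / sum(p)
    }
    p
  }
  p_plain <- draw_cat(FALSE)
  p_boost <- draw_cat(TRUE)
  in_band <- band == cfg$cog_enriched_band
  cat1 <- character(cfg$n_clusters)
  cat1[in_band] <- sample(cats, sum(in_band), replace = TRUE, prob = p_boost)
  cat1[!in_band] <- sample(cats, sum(!in_band), replace = TRUE, prob = p_plain)
  has2 <- runif(cfg$n_clusters) < cfg$multi_annot_prob & cat1 != "N/A"
  cat2 <- rep(NA_character_, cfg$n_clusters)
  cat2[has2] <- vapply(cat1[has2], function(c1)
    sample(setdiff(setdiff(cats, "N/A"), c1), 1L), character(1))

  ## ---- reference coding sequences (one per cluster) ----
  codons_n <- sample(cfg$orf_codons_range[1]:cfg$orf_codons_range[2],
                     cfg$n_clusters, replace = TRUE)
  gene_len_bp <- codons_n * 3L
  if (max(gene_len_bp) + cfg$gene_spacing_bp > cfg$contig_length_bp) {
    pg_error("pangevo_sizing_error",
             "longest gene does not fit on a contig; increase contig_length_bp")
  }
  all_cod <- sample(.SENSE_CODONS, sum(codons_n), replace = TRUE)
  cod_end <- cumsum(codons_n)
  cod_start <- cod_end - codons_n + 1L
  cluster_seq <- vapply(seq_len(cfg$n_clusters), function(i)
    paste(all_cod[cod_start[i]:cod_end[i]], collapse = ""), character(1))

  ## ---- gene placement on contigs ----
  calls <- data.table(
    cluster_idx = rep(seq_len(cfg$n_clusters), obs_freq),
    bin_idx = unlist(observed)
  )
  setorder(calls, bin_idx)
  calls[, gene_id := sprintf("%s_g%05d", bins_id[bin_idx],
                             seq_len(.N)), by = bin_idx]
  # Shuffle gene order within each bin, but keep singleton clusters in
  # contiguous blocks at the end of each bin: recently acquired genes sit
  # in genomic islands, which is what concentrates them on shared contigs
  # (and is what makes contig-level sweep signals attributable to them).
  is_single <- class[calls$cluster_idx] == "singleton"
  calls <- calls[order(bin_idx, is_single, runif(nrow(calls)))]
  contig_tabs <- vector("list", M)
  placed <- vector("list", M)
  for (m in seq_len(M)) {
    sub <- calls[bin_idx == m]
    len <- gene_len_bp[sub$cluster_idx]
    need <- len + cfg$gene_spacing_bp
    contig_no <- integer(nrow(sub))
    start0 <- integer(nrow(sub))
    cur_contig <- 1L; cur_off <- 0L
    for (i in seq_len(nrow(sub))) {
      if (cur_off + need[i] > cfg$contig_length_bp) {
        cur_contig <- cur_contig + 1L; cur_off <- 0L
      }
      contig_no[i] <- cur_contig
      start0[i] <- cur_off
      cur_off <- cur_off + need[i]
    }
    sub[, `:=`(contig_no = contig_no, start0 = start0,
               stop0 = start0 + len)]
    n_contig <- max(contig_no)
    clen <- integer(n_contig)
    used <- tapply(sub$stop0, sub$contig_no, max)
    clen[as.integer(names(used))] <- as.integer(used)
    # pad contigs to the target length except a ragged last one
    clen <- pmax(clen + cfg$gene_spacing_bp,
                 c(rep(cfg$contig_length_bp, n_contig - 1L), 0L))
    contig_tabs[[m]] <- data.table(
      contig_id = sprintf("%s_c%04d", bins_id[m], seq_len(n_contig)),
      bin_id = bins_id[m],
      length_bp = clen
    )
    placed[[m]] <- sub
  }
  contigs <- rbindlist(contig_tabs)
  contigs[, mean_coverage := round(exp(rnorm(.N, log(50), 0.4)), 2)]
  calls <- rbindlist(placed)
  gene_calls <- data.table(
    gene_id = calls$gene_id,
    bin_id = bins_id[calls$bin_idx],
    contig_id = sprintf("%s_c%04d", bins_id[calls$bin_idx], calls$contig_no),
    start0 = calls$start0,
    stop0 = calls$stop0,
    strand = sample(c("+", "-"), nrow(calls), replace = TRUE),
    cluster_id = cluster_id[calls$cluster_idx]
  )

  bins <- data.table(
    bin_id = bins_id, site = site,
    completeness = round(completeness, 4),
    redundancy = round(redundancy, 4),
    total_length_bp = contigs[, sum(length_bp), by = bin_id][match(bins_id, bin_id), V1]
  )

  obs_clusters <- sort(unique(gene_calls$cluster_id))
  ann <- data.table(cluster_id = cluster_id, cog_category = cat1,
                    second = cat2)
  ann1 <- ann[, .(cluster_id, cog_category)]
  ann2 <- ann[!is.na(second), .(cluster_id, cog_category = second)]
  clusters_tab <- rbindlist(list(ann1, ann2))
  clusters_tab[, cog_function := ifelse(cog_category == "N/A",
                                        "hypothetical protein",
                                        paste0("COG-", cog_category,
                                               " family protein"))]
  setcolorder(clusters_tab, c("cluster_id", "cog_function", "cog_category"))
  clusters_tab <- clusters_tab[cluster_id %in% obs_clusters]
  setorder(clusters_tab, cluster_id, cog_category)

  sequences <- setNames(
    cluster_seq[calls$cluster_idx], calls$gene_id)

  pnps_class <- ifelse(class == "core", "core",
                       ifelse(class == "singleton", "singleton", "accessory"))
  truth_clusters <- data.table(
    cluster_id = cluster_id,
    class = class,
    site_biased = class == "biased",
    true_freq = true_freq,
    obs_freq = obs_freq,
    true_bins = vapply(presence, function(i)
      paste(bins_id[i], collapse = "|"), character(1)),
    cog_primary = cat1,
    cog_secondary = cat2,
    pnps_class = pnps_class,
    pnps_target = unname(cfg$pnps_targets[pnps_class]),
    codons = codons_n
  )
  truth_genes <- data.table(
    gene_id = gene_calls$gene_id,
    cluster_id = gene_calls$cluster_id,
    pnps_class = pnps_class[calls$cluster_idx],
    pnps_target = unname(cfg$pnps_targets[pnps_class[calls$cluster_idx]])
  )

  ds <- pg_dataset(bins = bins, contigs = contigs, gene_calls = gene_calls,
                   clusters = clusters_tab, sequences = sequences)
  list(dataset = ds, truth = list(clusters = truth_clusters,
                                  genes = truth_genes))
}

# flat lookup tables for vectorized neighbor sampling
.neighbor_flat <- local({
  syn <- .codon_tables$syn_neighbors
  non <- .codon_tables$nonsyn_neighbors
  build <- function(lst) {
    len <- lengths(lst)
    list(flat = unlist(lst, use.names = FALSE),
         start = setNames(cumsum(len) - len, names(lst)),
         len = setNames(len, names(lst)))
  }
  list(syn = build(syn), non = build(non))
})

sample_neighbor <- function(ref, kind) {
  tab <- .neighbor_flat[[kind]]
  n <- tab$len[ref]
  tab$flat[tab$start[ref] + ceiling(runif(length(ref)) * n)]
}

#' Generate single-codon-variant records with class-targeted pN/pS
#'
#' For each ORF, a Poisson number of variants is drawn; each variant is
#' synonymous with probability q chosen so that the expected pN/pS ratio —
#' under the same Nei-Gojobori site counting the selection module applies —
#' equals the ORF's class target. Synonymous variants are placed on codons
#' with at least one synonymous single-nucleotide neighbor; alternates are
#' sampled uniformly among qualifying neighbors. A small fraction of records
#' is marked as lacking full codon coverage and is ignored downstream.
#'
#' @param ds dataset from [generate_pangenome()] (needs `sequences`).
#' @param truth matching truth list.
#' @param cfg the same [sim_config()].
#' @param mean_variants overrides `cfg$mean_variants_per_orf` when not NULL.
#' @param frac_partial fraction of records flagged as not covering the full
#'   codon.
#' @return data.table of codon-variant records.
#' @export
generate_codon_variants <- function(ds, truth, cfg,
                                    mean_variants = NULL,
                                    frac_partial = 0.02) {
  stopifnot(inherits(ds, "pg_dataset"), !is.null(ds$sequences))
  set.seed(stage_seed(cfg$seed, "codon_variants"))
  mv <- mean_variants %||% cfg$mean_variants_per_orf
  genes <- truth$genes
  seqs <- ds$sequences[genes$gene_id]
  n_cod <- nchar(seqs) %/% 3L

  # per-gene site totals in thirds (integer-exact)
  cods <- strsplit(gsub("(...)", "\\1 ", seqs), " ", fixed = TRUE)
  syn_thirds_per <- lapply(cods, function(cc)
    .codon_tables$syn_thirds[cc])
  s_thirds <- vapply(syn_thirds_per, sum, numeric(1))
  n_thirds <- 9 * n_cod - s_thirds
  r <- genes$pnps_target
  q <- ifelse(r == 0, 1, 1 / (1 + r * n_thirds / s_thirds))

  V <- rpois(nrow(genes), mv)
  if (any(V > 0 & n_cod < 1L)) {
    pg_error("pangevo_sizing_error", "ORF too short to host variants")
  }
  gidx <- rep(seq_len(nrow(genes)), V)
  if (!length(gidx)) {
    return(data.table(gene_id = character(), codon_index0 = integer(),
                      ref_codon = character(), alt_codon = character(),
                      full_codon_coverage = logical()))
  }
  is_syn <- runif(length(gidx)) < q[gidx]

  # synonymous variants must land on codons with a synonymous neighbor
  elig <- lapply(cods, function(cc)
    which(.codon_tables$syn_thirds[cc] > 0))
  n_elig <- lengths(elig)
  if (any(is_syn & n_elig[gidx] == 0)) {
    pg_error("pangevo_sizing_error",
             "ORF has no codon with a synonymous neighbor")
  }
  codon_idx <- integer(length(gidx))
  u <- runif(length(gidx))
  codon_idx[!is_syn] <- ceiling(u[!is_syn] * n_cod[gidx[!is_syn]])
  flat_elig <- unlist(elig, use.names = FALSE)
  off_elig <- cumsum(n_elig) - n_elig
  codon_idx[is_syn] <- flat_elig[off_elig[gidx[is_syn]] +
                                   ceiling(u[is_syn] * n_elig[gidx[is_syn]])]
  flat_cod <- unlist(cods, use.names = FALSE)
  off_cod <- cumsum(n_cod) - n_cod
  ref <- flat_cod[off_cod[gidx] + codon_idx]
  alt <- character(length(gidx))
  alt[is_syn] <- sample_neighbor(ref[is_syn], "syn")
  alt[!is_syn] <- sample_neighbor(ref[!is_syn], "non")

  data.table(
    gene_id = genes$gene_id[gidx],
    codon_index0 = codon_idx - 1L,
    ref_codon = ref,
    alt_codon = alt,
    full_codon_coverage = runif(length(gidx)) >= frac_partial
  )
}

#' Generate SNV records with per-MAG densities and swept contigs
#'
#' Per-MAG SNV densities (per kbp) are drawn log-uniformly over the
#' configured range; each contig receives a Poisson number of SNVs at its
#' bin's density, with distinct uniform positions. Swept contigs — sampled
#' preferentially among contigs carrying a singleton-cluster gene — use the
#' density multiplied by `cfg$swept_multiplier` (default 0: SNV-free).
#'
#' @inheritParams generate_codon_variants
#' @return list with `snvs` (data.table of records) and `contig_truth`
#'   (contig id, bin, swept flag, density used).
#' @export
generate_snvs <- function(ds, truth, cfg) {
  stopifnot(inherits(ds, "pg_dataset"))
  set.seed(stage_seed(cfg$seed, "snvs"))
  bins <- ds$bins
  rng <- cfg$snv_density_range
  density <- if (rng[1] == rng[2]) {
    rep(rng[1], nrow(bins))          # fixed density (including 0)
  } else if (rng[1] > 0) {
    10^runif(nrow(bins), log10(rng[1]), log10(rng[2]))
  } else {
    pg_config_error("log-uniform density range needs a positive lower bound")
  }
  density <- setNames(density, bins$bin_id)

  contigs <- copy(ds$contigs)
  # swept contigs are drawn among singleton-dominated contigs (genomic
  # islands), falling back to any singleton-bearing contig, then any contig
  swept_ids <- character(0)
  if (cfg$n_swept > 0) {
    singleton_cl <- truth$clusters[class == "singleton", cluster_id]
    gc <- ds$gene_calls
    frac_single <- gc[, .(fs = mean(cluster_id %in% singleton_cl)),
                      by = contig_id]
    cand <- frac_single[fs >= 0.5, contig_id]
    if (length(cand) < cfg$n_swept) {
      cand <- unique(c(cand, frac_single[fs > 0, contig_id]))
    }
    if (length(cand) < cfg$n_swept) {
      cand <- unique(c(cand, contigs$contig_id))
    }
    swept_ids <- sample(cand, min(cfg$n_swept, length(cand)))
  }
  contigs[, swept := contig_id %in% swept_ids]
  contigs[, dens := density[bin_id] * ifelse(swept, cfg$swept_multiplier, 1)]
  x <- rpois(nrow(contigs), contigs$dens * contigs$length_bp / 1000)
  x <- pmin(x, contigs$length_bp)  # cannot exceed one SNV per position
  pos <- lapply(seq_len(nrow(contigs)), function(i) {
    if (x[i] == 0L) integer(0)
    else sort(sample.int(contigs$length_bp[i], x[i])) - 1L
  })
  n_tot <- sum(x)
  ref <- sample(.CODON_BASES, n_tot, replace = TRUE)
  alt <- .CODON_BASES[((match(ref, .CODON_BASES) - 1L +
                          sample.int(3L, n_tot, replace = TRUE)) %% 4L) + 1L]
  snvs <- data.table(
    contig_id = rep(contigs$contig_id, x),
    pos0 = unlist(pos),
    ref = ref, alt = alt
  )
  contig_truth <- contigs[, .(contig_id, bin_id, length_bp, swept,
                              density_per_kbp = dens)]
  list(snvs = snvs, contig_truth = contig_truth)
}

#' Simulate a complete dataset (pangenome + codon variants + SNVs)
#'
#' Convenience wrapper chaining [generate_pangenome()],
#' [generate_codon_variants()] and [generate_snvs()].
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (fully populated [pg_dataset()]) and `truth`
#'   (`clusters`, `genes`, `contigs`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  pan <- generate_pangenome(cfg)
  cv <- generate_codon_variants(pan$dataset, pan$truth, cfg)
  sv <- generate_snvs(pan$dataset, pan$truth, cfg)
  ds <- pg_dataset(
    bins = pan$dataset$bins, contigs = pan$dataset$contigs,
    gene_calls = pan$dataset$gene_calls, clusters = pan$dataset$clusters,
    snvs = sv$snvs, codon_variants = cv,
    sequences = pan$dataset$sequences
  )
  truth <- pan$truth
  truth$contigs <- sv$contig_truth
  list(dataset = ds, truth = truth)
}

#' Write a truth table alongside a simulated dataset
#'
#' @param truth truth list from [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(truth$clusters, file.path(dir, "truth_clusters.tsv"), sep = "\t",
         na = "NA", quote = FALSE)
  fwrite(truth$genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
         na = "NA", quote = FALSE)
  if (!is.null(truth$contigs)) {
    fwrite(truth$contigs, file.path(dir, "truth_contigs.tsv"), sep = "\t",
           na = "NA", quote = FALSE)
  }
  invisible(dir)
}
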