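# Per-ORF pN/pS from single-codon variants.
#
# pN = N_obs / N_pot and pS = S_obs / S_pot, where the potential site
# counts come from Nei-Gojobori equal-weight enumeration of all single-nt
# mutants of the reference codons (see codon.R). The ratio is reported only
# when finite: ORFs without variants are "nonpolymorphic", ORFs with
# nonsynonymous but no synonymous variants are "undefined_no_syn".

#' pN/pS for one ORF
#'
#' Admits only variants flagged as covering the full codon; alternates
#' differing from the reference at more than one nucleotide are excluded
#' from counts and tallied in `n_excluded`. Reference stop codons (internal
#' stops) are excluded from the potential-site totals with a warning.
#'
#' @param orf_seq in-frame coding sequence (string over ACGT, length a
#'   multiple of 3).
#' @param variants data.table of the ORF's codon-variant records
#'   (`codon_index0`, `ref_codon`, `alt_codon`, `full_codon_coverage`).
#' @param code genetic code id (only `"standard"`).
#' @return one-row data.table: observed and potential counts, `pn`, `ps`,
#'   `pnps`, `status` (`"ok"`, `"nonpolymorphic"`, `"undefined_no_syn"`,
#'   or `"zero"` when pN = 0 with pS > 0), `n_excluded`.
#' @export
pnps <- function(orf_seq, variants, code = "standard") {
  check_standard_code(code)
  cods <- split_codons(orf_seq)
  if (!all(is_valid_codon(cods))) {
    pg_domain_error("ORF contains non-ACGT characters")
  }
  stops <- is_stop_codon(cods)
  if (any(stops)) {
    warning(sprintf("%d internal stop codon(s) excluded from site counting",
                    sum(stops)))
  }
  v <- as.data.table(variants)
  if (nrow(v)) {
    check_columns(v, "variants",
                  c("codon_index0", "ref_codon", "alt_codon",
                    "full_codon_coverage"))
    if (any(v$codon_index0 < 0L | v$codon_index0 >= length(cods))) {
      pg_integrity_error("variant codon index beyond ORF length")
    }
    if (any(v$ref_codon != cods[v$codon_index0 + 1L])) {
      pg_integrity_error("variant reference codon does not match ORF sequence")
    }
    v <- v[full_codon_coverage == TRUE]
  }
  syn_thirds <- .codon_tables$syn_thirds[cods[!stops]]
  n_sense <- sum(!stops)
  s_pot <- sum(syn_thirds) / 3
  n_pot <- 3 * n_sense - s_pot
  if (nrow(v)) {
    cls <- classify_variant_vec(v$ref_codon, v$alt_codon)
    cls[stops[v$codon_index0 + 1L]] <- "excluded"
  } else {
    cls <- character(0)
  }
  s_obs <- sum(cls == "synonymous")
  n_obs <- sum(cls == "nonsynonymous")
  n_excl <- sum(cls == "excluded")
  pn <- if (n_pot > 0) n_obs / n_pot else NA_real_
  ps <- if (s_pot > 0) s_obs / s_pot else NA_real_
  status <- if (s_obs + n_obs == 0L) "nonpolymorphic"
            else if (s_obs == 0L) "undefined_no_syn"
            else if (n_obs == 0L) "zero"
            else "ok"
  ratio <- if (status %in% c("ok", "zero")) pn / ps else NA_real_
  data.table(
    n_codons = length(cods), n_sense_codons = n_sense,
    n_obs = n_obs, s_obs = s_obs,
    n_pot = n_pot, s_pot = s_pot,
    pn = pn, ps = ps, pnps = ratio,
    status = status, n_excluded = n_excl
  )
}

#' pN/pS for every ORF of a dataset
#'
#' Vectorized application of the per-ORF computation over all ORFs with a
#' reference sequence. ORFs with no admitted variants are reported as
#' nonpolymorphic so downstream summaries can exclude them, mirroring the
#' exclusion of nonpolymorphic ORFs from ratio summaries.
#'
#' @param ds a [pg_dataset()] with `sequences` and `codon_variants`.
#' @return data.table keyed by `gene_id` with the columns of [pnps()].
#' @export
pnps_all <- function(ds) {
  stopifnot(inherits(ds, "pg_dataset"))
  if (is.null(ds$sequences)) pg_format_error("dataset has no coding sequences")
  gene_ids <- names(ds$sequences)
  seqs <- ds$sequences
  n_cod <- nchar(seqs) %/% 3L
  cods <- strsplit(gsub("(...)", "\\1 ", seqs), " ", fixed = TRUE)
  flat <- unlist(cods, use.names = FALSE)
  if (!all(is_valid_codon(flat))) {
    pg_domain_error("ORF sequences contain invalid codons")
  }
  off <- cumsum(n_cod) - n_cod
  stops_flat <- is_stop_codon(flat)
  gidx_flat <- rep(seq_along(gene_ids), n_cod)
  syn_thirds_flat <- .codon_tables$syn_thirds[flat]
  syn_thirds_flat[stops_flat] <- 0L
  n_sense <- tabulate(gidx_flat[!stops_flat], nbins = length(gene_ids))
  s_pot <- as.numeric(rowsum(as.numeric(syn_thirds_flat), gidx_flat,
                             reorder = TRUE)) / 3
  n_pot <- 3 * n_sense - s_pot

  v <- ds$codon_variants
  s_obs <- n_obs <- n_excl <- integer(length(gene_ids))
  if (!is.null(v) && nrow(v)) {
    v <- v[full_codon_coverage == TRUE]
    vg <- match(v$gene_id, gene_ids)
    if (anyNA(vg)) {
      pg_integrity_error("codon variants for ORFs without sequence",
                         ids = unique(v$gene_id[is.na(vg)]))
    }
    if (any(v$codon_index0 < 0L | v$codon_index0 >= n_cod[vg])) {
      pg_integrity_error("variant codon index beyond ORF length")
    }
    ref_from_seq <- flat[off[vg] + v$codon_index0 + 1L]
    if (any(v$ref_codon != ref_from_seq)) {
      pg_integrity_error("variant reference codon does not match ORF sequence")
    }
    cls <- classify_variant_vec(v$ref_codon, v$alt_codon)
    cls[stops_flat[off[vg] + v$codon_index0 + 1L]] <- "excluded"
    s_obs <- tabulate(vg[cls == "synonymous"], nbins = length(gene_ids))
    n_obs <- tabulate(vg[cls == "nonsynonymous"], nbins = length(gene_ids))
    n_excl <- tabulate(vg[cls == "excluded"], nbins = length(gene_ids))
  }
  pn <- ifelse(n_pot > 0, n_obs / n_pot, NA_real_)
  ps <- ifelse(s_pot > 0, s_obs / s_pot, NA_real_)
  status <- ifelse(s_obs + n_obs == 0L, "nonpolymorphic",
            ifelse(s_obs == 0L, "undefined_no_syn",
            ifelse(n_obs == 0L, "zero", "ok")))
  ratio <- ifelse(status %in% c("ok", "zero"), pn / ps, NA_real_)
  data.table(
    gene_id = gene_ids,
    n_codons = n_cod, n_sense_codons = n_sense,
    n_obs = n_obs, s_obs = s_obs,
    n_pot = n_pot, s_pot = s_pot,
    pn = pn, ps = ps, pnps = ratio,
    status = status, n_excluded = n_excl
  )
}

#' Group summaries and rank tests of pN/pS ratios
#'
#' Groups the finite ratios (statuses `"ok"` and `"zero"`) by a caller-
#' supplied label — gene frequency, MAG, or COG category — and reports per
#' group the mean, standard deviation, count, and the two-sided Wilcoxon
#' rank-sum P of that group against all other groups pooled. Groups with
#' fewer than 2 finite ratios are skipped with a notice.
#'
#' @param results a [pnps_all()] result.
#' @param grouping named character/integer vector gene_id -> group label.
#' @return data.table `group`, `n`, `mean`, `sd`, `p_wilcoxon`.
#' @export
pnps_group_stats <- function(results, grouping) {
  res <- as.data.table(results)[status %in% c("ok", "zero")]
  res[, group := as.character(grouping[gene_id])]
  res <- res[!is.na(group)]
  groups <- sort(unique(res$group))
  out <- lapply(groups, function(g) {
    x <- res[group == g, pnps]
    y <- res[group != g, pnps]
    if (length(x) < 2L) {
      message(sprintf("pnps_group_stats: group '%s' has <2 finite ratios; skipped", g))
      return(NULL)
    }
    pv <- if (length(y) < 1L) NA_real_ else ranksum_two_sided(x, y)
    data.table(group = g, n = length(x), mean = mean(x), sd = sd(x),
               p_wilcoxon = pv)
  })
  rbindlist(out)
}

# Two-sided rank-sum P. Small samples (<= max_enum assignments) are handled
# by exhaustive enumeration of group assignments on midranks, which stays
# exact under ties; larger samples use the normal approximation with tie
# correction (wilcox.test).
ranksum_two_sided <- function(x, y, max_enum = 20000) {
  n1 <- length(x); n2 <- length(y)
  if (choose(n1 + n2, n1) <= max_enum) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    mu <- n1 * (n1 + n2 + 1) / 2
    idx <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[idx], nrow = n1))
    return(mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12))
  }
  suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
}
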