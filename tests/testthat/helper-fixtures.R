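# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

suppressPackageStartupMessages(library(data.table))

# tiny hand-checkable dataset: 2 bins, 2 contigs, 3 gene calls, 2 clusters
tiny_dataset <- function() {
  pg_dataset(
    bins = data.table(
      bin_id = c("A", "B"), site = c("Axial", "MCR"),
      completeness = c(0.9, 0.8), redundancy = c(0.01, 0.02),
      total_length_bp = c(5000L, 4000L)),
    contigs = data.table(
      contig_id = c("A_c1", "B_c1"), bin_id = c("A", "B"),
      length_bp = c(5000L, 4000L), mean_coverage = c(50, 40)),
    gene_calls = data.table(
      gene_id = c("A_g1", "A_g2", "B_g1"),
      bin_id = c("A", "A", "B"),
      contig_id = c("A_c1", "A_c1", "B_c1"),
      start0 = c(0L, 1000L, 0L), stop0 = c(900L, 1900L, 900L),
      strand = c("+", "-", "+"),
      cluster_id = c("GC_1", "GC_2", "GC_1")),
    clusters = data.table(
      cluster_id = c("GC_1", "GC_2"),
      cog_function = c("COG-J family protein", "hypothetical protein"),
      cog_category = c("J", "N/A"))
  )
}

# build a pg_matrix directly from a named presence list (bin -> clusters)
matrix_from_sets <- function(sets) {
  clusters <- sort(unique(unlist(sets)))
  m <- matrix(FALSE, length(clusters), length(sets),
              dimnames = list(clusters, names(sets)))
  for (b in names(sets)) m[sets[[b]], b] <- TRUE
  structure(m, frequency = rowSums(m),
            class = c("pg_matrix", class(m)))
}

# pg_matrix with prescribed per-cluster frequencies over M bins
matrix_from_freqs <- function(f, M, bin_ids = sprintf("B%02d", seq_len(M)),
                              cluster_ids = sprintf("c%05d", seq_along(f))) {
  m <- matrix(FALSE, length(f), M, dimnames = list(cluster_ids, bin_ids))
  for (i in seq_along(f)) m[i, sample.int(M, f[i])] <- TRUE
  structure(m, frequency = rowSums(m),
            class = c("pg_matrix", class(m)))
}

# one full-default simulated dataset shared across test files (computed on
# first use; defaults are the stated world, only the seed is fixed here)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 2024L))
    cache
  }
})

# random in-frame ORF of `n_codons` sense codons plus random variants
SENSE <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
random_orf_case <- function(n_codons, n_var) {
  cods <- sample(SENSE, n_codons, replace = TRUE)
  idx <- sample.int(n_codons, n_var, replace = TRUE)
  alt <- vapply(idx, function(i) {
    repeat {
      # random alternate differing at 1 or (sometimes) 2 positions
      ch <- strsplit(cods[i], "")[[1]]
      npos <- sample(1:2, 1, prob = c(0.9, 0.1))
      for (p in sample(1:3, npos)) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
      out <- paste(ch, collapse = "")
      if (out != cods[i]) return(out)
    }
  }, character(1))
  list(
    seq = paste(cods, collapse = ""),
    variants = data.table(
      codon_index0 = idx - 1L,
      ref_codon = cods[idx],
      alt_codon = alt,
      full_codon_coverage = runif(n_var) > 0.1)
  )
}
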