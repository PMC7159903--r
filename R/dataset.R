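# Dataset container and TSV readers/writers.
#
# Canonical dialect: TSV with a header line, UTF-8, "NA" for missing values.
# Coordinates are 0-based half-open for gene calls and 0-based for SNV
# positions; the column headers state the convention.

.DATASET_SCHEMAS <- list(
  bins = c("bin_id", "site", "completeness", "redundancy", "total_length_bp"),
  contigs = c("contig_id", "bin_id", "length_bp", "mean_coverage"),
  gene_calls = c("gene_id", "bin_id", "contig_id", "start0", "stop0",
                 "strand", "cluster_id"),
  clusters = c("cluster_id", "cog_function", "cog_category"),
  snvs = c("contig_id", "pos0", "ref", "alt"),
  codon_variants = c("gene_id", "codon_index0", "ref_codon", "alt_codon",
                     "full_codon_coverage")
)

#' Construct a validated pangenome dataset
#'
#' Bundles the tabular inputs of the pipeline: genome bins (MAGs), contigs,
#' gene calls, cluster annotations, and optionally SNV records, single-codon
#' variant records, and per-ORF coding sequences. All cross-references are
#' checked at construction.
#'
#' @param bins data.frame with columns `bin_id`, `site`, `completeness`,
#'   `redundancy`, `total_length_bp`.
#' @param contigs data.frame with `contig_id`, `bin_id`, `length_bp`,
#'   `mean_coverage`.
#' @param gene_calls data.frame with `gene_id`, `bin_id`, `contig_id`,
#'   `start0`, `stop0` (0-based half-open), `strand`, `cluster_id`.
#' @param clusters data.frame with one row per (cluster, annotation):
#'   `cluster_id`, `cog_function`, `cog_category` (single letter or `"N/A"`).
#' @param snvs optional data.frame with `contig_id`, `pos0` (0-based),
#'   `ref`, `alt`.
#' @param codon_variants optional data.frame with `gene_id`, `codon_index0`,
#'   `ref_codon`, `alt_codon`, `full_codon_coverage` (logical).
#' @param sequences optional named character vector of in-frame coding
#'   sequences, names matching `gene_id`.
#' @return an object of class `pg_dataset`.
#' @export
pg_dataset <- function(bins, contigs, gene_calls, clusters,
                       snvs = NULL, codon_variants = NULL,
                       sequences = NULL) {
  ds <- structure(list(
    bins = as.data.table(bins),
    contigs = as.data.table(contigs),
    gene_calls = as.data.table(gene_calls),
    clusters = as.data.table(clusters),
    snvs = if (!is.null(snvs)) as.data.table(snvs),
    codon_variants = if (!is.null(codon_variants)) as.data.table(codon_variants),
    sequences = sequences
  ), class = "pg_dataset")
  validate_dataset(ds)
}

#' @export
print.pg_dataset <- function(x, ...) {
  cat("<pg_dataset>\n")
  cat(sprintf("  bins: %d (%s)\n", nrow(x$bins),
              paste(sprintf("%s=%d", names(table(x$bins$site)),
                            as.integer(table(x$bins$site))), collapse = ", ")))
  cat(sprintf("  contigs: %d, gene calls: %d, clusters: %d\n",
              nrow(x$contigs), nrow(x$gene_calls),
              length(unique(x$clusters$cluster_id))))
  cat(sprintf("  snvs: %s, codon variants: %s, sequences: %s\n",
              if (is.null(x$snvs)) "none" else nrow(x$snvs),
              if (is.null(x$codon_variants)) "none" else nrow(x$codon_variants),
              if (is.null(x$sequences)) "none" else length(x$sequences)))
  invisible(x)
}

check_columns <- function(tab, table_name, required) {
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    pg_format_error(
      sprintf("table '%s' is missing required column(s): %s",
              table_name, paste(missing, collapse = ", ")),
      column = missing
    )
  }
  invisible(tab)
}

validate_dataset <- function(ds) {
  for (nm in c("bins", "contigs", "gene_calls", "clusters")) {
    schema_nm <- nm
    check_columns(ds[[nm]], nm, .DATASET_SCHEMAS[[schema_nm]])
  }
  if (anyDuplicated(ds$bins$bin_id)) {
    pg_integrity_error("duplicated bin ids",
                       ids = ds$bins$bin_id[duplicated(ds$bins$bin_id)])
  }
  if (anyDuplicated(ds$contigs$contig_id)) {
    pg_integrity_error("duplicated contig ids",
                       ids = ds$contigs$contig_id[duplicated(ds$contigs$contig_id)])
  }
  bad <- setdiff(ds$contigs$bin_id, ds$bins$bin_id)
  if (length(bad)) {
    pg_integrity_error(
      sprintf("contigs reference unknown bins: %s",
              paste(head(bad, 5), collapse = ", ")), ids = bad)
  }
  gc <- ds$gene_calls
  if (nrow(gc)) {
    bad <- setdiff(gc$contig_id, ds$contigs$contig_id)
    if (length(bad)) {
      pg_integrity_error(
        sprintf("gene calls reference unknown contigs: %s",
                paste(head(bad, 5), collapse = ", ")), ids = bad)
    }
    bad <- setdiff(gc$bin_id, ds$bins$bin_id)
    if (length(bad)) {
      pg_integrity_error(
        sprintf("gene calls reference unknown bins: %s",
                paste(head(bad, 5), collapse = ", ")), ids = bad)
    }
    if (any(gc$start0 >= gc$stop0)) {
      pg_integrity_error("gene calls with start0 >= stop0",
                         ids = gc$gene_id[gc$start0 >= gc$stop0])
    }
    if (any(!nzchar(gc$cluster_id)) || anyNA(gc$cluster_id)) {
      pg_integrity_error("gene calls with empty cluster id",
                         ids = gc$gene_id[!nzchar(gc$cluster_id) | is.na(gc$cluster_id)])
    }
    clen <- ds$contigs$length_bp[match(gc$contig_id, ds$contigs$contig_id)]
    over <- gc$stop0 > clen
    if (any(over)) {
      pg_integrity_error(
        sprintf("gene spans exceed contig length: %s",
                paste(head(gc$gene_id[over], 5), collapse = ", ")),
        ids = gc$gene_id[over])
    }
  }
  if (!is.null(ds$snvs) && nrow(ds$snvs)) {
    check_columns(ds$snvs, "snvs", .DATASET_SCHEMAS$snvs)
    bad <- setdiff(ds$snvs$contig_id, ds$contigs$contig_id)
    if (length(bad)) {
      pg_integrity_error(
        sprintf("SNVs reference unknown contigs: %s",
                paste(head(bad, 5), collapse = ", ")), ids = bad)
    }
    clen <- ds$contigs$length_bp[match(ds$snvs$contig_id, ds$contigs$contig_id)]
    if (any(ds$snvs$pos0 >= clen | ds$snvs$pos0 < 0)) {
      pg_integrity_error("SNV positions outside contig",
                         ids = ds$snvs$contig_id[ds$snvs$pos0 >= clen])
    }
  }
  if (!is.null(ds$codon_variants) && nrow(ds$codon_variants)) {
    check_columns(ds$codon_variants, "codon_variants",
                  .DATASET_SCHEMAS$codon_variants)
    bad <- setdiff(ds$codon_variants$gene_id, ds$gene_calls$gene_id)
    if (length(bad)) {
      pg_integrity_error(
        sprintf("codon variants reference unknown genes: %s",
                paste(head(bad, 5), collapse = ", ")), ids = bad)
    }
  }
  ds
}

#' Write a dataset to a directory of TSV tables (and FASTA)
#'
#' Emits `bins.tsv`, `contigs.tsv`, `gene_calls.tsv`, `clusters.tsv`, and,
#' when present, `snvs.tsv`, `codon_variants.tsv` and `sequences.fasta`.
#'
#' @param ds a [pg_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "pg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("bins", "contigs", "gene_calls", "clusters",
               "snvs", "codon_variants")) {
    if (!is.null(ds[[nm]])) {
      fwrite(ds[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t",
             na = "NA", quote = FALSE)
    }
  }
  if (!is.null(ds$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ds$sequences),
      file.path(dir, "sequences.fasta"))
  }
  invisible(dir)
}

#' Load a dataset from a directory of TSV tables
#'
#' Reads the tables written by [write_dataset()] (or equivalently formatted
#' exports), cross-validates them and logs row counts. `snvs.tsv`,
#' `codon_variants.tsv` and `sequences.fasta` are optional; the pipeline
#' stages needing them are skipped when absent.
#'
#' @param dir directory containing the tables.
#' @param verbose log one line per table with its row count.
#' @return a [pg_dataset()].
#' @export
load_dataset <- function(dir, verbose = TRUE) {
  req <- function(nm) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) {
      pg_format_error(sprintf("required table not found: %s", path))
    }
    tab <- fread(path, sep = "\t", na.strings = "NA", colClasses = NULL)
    check_columns(tab, nm, .DATASET_SCHEMAS[[nm]])
    pg_log("load", sprintf("%s: %d rows", nm, nrow(tab)), verbose = verbose)
    tab
  }
  opt <- function(nm) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) return(NULL)
    req(nm)
  }
  seqs <- NULL
  fasta <- file.path(dir, "sequences.fasta")
  if (file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- setNames(as.character(ss), names(ss))
    pg_log("load", sprintf("sequences: %d", length(seqs)), verbose = verbose)
  }
  pg_dataset(
    bins = req("bins"), contigs = req("contigs"),
    gene_calls = req("gene_calls"), clusters = req("clusters"),
    snvs = opt("snvs"), codon_variants = opt("codon_variants"),
    sequences = seqs
  )
}

# strict equality across all tables and sequences, used by round-trip tests
#' @method all.equal pg_dataset
#' @export
all.equal.pg_dataset <- function(target, current, ...) {
  msgs <- character(0)
  for (nm in c("bins", "contigs", "gene_calls", "clusters",
               "snvs", "codon_variants")) {
    a <- target[[nm]]; b <- current[[nm]]
    if (is.null(a) != is.null(b)) {
      msgs <- c(msgs, sprintf("%s: presence differs", nm)); next
    }
    if (!is.null(a)) {
      eq <- all.equal(as.data.frame(a), as.data.frame(b),
                      check.attributes = FALSE)
      if (!isTRUE(eq)) msgs <- c(msgs, sprintf("%s: %s", nm, paste(eq, collapse = "; ")))
    }
  }
  if (!identical(is.null(target$sequences), is.null(current$sequences)) ||
      (!is.null(target$sequences) &&
       !identical(target$sequences[order(names(target$sequences))],
                  current$sequences[order(names(current$sequences))]))) {
    msgs <- c(msgs, "sequences differ")
  }
  if (length(msgs)) msgs else TRUE
}
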