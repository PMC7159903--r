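# Genetic-code machinery for pN/pS site counting and variant classification.
#
# Conventions fixed here (documented in the methods vignette):
#  * standard genetic code; start codons are treated as ordinary codons
#  * potential synonymous sites per codon = (number of the 9 single-nt
#    mutants that preserve the amino acid) / 3, Nei-Gojobori equal weights;
#    paths to stop codons count as nonsynonymous, so syn + nonsyn = 3 per
#    sense codon
#  * reference stop codons are excluded from site totals (with a warning)

.CODON_BASES <- c("A", "C", "G", "T")

.codon_tables <- local({
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  # all 9 single-nucleotide mutants per codon
  mutants <- lapply(codons, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    out <- character(0)
    for (posn in 1:3) {
      for (b in setdiff(.CODON_BASES, ch[posn])) {
        m <- ch
        m[posn] <- b
        out <- c(out, paste(m, collapse = ""))
      }
    }
    out
  })
  names(mutants) <- codons
  syn_thirds <- vapply(codons, function(cod) {
    if (code[[cod]] == "*") return(NA_integer_)
    sum(code[mutants[[cod]]] == code[[cod]])
  }, integer(1))
  syn_neighbors <- lapply(codons, function(cod) {
    if (code[[cod]] == "*") return(character(0))
    m <- mutants[[cod]]
    m[code[m] == code[[cod]]]
  })
  names(syn_neighbors) <- codons
  nonsyn_neighbors <- lapply(codons, function(cod) {
    if (code[[cod]] == "*") return(character(0))
    m <- mutants[[cod]]
    m[code[m] != code[[cod]]]
  })
  names(nonsyn_neighbors) <- codons
  list(code = code, codons = codons, syn_thirds = syn_thirds,
       syn_neighbors = syn_neighbors, nonsyn_neighbors = nonsyn_neighbors)
})

is_valid_codon <- function(codon) {
  is.character(codon) & nchar(codon) == 3L &
    !is.na(match(codon, .codon_tables$codons))
}

is_stop_codon <- function(codon) {
  unname(.codon_tables$code[codon] == "*")
}

#' Potential synonymous and nonsynonymous sites of a codon
#'
#' Counts, for each of the three codon positions, the fraction of the three
#' possible single-nucleotide mutants that preserve the encoded amino acid
#' (Nei-Gojobori equal-weight site counting). The two fractions sum to 3 for
#' every sense codon; mutational paths to stop codons are counted as
#' nonsynonymous.
#'
#' @param codon a 3-character string over A/C/G/T.
#' @param code genetic code identifier; only `"standard"` is supported.
#' @return named numeric vector `c(syn = , nonsyn = )`; `NA`s with a warning
#'   for a reference stop codon.
#' @examples
#' potential_sites("TTT")  # c(syn = 1/3, nonsyn = 8/3)
#' potential_sites("ATG")  # Met has no synonymous neighbor: c(0, 3)
#' @export
potential_sites <- function(codon, code = "standard") {
  check_standard_code(code)
  if (length(codon) != 1L || !is_valid_codon(codon)) {
    pg_domain_error(sprintf("invalid codon '%s': must be a 3-mer over ACGT",
                            paste(codon, collapse = ",")))
  }
  if (is_stop_codon(codon)) {
    warning(sprintf("reference stop codon %s excluded from site counting",
                    codon))
    return(c(syn = NA_real_, nonsyn = NA_real_))
  }
  s <- .codon_tables$syn_thirds[[codon]] / 3
  c(syn = s, nonsyn = 3 - s)
}

check_standard_code <- function(code) {
  if (!identical(code, "standard")) {
    pg_domain_error("only the standard genetic code is supported")
  }
  invisible(code)
}

#' Classify a single-codon variant
#'
#' A variant is synonymous iff reference and alternate codons translate to
#' the same amino acid. Alternates that differ from the reference at more
#' than one nucleotide are excluded (not decomposed into mutational paths).
#' Alternates introducing a stop codon are classified nonsynonymous, the
#' convention matching the potential-site enumeration where paths to stops
#' count as nonsynonymous sites.
#'
#' @param ref_codon,alt_codon 3-character codon strings, distinct.
#' @inheritParams potential_sites
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"excluded"`.
#' @export
classify_variant <- function(ref_codon, alt_codon, code = "standard") {
  check_standard_code(code)
  if (!is_valid_codon(ref_codon) || !is_valid_codon(alt_codon)) {
    pg_domain_error("codons must be 3-mers over ACGT")
  }
  if (ref_codon == alt_codon) {
    pg_domain_error("reference and alternate codon are identical")
  }
  classify_variant_vec(ref_codon, alt_codon)
}

# vectorized core, no validation (callers validate)
classify_variant_vec <- function(ref, alt) {
  nd <- codon_hamming(ref, alt)
  aa_ref <- .codon_tables$code[ref]
  aa_alt <- .codon_tables$code[alt]
  out <- ifelse(nd > 1L, "excluded",
                ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous"))
  # a reference stop codon cannot be scored
  out[aa_ref == "*"] <- "excluded"
  unname(out)
}

codon_hamming <- function(a, b) {
  (substr(a, 1, 1) != substr(b, 1, 1)) +
    (substr(a, 2, 2) != substr(b, 2, 2)) +
    (substr(a, 3, 3) != substr(b, 3, 3))
}

# split an in-frame sequence into its codons
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 3L || n %% 3L != 0L) {
    pg_domain_error("ORF length must be a positive multiple of 3")
  }
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}
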