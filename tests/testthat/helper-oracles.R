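# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and its lookup tables where feasible) so that agreement is a
# genuine cross-check, not a tautology.

# lower-tail binomial CDF by term-by-term summation
oracle_binom_cdf <- function(k, n, p) {
  sum(vapply(0:k, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# lower-tail Poisson CDF by term recurrence
oracle_ppois <- function(x, lambda) {
  if (lambda == 0) return(1)
  term <- exp(-lambda)
  acc <- term
  i <- 0
  while (i < x) {
    i <- i + 1
    term <- term * lambda / i
    acc <- acc + term
  }
  acc
}

ORACLE_CODE <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

# number of the 9 single-nt mutants of a codon preserving the amino acid
# (integer "thirds": potential synonymous sites = value / 3)
oracle_syn_thirds <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- ORACLE_CODE[[codon]]
  cnt <- 0L
  for (pos in 1:3) {
    for (b in BASES) {
      if (b == ch[pos]) next
      mut <- ch
      mut[pos] <- b
      if (ORACLE_CODE[[paste(mut, collapse = "")]] == aa) cnt <- cnt + 1L
    }
  }
  cnt
}

# full per-ORF pN/pS by exhaustive enumeration, integer arithmetic until
# the final division
oracle_pnps <- function(orf_seq, variants) {
  n <- nchar(orf_seq)
  cods <- substring(orf_seq, seq(1, n - 2, 3), seq(3, n, 3))
  sense <- ORACLE_CODE[cods] != "*"
  s_thirds <- sum(vapply(cods[sense], oracle_syn_thirds, integer(1)))
  s_pot <- s_thirds / 3
  n_pot <- 3 * sum(sense) - s_pot
  s_obs <- n_obs <- n_excl <- 0L
  if (nrow(variants)) {
    v <- variants[variants$full_codon_coverage, , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      ref <- v$ref_codon[i]; alt <- v$alt_codon[i]
      diffs <- sum(strsplit(ref, "")[[1]] != strsplit(alt, "")[[1]])
      if (diffs > 1 || ORACLE_CODE[[ref]] == "*" ||
          !sense[v$codon_index0[i] + 1]) {
        n_excl <- n_excl + 1L
      } else if (ORACLE_CODE[[ref]] == ORACLE_CODE[[alt]]) {
        s_obs <- s_obs + 1L
      } else {
        n_obs <- n_obs + 1L
      }
    }
  }
  pn <- n_obs / n_pot
  ps <- s_obs / s_pot
  list(n_obs = n_obs, s_obs = s_obs, n_pot = n_pot, s_pot = s_pot,
       pn = pn, ps = ps,
       pnps = if (s_obs > 0) pn / ps else NA_real_,
       n_excluded = n_excl)
}

# naive average-linkage (UPGMA) agglomeration returning the cophenetic
# distance matrix; ties broken by the lexicographically smallest pair
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  groups <- as.list(labs)
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  active <- seq_along(groups)
  while (length(active) > 1) {
    best <- NULL; best_val <- Inf
    for (i in active) for (j in active) {
      if (i >= j) next
      val <- mean(d[groups[[i]], groups[[j]]])
      key <- paste(min(groups[[i]][1], groups[[j]][1]),
                   max(groups[[i]][1], groups[[j]][1]))
      if (val < best_val - 1e-12 ||
          (abs(val - best_val) <= 1e-12 && !is.null(best) &&
           key < best$key)) {
        best <- list(i = i, j = j, key = key); best_val <- val
      }
    }
    for (a in groups[[best$i]]) for (b in groups[[best$j]]) {
      coph[a, b] <- coph[b, a] <- best_val
    }
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    active <- setdiff(active, best$j)
  }
  coph
}

# Poisson-binomial pmf over counts 0..n by dynamic-programming convolution
oracle_poisbinom_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

# exact Welch t-test from first principles
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}
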