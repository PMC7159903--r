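#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions: format errors name the offending column, integrity
# errors carry the offending ids, so callers and tests can match on class.
pg_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pangevo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pg_format_error <- function(msg, column = NULL) {
  pg_error("pangevo_format_error", msg, column = column)
}

pg_integrity_error <- function(msg, ids = NULL) {
  pg_error("pangevo_integrity_error", msg, ids = ids)
}

pg_domain_error <- function(msg) pg_error("pangevo_domain_error", msg)

pg_config_error <- function(msg) pg_error("pangevo_config_error", msg)

#' Derive a stage-local random seed from a global seed
#'
#' One global seed drives the whole pipeline; each named stage gets a
#' deterministic substream so that adding or reordering stages does not
#' perturb the draws of other stages. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed for the stage.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

pg_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[pangevo:%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

# stable hash of a configuration list for provenance stamping (no external
# digest dependency; serialization is version-pinned for reproducibility)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # FNV-1a style mix kept within 31 bits (bitwXor needs integers)
  h <- 21661361L
  for (b in as.integer(raw)) {
    h <- bitwXor(h, b)
    h <- as.integer((as.numeric(h) * 16777619) %% 2147483647)
  }
  sprintf("%08x", h)
}

# all permutations of 1..n as a list (n small; used by exhaustive modes)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  j <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in sub) {
      j <- j + 1L
      out[[j]] <- c(first, rest[s])
    }
  }
  out
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    pg_config_error(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}
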