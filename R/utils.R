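# Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Single master seed fans out to per-stage seeds so that each pipeline
#' stage is independently reproducible. Kept below 2^31 - 1.
#' @noRd
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (abs(as.integer(seed)) %% 1000003L) * 1009L + as.integer(stage)
}

#' Evaluate an expression under a local RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Polynomial rolling hash of a character scalar, as 8 hex digits
#'
#' Used to stamp outputs with a provenance hash of the configuration.
#' @noRd
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Check probabilities sum to one
#' @noRd
check_prob_row <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("invalid probability row for '%s': entries must be >= 0 and sum to 1", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Draw categorical samples from per-row probability tables, vectorized
#'
#' @param prob matrix, one row per parent configuration, columns = levels.
#' @param row integer vector of configuration indices, one per draw.
#' @return integer level indices.
#' @noRd
sample_rows <- function(prob, row) {
  n <- length(row)
  cum <- t(apply(prob, 1L, cumsum))
  u <- stats::runif(n)
  1L + rowSums(u > cum[row, , drop = FALSE])
}
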