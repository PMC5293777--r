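# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic generators in the package draw their randomness from a single
#' spec-level seed. Sub-streams (one per rendered object) are derived
#' deterministically so that regenerating any one object does not depend on the
#' order in which the others were generated.
#'
#' @param seed Master integer seed.
#' @param stream Integer stream index (>= 0).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  # Weyl-style mixing in double precision; exact for inputs < 2^31.
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + (as.numeric(stream) + 1) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(s %% (m - 1L) + 1)
}

#' Evaluate an expression with a local RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard error of the mean
#' @param x Numeric vector; `NA` dropped.
#' @return `sd(x)/sqrt(n)`; `NA` for n < 2.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Tissue / eye / group vocabularies used across the package.
TISSUES <- c("SC", "ONH", "RETINA")
EYES <- c("SALINE", "MICROBEAD")
GROUPS <- c("VEHICLE", "HE20", "HE100")
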