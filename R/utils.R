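# Internal helpers shared across modules.

NUCLEOTIDES <- c("A", "C", "G", "T")

TRAIT_SCALES <- c("continuous", "log_continuous", "log_odds", "absolute_risk")

# 95% normal multiplier used everywhere except Egger (which is t-based).
Z95 <- 1.959964

#' @noRd
complement_allele <- function(x) chartr("ACGT", "TGCA", x)

#' @noRd
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' @noRd
stage_log <- function(stage, n_in, n_out, t0 = NULL) {
  elapsed <- if (is.null(t0)) NA_real_ else as.numeric(proc.time()[["elapsed"]] - t0)
  message(sprintf("[%s] n_in=%d n_out=%d elapsed=%.3fs", stage, n_in, n_out, elapsed))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
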