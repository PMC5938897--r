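#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's random stream. All randomness in this package flows through
#' explicit seeds via this helper.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

stop_updown <- function(class, msg, ...) {
  stop(structure(class = c(class, "updown_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# FNV-1a 32-bit over a character scalar; cheap content fingerprint for
# lexicon/layout sidecars (not cryptographic). The multiply by the prime
# 16777619 is done in 16-bit halves so every intermediate stays below 2^53.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; h itself exceeds
    # .Machine$integer.max so it is kept as a double throughout
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * p) %% 65536 * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
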