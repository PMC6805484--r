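# Internal helpers shared across modules.

# Evaluate `code` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed, kept within 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Convert Phred quality strings to integer scores
#'
#' Decodes Sanger-encoded (ASCII offset 33) quality strings.
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_phred <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(s + 33L)), character(1))
}

# Right-open running mean of width w with truncated windows at the edges:
# position i averages indices (i - floor((w-1)/2)) .. (i + ceiling((w-1)/2)),
# clipped to the vector.
running_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  left <- floor((w - 1) / 2)
  right <- w - 1 - left
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
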