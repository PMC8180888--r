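#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames quantile sd lm coef predict
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never disturb the global
# random stream.
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1009) %% 2147483647)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp artifacts with the configuration that produced them.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; keep h as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, in doubles
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + (hi16 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Hash a configuration object
#'
#' Stable 32-bit content hash of any R object (via its canonical JSON
#' serialisation, numbers at 12 significant digits so values survive a
#' YAML round trip). Artifacts written by the pipeline carry this hash so
#' that re-runs can detect configuration changes.
#'
#' @param x An R object (typically a configuration list).
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(12), force = TRUE))
}
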