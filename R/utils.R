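# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators do
#' not disturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

# abort with a consistent prefix; used for user input errors
wa_stop <- function(...) stop(paste0(...), call. = FALSE)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    wa_stop("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) wa_stop("`", name, "` must be > 0")
  invisible(x)
}

#' FNV-1a hash of a character string
#'
#' Tiny dependency-free hash used to stamp output sidecars with a config
#' fingerprint. Not cryptographic.
#'
#' @param x character scalar.
#' @return hex string.
#' @keywords internal
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  # 32-bit FNV-1a in double arithmetic (exact below 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a 32-bit value held in a double with a byte
bitwXor_dbl <- function(h, b) {
  lo <- h %% 2^31
  hi <- h %/% 2^31
  xored <- bitwXor(as.integer(lo), as.integer(b))
  hi * 2^31 + (as.numeric(xored) %% 2^31)
}
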