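# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation internals never disturb
#' the caller's random stream.
#' @noRd
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
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and integer tags
#'
#' Deterministic multiplicative-congruential fold of the tag sequence;
#' result is always a valid 32-bit seed.
#' @noRd
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) {
    h <- (h * 48271 + as.numeric(v) + 11) %% 2147483629
  }
  as.integer(h)
}

#' @noRd
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant series", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' @noRd
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

#' @noRd
is_scalar <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x > min
}
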