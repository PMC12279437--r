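#' Derive a child seed from a master seed and a stream label
#'
#' All stochastic operations in the package draw their seeds through this
#' helper so that a single master seed deterministically fans out into
#' independent streams (per population, per replicate, per stage).  The
#' derivation is a simple multiplicative string hash folded into the
#' 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param master integer master seed.
#' @param ... further labels (character or integer) identifying the stream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "ancestral")
#' derive_seed(1, "derived", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1)
  labels <- c(as.character(as.integer(master)), vapply(list(...), as.character, ""))
  h <- 0
  m <- 2147483629  # largest prime < 2^31
  for (tok in labels) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 131 + code) %% m
    }
    h <- (h * 131 + 7) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x))) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(x)
}
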