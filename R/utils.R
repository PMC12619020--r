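#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that stages can be re-run independently yet reproducibly.
#' The result is always a valid 32-bit R integer seed.
#'
#' @param seed integer root seed.
#' @param tag character label of the substream (e.g. `"labels"`, `"run3"`).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% m
  }
  ## two mixing rounds; every product stays below 2^53 so the doubles are
  ## exact and distinct seeds never collapse onto one substream
  x <- (abs(seed) %% m)
  x <- (x * 48271 + h) %% m
  x <- (x * 69621 + h + 1) %% m
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## assert a scalar probability
check_prob <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name = deparse(substitute(x)), min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

## seconds since local midnight for a POSIXct-free representation:
## times in this package are stored as numeric seconds within a day, and
## dates as "Date" objects; this avoids timezone arithmetic entirely.
hms <- function(h, m = 0, s = 0) h * 3600 + m * 60 + s
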