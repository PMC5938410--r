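#' @keywords internal
"_PACKAGE"

#' @useDynLib mlsmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm median pt qnorm rbinom rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

# Derive a named 32-bit substream seed from a master seed so that, e.g.,
# changing the permutation count never perturbs the simulation stream.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mlsmap <- function(...) stop(sprintf(...), call. = FALSE)

warn_mlsmap <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}
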