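#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rbinom rlnorm rnbinom runif setNames p.adjust
#' @importFrom utils read.table write.table
NULL

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

# derive a stream of child seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
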