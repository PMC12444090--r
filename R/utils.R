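#' @keywords internal
#' @useDynLib adaptsize, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

utils::globalVariables(c("sample_count", "value", "characteristic"))

# Classed conditions so callers can distinguish failure modes programmatically.
abort_adaptsize <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "adaptsize_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Deterministic integer mixing for per-(size, instance, block) RNG streams.
# All arithmetic stays below 2^53 so doubles are exact; result is in
# [0, 2^31 - 2] and therefore a valid `set.seed()` argument.
mix_seed <- function(...) {
  v <- c(...)
  h <- 0
  for (x in v) {
    h <- (h * 1000003 + (abs(as.numeric(x)) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
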