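#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state seeded from `seed`, restoring the caller's
# state afterwards so package functions never clobber user RNG streams.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Kept below 2^31 so the result is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

stopifnot_matrix <- function(x, what = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  }
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

geometric_mean <- function(v) {
  if (any(v < 0)) stop("geometric mean requires non-negative values", call. = FALSE)
  if (any(v == 0)) return(0)
  exp(mean(log(v)))
}
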