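# Internal helpers shared across modules.

# Clip x into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a per-stream seed from a global seed so that adding a stream never
# perturbs the draws of another. Kept below .Machine$integer.max.
stream_seed <- function(seed, stream) {
  (as.numeric(seed) %% 1e9) * 2 + 1 + 97003 * stream_id(stream)
}

stream_id <- function(stream) {
  ids <- c(fractions = 1, ages = 2, map = 3, beta = 4, counts = 5,
           pairing = 6, boot = 7, perm = 8, modules = 9)
  if (!stream %in% names(ids)) stop("unknown RNG stream: ", stream)
  unname(ids[[stream]])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Round half-up to `digits` decimals (report style: 58.35 -> 58.4).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Column medians of a numeric matrix (rows = items, cols = samples is the
# caller's concern; this is plain per-column median).
col_medians <- function(m) apply(m, 2, stats::median)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}
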