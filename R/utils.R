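# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## All user-facing stochastic entry points funnel through this so that a
## NULL seed leaves the caller's RNG stream alone while an integer seed
## gives bit-identical output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a base seed and a stream label,
## kept below 2^31 (R integers are 32-bit).
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "/")
  as.integer(sum(utf8ToInt(key) * (31L^(seq_along(utf8ToInt(key)) %% 7L))) %% 2147483629) + 1L
}

## Hyndman-Fan type-7 quantile (R's default), isolated so the quantile
## definition used for empirical thresholds sits behind one function.
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
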