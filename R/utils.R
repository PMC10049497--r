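#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded helpers behave as pure functions.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Deterministic sub-stream seed for (n, rep) so adding replicates never
# perturbs earlier drawings. Kept strictly below 2^31.
substream_seed <- function(seed, n, rep) {
  s <- (as.double(seed) * 2654435761 + as.double(n) * 975661 +
          as.double(rep) * 7919) %% 2147483629
  as.integer(s)
}

stopifnot_scalar_prob <- function(x, name, open_lower = TRUE, open_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > 0 else x >= 0) &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a single value in %s0,1%s", name,
                        if (open_lower) "(" else "[",
                        if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
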