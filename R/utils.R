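# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the current RNG stream" (no save/restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a reproducible stream of sub-seeds (< 2^31) from one seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

stage_levels <- function() c("HC", "SMC", "EMCI", "LMCI", "AD")
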