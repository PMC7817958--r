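# Internal helpers: seed streams, argument checks.

# Deterministic sub-seed for a labelled generator stream. Adding a new stream
# label never perturbs draws of existing streams because each stream reseeds
# from its own label hash.
sub_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  # keep arithmetic well inside 2^53 so the modulo is exact
  as.integer((h * 2654435 + as.numeric(seed)) %% (2^31 - 1))
}

# Evaluate `expr` under a seeded RNG state, restoring the caller's stream.
with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, label))
  expr
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be probabilities in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  invisible(x)
}

# Sample from a named categorical distribution.
sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
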