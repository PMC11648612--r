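# Internal helpers shared across modules.

# Run `expr` under a deterministic RNG state without disturbing the caller's
# stream. Seeds must stay below 2^31 - 1 (R integers are 32-bit).
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
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
  set.seed(seed)
  expr
}

# Counter-based sub-seed so surrogate i is reproducible independently of the
# order in which surrogates are generated.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index)) %%
               (.Machine$integer.max - 1L)) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Nearest-rank (type-1) empirical quantile; the fixed convention for all
# surrogate band quantiles.
quantile1 <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 1, names = FALSE))
}

sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}
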