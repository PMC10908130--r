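# Internal helpers shared across modules.

#' Derive a component seed from a master seed
#'
#' A single run seed expands deterministically into independent per-component
#' seeds (corpus generation, phase-1 sampling, model fitting, oracle error,
#' baselines) so that one integer reproduces an entire run.  The derivation is
#' a fixed affine-mod hash of the master seed and a component tag; results are
#' always in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the component (e.g. `"oracle"`).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 69621 + 12345) %% 2147483645 + 1)
}

# run expr under a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# normalize text for duplicate detection: lowercase, collapse whitespace
normalize_text <- function(x) {
  x <- tolower(ifelse(is.na(x), "", x))
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
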