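# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so seeded package functions do not perturb the
#' caller's random stream. `seed = NULL` evaluates `code` unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a master seed and a stage label.
# Keeps sub-stage streams independent while remaining a pure function of
# (seed, label). Result fits in a 32-bit signed integer.
derive_seed <- function(seed, label) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Coerce to an unstranded, sorted-seqlevel GRanges without metadata surprises.
as_unstranded <- function(x) {
  stopifnot(is(x, "GRanges"))
  strand(x) <- "*"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
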