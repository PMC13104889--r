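#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' seeded package internals never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in a run flows from one master seed; each named stage gets
#' its own derived seed so artifacts are independently reproducible. The
#' derivation is a fixed affine map kept within the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  offsets <- c(predictions = 101L, features = 211L, annotations = 307L,
               folds = 401L, forest = 503L, embedding = 601L,
               representatives = 701L, acceptance = 811L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
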