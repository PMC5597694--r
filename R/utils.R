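#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed for the duration of \code{expr} and restores the global
#' RNG state afterwards, so seeded computations never perturb the caller's
#' random stream. A NULL seed evaluates \code{expr} unseeded.
#'
#' @param seed integer seed or NULL
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive an independent sub-seed from a base seed and a stream id
#'
#' A small deterministic hash so every named computation consumes its own
#' seed stream: adding streams never perturbs earlier ones. Result is in
#' [1, 2^31 - 2].
#'
#' @param seed base integer seed
#' @param id character stream identifier
#' @export
derive_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(id))
  m <- 2147483647
  h <- (abs(seed) %% m)
  for (c in utf8ToInt(paste(id, collapse = "/"))) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 1) + 1)
}
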