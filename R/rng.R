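#' Derive a reproducible sub-seed from a root seed and a stream tag
#'
#' Every stochastic operation in the package draws from its own RNG
#' substream, derived deterministically from one root seed plus a short
#' text tag naming the operation.  This keeps independent stages (tree
#' simulation, retention sampling, noise draws, ...) decoupled: changing
#' the number of draws in one stage does not shift any other stage.
#'
#' @param seed Integer root seed.
#' @param tag Character scalar naming the substream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "tree") != derive_seed(1, "noise")
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes) * 131)
  # all intermediates stay far below 2^53, so double arithmetic is exact
  as.integer((abs(seed) %% 2147483647 * 69069 + h * 7919 + 12345) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}
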