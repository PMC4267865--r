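#' Derive a stage-specific child seed from a root seed
#'
#' All generators in the package are pure functions of their inputs and a
#' seed.  A pipeline run uses one root seed; each stage (tree, status,
#' traits, plots, grid, ...) draws its own child seed so that stages can be
#' re-run independently and still reproduce the same output.  The
#' derivation is a fixed affine hash of the stage name modulo 2^31 - 1,
#' so child seeds stay within R's integer range.
#'
#' @param seed integer root seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "tree")
#' child_seed(1, "traits")
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  m <- 2147483647
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's
# state afterwards so generators do not disturb the global RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
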