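#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific seed from a root seed
#'
#' All stochastic stages of the pipeline draw their randomness from a single
#' root seed through this splitting rule, so that each stage is reproducible
#' in isolation: the stage name is hashed to an integer offset (sum of UTF-8
#' codes weighted by position) and combined with the root seed modulo
#' 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed usable with [set.seed()].
#' @export
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(seed) + h * 7919) %% (2^31 - 1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# p-value adjusted by Benjamini-Hochberg, preserving NA.
bh <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
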