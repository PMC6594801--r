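#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm rpois rbinom runif pt pchisq quantile setNames
#' @importFrom utils read.csv write.csv combn
NULL

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Derive an independent 32-bit substream seed from a master seed and a stage
# name. Stages hash their name so adding a stage never shifts another
# stage's stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 1009)
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
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

stop_teanet <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_teanet(what, " contains non-finite values")
  invisible(x)
}
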