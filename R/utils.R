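#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All stochastic stages of the pipeline draw their randomness from one master
#' seed. Sub-seeds are derived by a stable string hash of the identifying
#' labels (pair, fly, protocol, repeat index, stage name), so a simulated
#' repeat does not depend on the order in which repeats are generated.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer((h + (abs(master) %% 65536) * 30269 + 7) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Trapezoidal integral of y over x (uniform or not).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
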