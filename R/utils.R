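#' Derive a reproducible sub-seed from a base seed and labels
#'
#' All randomness in the package flows from a single user-supplied integer
#' seed. Stage-, task- and round-specific seeds are derived by mixing the
#' base seed with string/integer labels through a multiplicative congruential
#' hash, so that independent components get independent, reproducible RNG
#' streams and the stream of one task does not depend on how many other tasks
#' are trained alongside it.
#'
#' @param seed Integer base seed.
#' @param ... Labels (strings or integers) identifying the consumer.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "split")
#' derive_seed(1, "task", "GENE07")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  h <- (abs(as.double(seed)) %% m)
  for (part in list(...)) {
    codes <- if (is.character(part)) {
      unlist(lapply(part, utf8ToInt))
    } else {
      as.double(part)
    }
    for (v in codes) {
      h <- (h * 48271 + abs(v) + 17) %% m
    }
  }
  as.integer(max(1, h))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

abort_velonet <- function(msg, class = "velonet_error") {
  rlang::abort(msg, class = class)
}
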