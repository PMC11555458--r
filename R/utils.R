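## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded components do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## Derive a child seed from a parent seed and a stage tag, staying inside
## 32-bit integer range. Deterministic and stable across platforms.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert <- function(ok, ...) if (!isTRUE(ok)) stop2(...)
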