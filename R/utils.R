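# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All exported stochastic entry points go
# through this so that a single integer seed pins down every draw.
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derived seeds for repetition r of a run seeded with `seed`, kept inside
# the 32-bit integer range.
derive_seed <- function(seed, r) {
  as.integer((as.double(seed) + as.double(r)) %% 2147483647)
}

check_number <- function(x, name, min = -Inf, allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, format(min)))
  }
  invisible(x)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' throughout to score recovery of planted clusters and to quantify residual
#' batch structure. Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\]; 1 means identical partitions up to
#'   renaming, 0 is the chance level.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same length.")
  }
  mclust::adjustedRandIndex(a, b)
}
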