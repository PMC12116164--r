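#' @keywords internal
"_PACKAGE"

# Unified organ label space used by both phenological stages.
# 0 = background, 1 = flower, 2 = fruit (bagged), 3 = leaf, 4 = branch/trunk.
ORGAN_LABELS <- c(background = 0L, flower = 1L, fruit = 2L, leaf = 3L, branch = 4L)

#' Organ label ids
#'
#' Returns the unified 5-label space shared by flowering and young-fruit
#' scenes: background, flower, fruit, leaf, branch.
#'
#' @return Named integer vector of label ids.
#' @export
organ_labels <- function() ORGAN_LABELS

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_bad_arg(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < lower || x > upper) {
    stop_bad_arg(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
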