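## Internal helpers shared across modules.

#' @importFrom stats rnorm runif predict
#' @importFrom utils read.csv write.csv write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min))
    stop(sprintf("`%s` must be a single finite number %s %s", name,
                 if (strict) ">" else ">=", format(min)), call. = FALSE)
  as.numeric(x)
}

# argmax with deterministic smallest-index tie-break
which_max_first <- function(x) which(x == max(x))[1L]

# Column-wise Euclidean norms of a matrix.
col_norms <- function(A) sqrt(colSums(A^2))
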