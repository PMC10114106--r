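# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so package calls do not perturb user-level randomness.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  set.seed(as.integer(seed))
  force(code)
}

# stopifnot() with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced, optionally stratified fold assignment.  Depends only on
# (seed, n, k, strata): identical across runs by construction.
make_folds <- function(n, k, seed, strata = NULL) {
  fail_if(k > n, "number of folds k = %d exceeds n = %d", k, n)
  fail_if(k < 3, "at least 3 folds are required (k = %d)", k)
  folds <- integer(n)
  with_seed(seed, {
    if (is.null(strata)) strata <- rep(1L, n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}
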