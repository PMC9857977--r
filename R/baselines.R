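#' Baseline sorters
#'
#' `identity_sort()` returns the input ordering unchanged (the "unsorted"
#' baseline). `random_sort()` shuffles the rows with a seeded generator and
#' leaves the columns fixed — the random-shuffling control used in the
#' synthetic benchmarks.
#'
#' @param bm a [binmat].
#' @param seed integer seed for the row shuffle (`random_sort` only).
#' @return a [sort_result].
#' @export
identity_sort <- function(bm) {
  validate_binmat(unclass(bm))
  sort_result("identity", rownames(bm), colnames(bm),
              source = matrix_fingerprint(bm))
}

#' @rdname identity_sort
#' @export
random_sort <- function(bm, seed = NULL) {
  validate_binmat(unclass(bm))
  ro <- with_seed(seed, sample(rownames(bm)))
  sort_result("random", ro, colnames(bm), source = matrix_fingerprint(bm))
}

# Evaluate code with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
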