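#' MEMo-style row ordering: decreasing marginal
#'
#' Rows sorted by decreasing number of non-zero entries; ties keep the
#' original row order (stable sort).
#'
#' @param bm a [binmat].
#' @return a character vector: the row ids in sorted order.
#' @export
memo_row_order <- function(bm) {
  validate_binmat(unclass(bm))
  rs <- rowSums(bm)
  rownames(bm)[order(-rs, seq_along(rs), method = "radix")]
}

#' MEMo-style column key: the column pattern in binary notation
#'
#' The column's 0/1 pattern, read top-to-bottom under `row_order`, as a
#' character string of bits. Comparing two keys lexicographically (C locale)
#' is equivalent to comparing the big integers
#' `sum_i B[i,s] * 2^(n - i)` (top row most significant), for any number of
#' rows and without overflow: the keys have equal length, and `"1" > "0"`
#' at the first differing position decides both comparisons.
#'
#' @param bm a [binmat].
#' @param row_order character vector: a permutation of `rownames(bm)`.
#' @param s a column id.
#' @return a character scalar, e.g. `"101"`.
#' @export
memo_col_key <- function(bm, row_order, s) {
  M <- unclass(bm)
  if (!setequal(row_order, rownames(M)) || length(row_order) != nrow(M))
    stop("row_order is not a permutation of the matrix row ids", call. = FALSE)
  paste0(M[match(row_order, rownames(M)), s], collapse = "")
}

#' MEMo matrix sorting
#'
#' The matrix-sorting procedure of the MEMo tool, used here as a comparator:
#' rows are ordered by decreasing marginal ([memo_row_order()]); columns are
#' then ordered by decreasing value of their 0/1 pattern interpreted as a
#' number in binary notation with the top row as the most significant bit
#' ([memo_col_key()]). Non-zero entries in high rows thus pull a column
#' leftwards ("waterfall" layout). Ties on both axes keep original order;
#' the procedure is deterministic.
#'
#' @param bm a [binmat].
#' @return a [sort_result] with `method = "memo"`.
#' @export
memo_sort <- function(bm) {
  validate_binmat(unclass(bm))
  M <- unclass(bm)
  ro <- memo_row_order(bm)
  P <- M[match(ro, rownames(M)), , drop = FALSE]
  keys <- apply(P, 2L, paste0, collapse = "")
  co <- colnames(M)[order(keys, seq_along(keys), method = "radix",
                          decreasing = c(TRUE, FALSE))]
  sort_result("memo", ro, co, source = matrix_fingerprint(bm))
}
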