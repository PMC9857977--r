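#' Construct a binary matrix
#'
#' A `binmat` is an integer matrix whose entries are all 0 or 1, with unique
#' row identifiers (genes/features) and unique column identifiers
#' (samples/patients). It is the object every sorting algorithm and score in
#' this package consumes and produces. Marginals are always derived from the
#' entries, never stored.
#'
#' @param x a matrix (numeric, integer or logical) of 0/1 values. Logical
#'   matrices are mapped `TRUE` -> 1, `FALSE` -> 0.
#' @param row_ids,col_ids optional character vectors of unique identifiers.
#'   Default to existing dimnames, or positional labels (`"R1"..."Rn"`,
#'   `"C1"..."Cm"`) when the input is unnamed.
#' @return an object of class `binmat` (an integer matrix with dimnames).
#' @examples
#' b <- binmat(rbind(g1 = c(1, 1, 0, 0), g2 = c(0, 0, 1, 1)),
#'             col_ids = paste0("s", 1:4))
#' marginals(b, "rows")
#' @export
binmat <- function(x, row_ids = NULL, col_ids = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.logical(x)) storage.mode(x) <- "integer"
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("dimension error: binary matrix must have at least one row and one column",
         call. = FALSE)
  if (is.null(row_ids)) row_ids <- rownames(x)
  if (is.null(col_ids)) col_ids <- colnames(x)
  if (is.null(row_ids)) row_ids <- paste0("R", seq_len(nrow(x)))
  if (is.null(col_ids)) col_ids <- paste0("C", seq_len(ncol(x)))
  storage.mode(x) <- "integer"
  dimnames(x) <- list(as.character(row_ids), as.character(col_ids))
  validate_binmat(x)
  class(x) <- c("binmat", class(matrix()))
  x
}

#' @rdname binmat
#' @export
is_binmat <- function(x) inherits(x, "binmat")

#' Validate the binary-matrix invariants
#'
#' Checks that the matrix is non-empty, strictly 0/1 with no missing values,
#' and that row and column identifiers are present and pairwise distinct.
#' Called by every constructor and by [read_matrix()]; exposed for users
#' assembling matrices by hand.
#'
#' @param x a matrix.
#' @return `x`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_binmat <- function(x) {
  if (!is.matrix(x)) stop("not a matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("dimension error: binary matrix must have at least one row and one column",
         call. = FALSE)
  bad <- which(is.na(x) | !(x == 0L | x == 1L))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("non-binary entry at row '%s', column '%s'",
                 rn_or_pos(rownames(x), i), rn_or_pos(colnames(x), j)),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("row and column identifiers are required", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate row identifier: '%s'",
                 rownames(x)[duplicated(rownames(x))][1L]), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate column identifier: '%s'",
                 colnames(x)[duplicated(colnames(x))][1L]), call. = FALSE)
  invisible(x)
}

rn_or_pos <- function(nm, i) if (is.null(nm)) as.character(i) else nm[i]

#' @export
print.binmat <- function(x, ...) {
  cat(sprintf("binary matrix: %d rows (genes) x %d columns (samples), %d non-zero (density %.4g)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  y <- unclass(x)
  print(y[seq_len(min(10L, nrow(y))), seq_len(min(10L, ncol(y))), drop = FALSE], ...)
  if (nrow(x) > 10L || ncol(x) > 10L) cat("...\n")
  invisible(x)
}

#' Row or column marginal totals
#'
#' Counts of non-zero entries per row or per column. The sum over rows always
#' equals the sum over columns (total number of 1s).
#'
#' @param bm a [binmat].
#' @param axis `"rows"` or `"cols"`.
#' @return a named integer vector.
#' @export
marginals <- function(bm, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  validate_binmat(unclass(bm))
  s <- if (axis == "rows") rowSums(bm) else colSums(bm)
  storage.mode(s) <- "integer"
  s
}

#' Read a binary matrix from a delimited text file
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers (a leading corner cell above the gene-id column is tolerated).
#' Cell tokens `0`, `1`, `TRUE`, `FALSE` are accepted case-insensitively and
#' mapped to 0/1. With `no_names = TRUE`, the file is treated as a bare table
#' of tokens and rows/columns are named by position (`"R1"..."Rn"`,
#' `"C1"..."Cm"`).
#'
#' @param path path to a UTF-8 delimited text file.
#' @param delimiter field separator, default TAB.
#' @param no_names if `TRUE`, the file has no header row and no row-id column.
#' @return a [binmat].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, delimiter = "\t", no_names = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (!length(lines)) stop("dimension error: empty file", call. = FALSE)
  parts <- strsplit(lines, delimiter, fixed = TRUE)

  if (no_names) {
    widths <- lengths(parts)
    if (length(unique(widths)) != 1L)
      stop(sprintf("format error: ragged rows (line %d has %d fields, expected %d)",
                   which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L],
                   widths[1L]), call. = FALSE)
    row_ids <- paste0("R", seq_along(parts))
    col_ids <- paste0("C", seq_len(widths[1L]))
    cells <- parts
  } else {
    if (length(parts) < 2L)
      stop("dimension error: no data rows below the header", call. = FALSE)
    header <- parts[[1L]]
    body <- parts[-1L]
    widths <- lengths(body)
    if (length(unique(widths)) != 1L)
      stop(sprintf("format error: ragged rows (line %d has %d fields, expected %d)",
                   which(widths != widths[1L])[1L] + 1L,
                   widths[widths != widths[1L]][1L], widths[1L]), call. = FALSE)
    w <- widths[1L]
    if (length(header) == w) header <- header[-1L]   # corner cell present
    if (length(header) != w - 1L)
      stop(sprintf("format error: header has %d fields but data rows have %d",
                   length(header), w), call. = FALSE)
    row_ids <- vapply(body, `[`, character(1L), 1L)
    col_ids <- header
    cells <- lapply(body, `[`, -1L)
  }

  n <- length(cells); m <- length(col_ids)
  if (m < 1L) stop("dimension error: matrix has no columns", call. = FALSE)
  ent <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    tok <- toupper(cells[[i]])
    v <- ifelse(tok %in% c("1", "TRUE"), 1L, ifelse(tok %in% c("0", "FALSE"), 0L, NA_integer_))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("parse error: non-binary token '%s' at row '%s', column '%s'",
                   cells[[i]][j], row_ids[i], col_ids[j]), call. = FALSE)
    }
    ent[i, ] <- v
  }
  binmat(ent, row_ids = row_ids, col_ids = col_ids)
}

#' Write a binary matrix to a delimited text file
#'
#' Writes a header row of column identifiers (with a leading empty corner
#' cell) and one row per gene, first field the row identifier. The output
#' round-trips through [read_matrix()] bit-exactly.
#'
#' @param bm a [binmat].
#' @param path output file path.
#' @param delimiter field separator, default TAB.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(bm, path, delimiter = "\t") {
  validate_binmat(unclass(bm))
  utils::write.table(unclass(bm), file = path, sep = delimiter, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Construct a sort result
#'
#' A `sort_result` couples a row permutation and a column permutation of a
#' binary matrix with the name of the method that produced them and a
#' structural fingerprint of the input, so an ordering can be stored,
#' exchanged and re-applied.
#'
#' @param method one of `"mutex"`, `"memo"`, `"random"`, `"identity"`.
#' @param row_order character vector: a permutation of the matrix row ids.
#' @param col_order character vector: a permutation of the matrix column ids.
#' @param source optional fingerprint of the input matrix (see
#'   [matrix_fingerprint()]).
#' @return an object of class `sort_result`.
#' @export
sort_result <- function(method = c("mutex", "memo", "random", "identity"),
                        row_order, col_order, source = NULL) {
  method <- match.arg(method)
  row_order <- as.character(row_order); col_order <- as.character(col_order)
  if (anyDuplicated(row_order) || anyDuplicated(col_order))
    stop("orders must not contain duplicated identifiers", call. = FALSE)
  structure(list(method = method, row_order = row_order,
                 col_order = col_order, source = source),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("sort_result [%s]: %d rows, %d columns%s\n", x$method,
              length(x$row_order), length(x$col_order),
              if (is.null(x$source)) "" else paste0(" (input ", x$source, ")")))
  cat(" rows: ", paste(utils::head(x$row_order, 8L), collapse = ", "),
      if (length(x$row_order) > 8L) ", ..." else "", "\n", sep = "")
  cat(" cols: ", paste(utils::head(x$col_order, 8L), collapse = ", "),
      if (length(x$col_order) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Structural fingerprint of a binary matrix
#'
#' A short provenance string (dimensions, number of non-zero entries and a
#' positional checksum) recorded in [sort_result] objects so that an ordering
#' can be matched to the matrix it was computed on. It is a lightweight
#' integrity aid, not a cryptographic hash.
#'
#' @param bm a [binmat].
#' @return a character scalar.
#' @export
matrix_fingerprint <- function(bm) {
  v <- which(unclass(bm) == 1L)
  chk <- if (length(v)) sum((v %% 65521) * (seq_along(v) %% 251)) %% 100000007 else 0
  sprintf("%dx%d:%d:%d", nrow(bm), ncol(bm), length(v), chk)
}

#' Apply a sort result to a binary matrix
#'
#' Reorders rows and columns of `bm` according to `r`, so that
#' `output[i, j] == bm[r$row_order[i], r$col_order[j]]`. The multiset of
#' entries and the row/column marginals are conserved under the id mapping.
#'
#' @param bm a [binmat].
#' @param r a [sort_result] whose orders are permutations of `bm`'s ids.
#' @return the permuted [binmat].
#' @export
permute_matrix <- function(bm, r) {
  validate_binmat(unclass(bm))
  if (!inherits(r, "sort_result")) stop("r must be a sort_result", call. = FALSE)
  if (!setequal(r$row_order, rownames(bm)) ||
      length(r$row_order) != nrow(bm))
    stop("row_order is not a permutation of the matrix row ids", call. = FALSE)
  if (!setequal(r$col_order, colnames(bm)) ||
      length(r$col_order) != ncol(bm))
    stop("col_order is not a permutation of the matrix column ids", call. = FALSE)
  out <- unclass(bm)[r$row_order, r$col_order, drop = FALSE]
  class(out) <- class(bm)
  out
}

#' Serialize a sort result
#'
#' `write_sort_result()` writes either a JSON object (`format = "json"`) or a
#' two-section plain-text file (`format = "text"`: a `[rows]` section listing
#' the ordered row ids one per line, then a `[cols]` section).
#' `read_sort_result()` reads both formats back.
#'
#' @param r a [sort_result].
#' @param path output file path.
#' @param format `"json"` or `"text"`.
#' @return `path` (write) or a [sort_result] (read).
#' @export
write_sort_result <- function(r, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(method = r$method, row_order = r$row_order,
                              col_order = r$col_order, source = r$source),
                         path, auto_unbox = TRUE, null = "null")
  } else {
    writeLines(c(sprintf("# method: %s", r$method),
                 sprintf("# source: %s", if (is.null(r$source)) "NA" else r$source),
                 "[rows]", r$row_order, "[cols]", r$col_order), path)
  }
  invisible(path)
}

#' @rdname write_sort_result
#' @export
read_sort_result <- function(path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(sort_result(x$method, x$row_order, x$col_order,
                       source = if (is.null(x$source)) NULL else x$source))
  }
  lines <- readLines(path)
  method <- sub("^# method: ", "", lines[grepl("^# method: ", lines)][1L])
  src <- sub("^# source: ", "", lines[grepl("^# source: ", lines)][1L])
  body <- lines[!grepl("^#", lines)]
  ri <- which(body == "[rows]"); ci <- which(body == "[cols]")
  sort_result(method, body[(ri + 1L):(ci - 1L)], body[(ci + 1L):length(body)],
              source = if (identical(src, "NA")) NULL else src)
}
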