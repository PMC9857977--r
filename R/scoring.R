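#' Overall mutual-exclusivity coverage score of a (row-ordered) matrix
#'
#' The comparison score used to rate how well a row ordering exposes mutual
#' exclusivity. Genes are visited top to bottom in the matrix's current row
#' order; the current gene g is scored with the best-in-class exclusive
#' coverage over the remaining genes and samples,
#' `sum_{s in S_r}(B[g,s] - sum_{g' in G_r, g' != g} B[g',s])`, then g and
#' every remaining sample in which g is mutated are removed. The overall
#' score is the sum of the gene scores; it can be negative, and larger is
#' better. It depends only on the row order (column order never enters), so
#' it is a pure row-ordering quality score.
#'
#' @param bm a [binmat]; its current row order is the order being scored.
#' @param variant `"printed"` (default) or `"restricted"`, see
#'   [best_in_class_score()].
#' @return an integer score.
#' @examples
#' b <- binmat(diag(3), row_ids = paste0("g", 1:3), col_ids = paste0("s", 1:3))
#' overall_me_coverage(b)  # n - n(n-1)/2 = 0 for the 3x3 identity
#' @export
overall_me_coverage <- function(bm, variant = c("printed", "restricted")) {
  variant <- match.arg(variant)
  validate_binmat(unclass(bm))
  M <- unclass(bm)
  n <- nrow(M); m <- ncol(M)
  unc_s <- rep(TRUE, m)
  cov <- rowSums(M)                 # per-gene coverage of the remaining samples
  total <- 0
  for (i in seq_len(n)) {
    if (variant == "printed") {
      total <- total + 2 * cov[i] - sum(cov[i:n])
    } else {
      cs <- colSums(M[i:n, unc_s, drop = FALSE])
      total <- total + sum((2 - cs)[M[i, unc_s] == 1L])
    }
    newly <- which(unc_s & M[i, ] == 1L)
    if (length(newly)) {
      unc_s[newly] <- FALSE
      cov <- cov - rowSums(M[, newly, drop = FALSE])
    }
  }
  as.integer(total)
}

#' Empirical joint Shannon entropy of two binary vectors
#'
#' Plug-in estimate of the joint entropy of the paired binary variables, in
#' nats: `H = -sum_{(a,b) in {0,1}^2} p(a,b) log p(a,b)` with `0 log 0 = 0`
#' and `p` the empirical cell frequencies. Bounded by `log(4)`; symmetric in
#' its arguments. For a fixed pair of marginals it is maximal under
#' independence, and strictly larger for column-disjoint supports than for
#' identical supports — which is what makes it able to separate mutually
#' exclusive from co-occurring gene pairs of comparable frequency.
#'
#' @param x,y binary (0/1 or logical) vectors of equal length >= 1.
#' @return a non-negative numeric scalar (nats).
#' @examples
#' joint_entropy(c(1, 1, 0, 0), c(1, 1, 0, 0))  # log(2)
#' joint_entropy(c(1, 0, 0, 0), c(0, 1, 0, 0))  # ~1.0397, exclusivity
#' @export
joint_entropy <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (!length(x)) stop("vectors must be non-empty", call. = FALSE)
  x <- as.integer(x); y <- as.integer(y)
  if (anyNA(x) || anyNA(y) || any(x > 1L | x < 0L | y > 1L | y < 0L))
    stop("x and y must be binary", call. = FALSE)
  p <- tabulate(1L + x + 2L * y, nbins = 4L) / length(x)
  -sum(p[p > 0] * log(p[p > 0]))
}

#' Mean pairwise joint entropy among the top rows of a sorted matrix
#'
#' Applies the row order of `sortres` (if given) to `bm`, takes the first `k`
#' rows and computes [joint_entropy()] for each of the `choose(k, 2)`
#' unordered row pairs. A sorting method that places genuinely mutually
#' exclusive genes of comparable frequency at the top yields a larger mean
#' than one that places co-occurring genes there.
#'
#' @param bm a [binmat].
#' @param sortres optional [sort_result]; `NULL` scores `bm`'s current order.
#' @param k number of top rows to consider, `2 <= k <= nrow(bm)`.
#' @return a list with elements `mean` (numeric scalar) and `pairs`
#'   (data.frame with columns `gene1`, `gene2`, `entropy`).
#' @export
topk_pair_entropy <- function(bm, sortres = NULL, k = 10L) {
  validate_binmat(unclass(bm))
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(bm)) stop("k exceeds the number of rows", call. = FALSE)
  M <- unclass(bm)
  if (!is.null(sortres)) M <- M[sortres$row_order, , drop = FALSE]
  top <- M[seq_len(k), , drop = FALSE]
  idx <- utils::combn(k, 2L)
  ent <- vapply(seq_len(ncol(idx)), function(p)
    joint_entropy(top[idx[1L, p], ], top[idx[2L, p], ]), numeric(1L))
  list(mean = mean(ent),
       pairs = data.frame(gene1 = rownames(top)[idx[1L, ]],
                          gene2 = rownames(top)[idx[2L, ]],
                          entropy = ent, stringsAsFactors = FALSE))
}

#' Run and overlap diagnostics
#'
#' A run is a maximal block of consecutive non-zero entries within one row.
#' `run_stats()` reports, per row, the number of runs and their mean length
#' (`NA` for all-zero rows), plus the total consecutive-row overlap: the
#' number of (row i, row i+1, column j) triples with both entries non-zero.
#' Mutual-exclusivity sorting aims at few, long runs and small overlap; these
#' are diagnostics of a layout, not quantities any sorter optimizes directly.
#'
#' @param bm a [binmat].
#' @return an object of class `run_stats`: a list with `per_row` (data.frame
#'   `row_id`, `n_runs`, `mean_run_length`) and `overlap` (integer).
#' @export
run_stats <- function(bm) {
  validate_binmat(unclass(bm))
  M <- unclass(bm)
  per <- lapply(seq_len(nrow(M)), function(i) {
    r <- rle(M[i, ])
    len <- r$lengths[r$values == 1L]
    c(n = length(len), mean = if (length(len)) mean(len) else NA_real_)
  })
  per <- do.call(rbind, per)
  overlap <- if (nrow(M) > 1L)
    sum(M[-nrow(M), , drop = FALSE] * M[-1L, , drop = FALSE]) else 0L
  structure(list(per_row = data.frame(row_id = rownames(M),
                                      n_runs = as.integer(per[, "n"]),
                                      mean_run_length = per[, "mean"],
                                      stringsAsFactors = FALSE),
                 overlap = as.integer(overlap)),
            class = "run_stats")
}

#' @export
print.run_stats <- function(x, ...) {
  cat(sprintf("run statistics: %d rows, consecutive-row overlap %d\n",
              nrow(x$per_row), x$overlap))
  print(utils::head(x$per_row, 10L), ...)
  if (nrow(x$per_row) > 10L) cat("...\n")
  invisible(x)
}

#' Rank gene pairs by their position in a sorted matrix
#'
#' For each pair of row ids, reports the worse (maximum) of the two 1-based
#' positions in `sortres$row_order` — a pair is only visible "in the top k
#' rows" when both members are there — and whether that best rank is within
#' the top `k`. Pairs with a member absent from the matrix are flagged
#' missing and excluded from top-k counts, not treated as errors.
#'
#' @param sortres a [sort_result].
#' @param pairs a two-column character matrix or data.frame of row ids; extra
#'   columns are ignored.
#' @param k the top-row cutoff (default 25).
#' @return a data.frame with columns `gene1`, `gene2`, `rank1`, `rank2`,
#'   `best_rank`, `in_top_k`, `missing`.
#' @export
rank_pairs <- function(sortres, pairs, k = 25L) {
  if (!inherits(sortres, "sort_result")) stop("sortres must be a sort_result", call. = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs))
    return(data.frame(gene1 = character(), gene2 = character(),
                      rank1 = integer(), rank2 = integer(),
                      best_rank = integer(), in_top_k = logical(),
                      missing = logical(), stringsAsFactors = FALSE))
  g1 <- as.character(pairs[[1L]]); g2 <- as.character(pairs[[2L]])
  r1 <- match(g1, sortres$row_order); r2 <- match(g2, sortres$row_order)
  missing <- is.na(r1) | is.na(r2)
  best <- pmax(r1, r2)
  data.frame(gene1 = g1, gene2 = g2, rank1 = r1, rank2 = r2,
             best_rank = best, in_top_k = !missing & best <= k,
             missing = missing, stringsAsFactors = FALSE)
}
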