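#' Best-in-class exclusive-coverage score of a gene
#'
#' Phase-1 selection score of the mutual-exclusivity sorting heuristic. For an
#' uncovered gene g, the score sums, over all uncovered samples s, the entry
#' `B[g,s]` minus the entries of every other uncovered gene in s:
#'
#'   score(g) = sum_{s in S} ( B[g,s] - sum_{g' in G, g' != g} B[g',s] )
#'
#' where G and S are the uncovered gene and sample sets. The score can be
#' negative. Algebraically it equals `2*cov(g) - T`, where `cov(g)` is the
#' number of uncovered samples in which g is mutated and `T` the total number
#' of 1s in the uncovered submatrix; the subtracted mass is therefore
#' constant in g, and the argmax coincides with the argmax of `cov(g)`.
#'
#' With `variant = "restricted"` the penalty runs only over the samples in
#' which g itself is mutated (the phase-2 reading of exclusive coverage):
#' `score_r(g) = sum_{s: B[g,s]=1} (1 - sum_{g' != g} B[g',s])`. This variant
#' is a documented alternative, not the default.
#'
#' @param bm a [binmat].
#' @param g an uncovered row id.
#' @param uncovered_genes,uncovered_samples character vectors of currently
#'   uncovered row/column ids (both must be non-empty, and contain `g`
#'   respectively be valid column ids).
#' @param variant `"printed"` (default) or `"restricted"`.
#' @return an integer score (possibly negative).
#' @export
best_in_class_score <- function(bm, g, uncovered_genes, uncovered_samples,
                                variant = c("printed", "restricted")) {
  variant <- match.arg(variant)
  if (!g %in% uncovered_genes)
    stop(sprintf("gene '%s' is not in the uncovered set", g), call. = FALSE)
  if (!length(uncovered_samples)) stop("no uncovered samples", call. = FALSE)
  sub <- unclass(bm)[uncovered_genes, uncovered_samples, drop = FALSE]
  others <- colSums(sub) - sub[g, ]
  if (variant == "printed") {
    as.integer(sum(sub[g, ] - others))
  } else {
    as.integer(sum((1L - others)[sub[g, ] == 1L]))
  }
}

#' Phase 1: greedy best-in-class row ordering
#'
#' Repeatedly selects the uncovered gene with the maximal
#' [best_in_class_score()] (ties broken by original row position), appends it
#' to the covered-gene vector and marks as covered every uncovered sample in
#' which it is mutated. When uncovered samples run out before genes, the
#' remaining genes are appended in their original order.
#'
#' Internally the selection uses the identity `score = 2*cov - T` (the
#' penalty term is constant across candidates), so each iteration picks the
#' gene covering the most uncovered samples; the loop stops as soon as the
#' maximal coverage is zero, because from that point the uncovered submatrix
#' is all-zero and the printed loop would append the remaining genes in
#' original order anyway — the same output as the leftover rule.
#'
#' @param bm a [binmat].
#' @param variant see [best_in_class_score()].
#' @return a character vector: the row ids in covered order (a permutation of
#'   `rownames(bm)`).
#' @export
select_rows <- function(bm, variant = c("printed", "restricted")) {
  variant <- match.arg(variant)
  validate_binmat(unclass(bm))
  M <- unclass(bm)
  n <- nrow(M); m <- ncol(M)
  unc_g <- rep(TRUE, n); unc_s <- rep(TRUE, m)
  cov <- rowSums(M)                      # coverage of uncovered samples, per gene
  out <- integer(n); k <- 0L

  while (any(unc_g) && any(unc_s)) {
    if (variant == "printed") {
      sc <- cov                          # argmax(2*cov - T) == argmax(cov)
    } else {
      cs <- numeric(m); cs[unc_s] <- colSums(M[unc_g, unc_s, drop = FALSE])
      sc <- as.vector(M[, unc_s, drop = FALSE] %*% (2 - cs[unc_s]))
    }
    if (max(cov[unc_g]) == 0L) break     # uncovered submatrix is all-zero
    sc[!unc_g] <- -Inf
    g <- which.max(sc)                   # first maximum = smallest original index
    k <- k + 1L; out[k] <- g; unc_g[g] <- FALSE
    newly <- which(unc_s & M[g, ] == 1L)
    if (length(newly)) {
      unc_s[newly] <- FALSE
      cov <- cov - rowSums(M[, newly, drop = FALSE])
    }
  }
  leftover <- which(unc_g)               # original order
  rownames(M)[c(out[seq_len(k)], leftover)]
}

#' Phase-2 exclusive coverage of a sample with respect to a gene
#'
#' Per-column score used to order the samples claimed by a gene:
#'
#'   L_s = B[g,s] * (1 - sum_{g' in gene_queue, g' != g} B[g',s])
#'
#' It is 0 whenever g is not mutated in s, 1 when g is the only queued gene
#' mutated in s, and negative when several other queued genes are.
#'
#' @param bm a [binmat].
#' @param g a row id, member of `gene_queue`.
#' @param s a column id.
#' @param gene_queue character vector of row ids (the phase-1 output).
#' @return an integer score.
#' @export
sample_exclusive_coverage <- function(bm, g, s, gene_queue) {
  if (!g %in% gene_queue)
    stop(sprintf("gene '%s' is not in the gene queue", g), call. = FALSE)
  M <- unclass(bm)
  others <- sum(M[gene_queue, s]) - M[g, s]
  as.integer(M[g, s] * (1L - others))
}

#' Phase 2: exclusive-coverage column ordering
#'
#' All samples start uncovered. For each gene in `gstar` order (while
#' uncovered samples remain), the uncovered samples in which the gene is
#' mutated are sorted by decreasing [sample_exclusive_coverage()] (ties by
#' original column position), appended to the output and marked covered.
#' Samples never claimed by any gene (e.g. all-zero columns) are appended
#' last in original order. This phase maximizes run lengths: each gene's
#' samples become contiguous, with its exclusively-mutated samples first.
#'
#' @param bm a [binmat].
#' @param gstar character vector: a permutation of `rownames(bm)` (the
#'   phase-1 covered-gene order).
#' @return a character vector: the column ids in final order.
#' @export
order_columns <- function(bm, gstar) {
  validate_binmat(unclass(bm))
  M <- unclass(bm)
  if (!setequal(gstar, rownames(M)) || length(gstar) != nrow(M))
    stop("gstar is not a permutation of the matrix row ids", call. = FALSE)
  m <- ncol(M)
  coltot <- colSums(M)                   # queue = all genes; sum_{g'!=g} = coltot - 1 on candidates
  unc_s <- rep(TRUE, m)
  L <- integer(0)
  for (g in match(gstar, rownames(M))) {
    if (!any(unc_s)) break
    cand <- which(unc_s & M[g, ] == 1L)
    if (!length(cand)) next
    # L_s = 2 - coltot[s] on candidates: decreasing L_s == increasing coltot
    cand <- cand[order(coltot[cand], seq_along(cand))]
    L <- c(L, cand)
    unc_s[cand] <- FALSE
  }
  colnames(M)[c(L, which(unc_s))]
}

#' Mutual-exclusivity sorting of a binary matrix
#'
#' The full two-phase heuristic: greedy best-in-class row ordering
#' ([select_rows()]) followed by per-gene exclusive-coverage column ordering
#' ([order_columns()]). The result reorders rows and columns so that runs of
#' consecutive non-zero entries are long and overlap as little as possible
#' vertically, visually exposing mutual-exclusivity trends. The procedure is
#' fully deterministic. Time complexity is O(n^2 m + n m log m) for an
#' n-gene, m-sample matrix.
#'
#' @param bm a [binmat].
#' @param variant see [best_in_class_score()].
#' @return a [sort_result] with `method = "mutex"`.
#' @examples
#' b <- binmat(rbind(g1 = c(1, 1, 0, 0), g2 = c(0, 0, 1, 1), g3 = c(1, 0, 1, 0)),
#'             col_ids = paste0("s", 1:4))
#' r <- mutex_sort(b)
#' permute_matrix(b, r)
#' @export
mutex_sort <- function(bm, variant = c("printed", "restricted")) {
  variant <- match.arg(variant)
  ro <- select_rows(bm, variant = variant)
  co <- order_columns(bm, ro)
  sort_result("mutex", ro, co, source = matrix_fingerprint(bm))
}
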