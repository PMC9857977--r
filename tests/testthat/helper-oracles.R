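# Fixtures and independent brute-force oracles used across the suite.
# Oracles evaluate the defining formulas literally (explicit loops over the
# printed sums), independently of the package's incremental implementations.

fixture_3x4 <- function() {
  binmat(rbind(g1 = c(1, 1, 0, 0),
               g2 = c(0, 0, 1, 1),
               g3 = c(1, 0, 1, 0)),
         col_ids = paste0("s", 1:4))
}

identity_bm <- function(n) {
  binmat(diag(n), row_ids = paste0("g", seq_len(n)),
         col_ids = paste0("s", seq_len(n)))
}

# Literal evaluation of the phase-1 best-in-class sum:
#   sum_{s in S} ( B[g,s] - sum_{g' in G, g' != g} B[g',s] )
oracle_bic <- function(M, g, G, S) {
  tot <- 0L
  for (s in S) {
    pen <- 0L
    for (gp in G) if (gp != g) pen <- pen + M[gp, s]
    tot <- tot + M[g, s] - pen
  }
  tot
}

# Literal evaluation of the phase-2 per-sample score:
#   L_s = B[g,s] * (1 - sum_{g' in Q, g' != g} B[g',s])
oracle_ls <- function(M, g, s, Q) {
  pen <- 0L
  for (gp in Q) if (gp != g) pen <- pen + M[gp, s]
  M[g, s] * (1L - pen)
}

# Straight-from-the-formulas trace of the whole two-phase heuristic, using
# only the literal oracles above (no coverage identity, no incremental state).
oracle_mutex_sort <- function(bm) {
  M <- unclass(bm)
  genes <- rownames(M); samples <- colnames(M)
  G <- genes; S <- samples; gstar <- character(0)
  while (length(G) && length(S)) {
    sc <- vapply(G, function(g) oracle_bic(M, g, G, S), numeric(1))
    g <- G[which.max(sc)]                       # ties: first in original order
    gstar <- c(gstar, g)
    G <- setdiff(G, g)
    S <- setdiff(S, samples[M[g, ] == 1L & samples %in% S])
  }
  gstar <- c(gstar, G)                          # leftover genes, original order
  S <- samples; L <- character(0)
  for (g in gstar) {
    if (!length(S)) break
    cand <- S[M[g, S] == 1L]
    if (!length(cand)) next
    ls <- vapply(cand, function(s) oracle_ls(M, g, s, gstar), numeric(1))
    cand <- cand[order(-ls, match(cand, samples))]
    L <- c(L, cand)
    S <- setdiff(S, cand)
  }
  list(row_order = gstar, col_order = c(L, S))
}

# Literal evaluation of the overall mutual-exclusivity coverage score:
# visit rows top to bottom, score with oracle_bic over the remaining
# submatrix, then delete the gene and its remaining mutated samples.
oracle_coverage <- function(bm) {
  M <- unclass(bm)
  G <- rownames(M); S <- colnames(M); total <- 0L
  for (g in rownames(M)) {
    total <- total + oracle_bic(M, g, G, S)
    S <- S[!(M[g, S] == 1L)]
    G <- setdiff(G, g)
  }
  total
}

# Exact big-integer value of a column pattern in binary notation, top row
# most significant. Exact in double precision for n <= 30.
oracle_memo_value <- function(bits) sum(bits * 2^(rev(seq_along(bits)) - 1))

expect_same_sort <- function(a, b) {
  expect_identical(a$row_order, b$row_order)
  expect_identical(a$col_order, b$col_order)
}
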