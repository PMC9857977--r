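test_that("best-in-class score matches hand-evaluated cases", {
  b <- fixture_3x4()
  expect_identical(best_in_class_score(b, "g1", rownames(b), colnames(b)), -2L)
  expect_identical(best_in_class_score(b, "g2", c("g2", "g3"), c("s3", "s4")), 1L)

  single <- binmat(matrix(c(1L, 0L, 1L), 1, 3,
                          dimnames = list("g1", paste0("s", 1:3))))
  expect_identical(best_in_class_score(single, "g1", "g1", colnames(single)), 2L)

  expect_error(best_in_class_score(b, "g1", c("g2", "g3"), colnames(b)),
               "not in the uncovered set")
})

test_that("best-in-class score and argmax agree with the literal formula on random matrices", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    bm <- random_bm(n, m, runif(1, 0.1, 0.7))
    M <- unclass(bm)
    for (j in 1:15) {
      G <- sample(rownames(M), sample(seq_len(n), 1))
      S <- sample(colnames(M), sample(seq_len(m), 1))
      sc_pkg <- vapply(G, function(g) best_in_class_score(bm, g, G, S), integer(1))
      sc_orc <- vapply(G, function(g) oracle_bic(M, g, G, S), numeric(1))
      expect_equal(unname(sc_pkg), unname(sc_orc))
      # the penalty term is constant in g, so argmax == argmax of coverage
      cov <- vapply(G, function(g) sum(M[g, S]), numeric(1))
      expect_identical(which.max(sc_orc), which.max(cov))
    }
  }
})

test_that("phase-1 row selection follows the greedy covering trace", {
  expect_identical(select_rows(fixture_3x4()), c("g1", "g2", "g3"))
  expect_identical(select_rows(identity_bm(5)), paste0("g", 1:5))

  # an all-zero row can never be best-in-class while a non-zero uncovered row
  # and uncovered samples remain: it lands in the leftover block
  set.seed(33)
  for (i in 1:10) {
    M <- matrix(rbinom(30, 1, 0.5), 5, 6)
    M[3, ] <- 0L
    M[1, 1] <- 1L   # at least one non-zero row
    bm <- binmat(M, row_ids = paste0("g", 1:5), col_ids = paste0("s", 1:6))
    expect_identical(select_rows(bm), oracle_mutex_sort(bm)$row_order)
  }
})

test_that("phase-2 sample scores match hand-evaluated cases", {
  b <- fixture_3x4()
  q <- rownames(b)
  expect_identical(sample_exclusive_coverage(b, "g1", "s2", q), 1L)
  expect_identical(sample_exclusive_coverage(b, "g1", "s1", q), 0L)
  expect_identical(sample_exclusive_coverage(b, "g2", "s1", q), 0L)  # B[g,s]=0 gate
  set.seed(8)
  bm <- random_bm(6, 6, 0.5)
  M <- unclass(bm)
  for (g in rownames(M)) for (s in colnames(M))
    expect_equal(sample_exclusive_coverage(bm, g, s, rownames(M)),
                 oracle_ls(M, g, s, rownames(M)))
})

test_that("phase-2 column ordering claims, sorts and appends leftovers", {
  b <- fixture_3x4()
  expect_identical(order_columns(b, c("g1", "g2", "g3")), c("s2", "s1", "s4", "s3"))
  expect_identical(order_columns(identity_bm(4), paste0("g", 1:4)), paste0("s", 1:4))

  withzero <- binmat(cbind(unclass(b), s5 = c(0L, 0L, 0L)))
  co <- order_columns(withzero, select_rows(withzero))
  expect_identical(co[5], "s5")  # all-zero column appended last
})

test_that("mutex_sort reproduces the hand-traced fixture and fixed points", {
  b <- fixture_3x4()
  r <- mutex_sort(b)
  expect_identical(r$row_order, c("g1", "g2", "g3"))
  expect_identical(r$col_order, c("s2", "s1", "s4", "s3"))
  p <- permute_matrix(b, r)
  expect_identical(unname(p["g1", ]), c(1L, 1L, 0L, 0L))
  expect_identical(unname(p["g2", ]), c(0L, 0L, 1L, 1L))
  expect_identical(unname(p["g3", ]), c(0L, 1L, 0L, 1L))

  for (n in c(1, 3, 6)) {
    idm <- identity_bm(n)
    ri <- mutex_sort(idm)
    expect_identical(ri$row_order, rownames(idm))
    expect_identical(ri$col_order, colnames(idm))
  }
})

test_that("mutex_sort equals an independent straight-from-the-formulas trace", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(2:7, 1); m <- sample(2:9, 1)
    bm <- random_bm(n, m, runif(1, 0.05, 0.9))
    r <- mutex_sort(bm)
    o <- oracle_mutex_sort(bm)
    expect_identical(r$row_order, o$row_order)
    expect_identical(r$col_order, o$col_order)
  }
})

test_that("rows with pairwise disjoint supports end with one run each and zero overlap", {
  # exhaustive over all assignments of m columns to {row1, row2, neither},
  # both rows non-empty; then spot-grid for 3 rows
  for (m in 2:6) {
    grids <- expand.grid(rep(list(0:2), m))
    for (gi in seq_len(nrow(grids))) {
      a <- as.integer(grids[gi, ] == 1); bvec <- as.integer(grids[gi, ] == 2)
      if (!sum(a) || !sum(bvec)) next
      bm <- binmat(rbind(g1 = a, g2 = bvec), col_ids = paste0("s", 1:m))
      p <- permute_matrix(bm, mutex_sort(bm))
      st <- run_stats(p)
      expect_identical(st$overlap, 0L)
      expect_true(all(st$per_row$n_runs == 1L))
    }
  }
  for (m in 3:6) {
    grids <- expand.grid(rep(list(0:3), m))
    keep <- apply(grids, 1, function(v) all(tabulate(v + 1, 4)[2:4] > 0))
    grids <- grids[keep, , drop = FALSE]
    for (gi in seq_len(nrow(grids))) {
      rows <- vapply(1:3, function(k) as.integer(grids[gi, ] == k), integer(m))
      bm <- binmat(t(rows), row_ids = paste0("g", 1:3), col_ids = paste0("s", 1:m))
      p <- permute_matrix(bm, mutex_sort(bm))
      st <- run_stats(p)
      expect_identical(st$overlap, 0L)
      expect_true(all(st$per_row$n_runs == 1L))
    }
  }
})

test_that("mutex_sort is deterministic and conserves entries and marginals", {
  set.seed(77)
  for (i in 1:8) {
    bm <- random_bm(15, 20, runif(1, 0.05, 0.5))
    r1 <- mutex_sort(bm); r2 <- mutex_sort(bm)
    expect_same_sort(r1, r2)
    expect_setequal(r1$row_order, rownames(bm))
    expect_setequal(r1$col_order, colnames(bm))
    p <- permute_matrix(bm, r1)
    expect_identical(sum(p), sum(bm))
    expect_identical(marginals(p, "rows")[rownames(bm)], marginals(bm, "rows"))
    expect_identical(marginals(p, "cols")[colnames(bm)], marginals(bm, "cols"))
  }
})

test_that("restricted best-in-class variant implements the gated penalty", {
  b <- fixture_3x4()
  # g1 over all: s1: 1-(1)=0, s2: 1-0=1 -> 1 (penalty only where g1 mutated)
  expect_identical(best_in_class_score(b, "g1", rownames(b), colnames(b),
                                       variant = "restricted"), 1L)
  set.seed(14)
  bm <- random_bm(6, 8, 0.4)
  M <- unclass(bm)
  G <- rownames(M); S <- colnames(M)
  for (g in G) {
    lit <- sum(vapply(S[M[g, S] == 1L], function(s)
      1 - (sum(M[G, s]) - M[g, s]), numeric(1)))
    expect_equal(best_in_class_score(bm, g, G, S, variant = "restricted"), lit)
  }
  r <- mutex_sort(bm, variant = "restricted")
  expect_setequal(r$row_order, rownames(bm))
  expect_same_sort(mutex_sort(bm, variant = "restricted"), r)
})

test_that("runtime growth in n is no worse than roughly quadratic (smoke)", {
  t_of <- function(n) {
    bm <- random_bm(n, 150, 0.1, seed = n)
    min(vapply(1:3, function(i) system.time(mutex_sort(bm))["elapsed"], numeric(1)))
  }
  t1 <- t_of(80); t2 <- t_of(320)
  # 4x rows: quadratic predicts ~16x; allow wide slack for timer noise
  expect_lt(t2, max(16 * 4 * t1, 0.5))
})
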