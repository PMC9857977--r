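#' Paired one-sided signed-rank p-value
#'
#' Wilcoxon signed-rank test of H1: `left > right` on paired score vectors,
#' the significance test used throughout the benchmark harness (the paired
#' replicate design and non-normal scores make a rank test the natural
#' choice). Zero differences are dropped; the null distribution is exact for
#' up to 25 untied non-zero differences and a normal approximation with
#' continuity correction beyond. When every difference is zero the test is
#' degenerate and `p = 1` is returned with attribute `degenerate = TRUE`.
#'
#' @param left,right numeric vectors of equal length (>= 5 recommended).
#' @param method `"signed_rank"` (default) or `"signflip"`: the latter is an
#'   exact sign-flip permutation test on the mean difference, enumerating all
#'   `2^n` flips for up to 20 non-zero differences and falling back to the
#'   signed-rank test above that.
#' @return a numeric p-value in `(0, 1]`, with attributes `degenerate`
#'   (logical) and `n_used` (number of non-zero differences).
#' @examples
#' paired_onesided_p(c(1:10) + (1:10) / 100, rep(0, 10))  # all positive, untied: 2^-10
#' @export
paired_onesided_p <- function(left, right, method = c("signed_rank", "signflip")) {
  method <- match.arg(method)
  if (length(left) != length(right))
    stop("left and right must have equal length", call. = FALSE)
  d <- left - right
  d <- d[d != 0]
  if (!length(d))
    return(structure(1, degenerate = TRUE, n_used = 0L))
  n <- length(d)
  if (method == "signflip" && n <= 20L) {
    # exact: all 2^n sign assignments of |d|; one-sided on the sum
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_sums <- as.vector(signs %*% abs(d))
    p <- mean(null_sums >= sum(d) - 1e-12)
    return(structure(min(p, 1), degenerate = FALSE, n_used = n))
  }
  exact <- n <= 25L && !anyDuplicated(abs(d))
  p <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "greater",
                       exact = exact, correct = TRUE)$p.value)
  structure(min(p, 1), degenerate = FALSE, n_used = n)
}

#' Replicated comparison of sorting methods
#'
#' The benchmark harness: for every combination of matrix size and density
#' and for `reps` seeded replicates, generates an input matrix, applies each
#' requested sorting method, scores the arranged matrix, and tests the paired
#' score differences between consecutive methods (first vs second, second vs
#' third, ...) with the one-sided signed-rank test — so pass methods ordered
#' from the expected best to the baseline.
#'
#' Two generation modes are available: `"random"` (iid Bernoulli background,
#' [random_bm()]) and `"inject"` (matrices with injected mutually exclusive
#' and co-occurrent row sets, [inject_patterns()]). Two metrics: `"coverage"`
#' ([overall_me_coverage()] of the arranged matrix) and `"entropy"` (mean
#' top-`top_k` pairwise [joint_entropy], [topk_pair_entropy()]). The whole
#' report is reproducible from `seed`.
#'
#' @param sizes integer vector of matrix sizes (square matrices: n = m = size).
#' @param densities numeric vector of background densities.
#' @param reps replicates per condition (>= 5).
#' @param methods character vector, a subset of
#'   `c("mutex", "memo", "random", "identity")`, ordered best-to-baseline.
#' @param metric `"coverage"` or `"entropy"`.
#' @param top_k top rows for the entropy metric.
#' @param mode `"random"` or `"inject"`.
#' @param seed master seed.
#' @param spec_args named list of [synthetic_spec()] overrides for
#'   `mode = "inject"` (e.g. `n_me`, `me_ones`).
#' @return an object of class `comparison_report`: a list with `config`,
#'   `scores` (data.frame: size, density, rep, method, score) and `tests`
#'   (data.frame: size, density, comparison, p_value, win_fraction, n_used).
#' @export
compare_methods <- function(sizes = 100L, densities = c(0.05, 0.1),
                            reps = 50L,
                            methods = c("mutex", "memo", "identity"),
                            metric = c("coverage", "entropy"),
                            top_k = 10L,
                            mode = c("random", "inject"),
                            seed = 1L, spec_args = list()) {
  metric <- match.arg(metric); mode <- match.arg(mode)
  methods <- match.arg(methods, c("mutex", "memo", "random", "identity"),
                       several.ok = TRUE)
  if (reps < 5L) stop("reps must be at least 5", call. = FALSE)
  if (length(methods) < 2L) stop("need at least two methods", call. = FALSE)

  grid <- expand.grid(size = as.integer(sizes), density = densities,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, nrow(grid) * reps),
           nrow(grid), reps))

  scores <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    sz <- grid$size[ci]; dd <- grid$density[ci]
    cond <- vector("list", reps)
    for (r in seq_len(reps)) {
      rs <- seeds[ci, r]
      bm <- if (mode == "random") {
        random_bm(sz, sz, dd, seed = rs)
      } else {
        spec <- do.call(synthetic_spec,
                        c(list(n = sz, m = sz, density = dd, seed = rs), spec_args))
        inject_patterns(spec)$bm
      }
      vals <- vapply(seq_along(methods), function(k) {
        sr <- switch(methods[k],
                     mutex = mutex_sort(bm),
                     memo = memo_sort(bm),
                     random = random_sort(bm, seed = rs + k),
                     identity = identity_sort(bm))
        if (metric == "coverage") {
          as.numeric(overall_me_coverage(permute_matrix(bm, sr)))
        } else {
          topk_pair_entropy(bm, sr, k = top_k)$mean
        }
      }, numeric(1L))
      cond[[r]] <- data.frame(size = sz, density = dd, rep = r,
                              method = methods, score = vals,
                              stringsAsFactors = FALSE)
    }
    scores[[ci]] <- do.call(rbind, cond)
  }
  scores <- do.call(rbind, scores)

  tests <- list()
  for (ci in seq_len(nrow(grid))) {
    sz <- grid$size[ci]; dd <- grid$density[ci]
    sub <- scores[scores$size == sz & scores$density == dd, ]
    for (k in seq_len(length(methods) - 1L)) {
      l <- sub$score[sub$method == methods[k]]
      r <- sub$score[sub$method == methods[k + 1L]]
      p <- paired_onesided_p(l, r)
      tests[[length(tests) + 1L]] <- data.frame(
        size = sz, density = dd,
        comparison = paste0(methods[k], ">", methods[k + 1L]),
        p_value = as.numeric(p),
        win_fraction = mean(l > r),
        n_used = attr(p, "n_used"),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(config = list(sizes = sizes, densities = densities,
                               reps = reps, methods = methods, metric = metric,
                               top_k = top_k, mode = mode, seed = seed,
                               spec_args = spec_args),
                 scores = scores, tests = do.call(rbind, tests)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison report: metric=%s, mode=%s, %d reps, seed=%d\n",
              x$config$metric, x$config$mode, x$config$reps, x$config$seed))
  agg <- stats::aggregate(score ~ size + density + method, data = x$scores, FUN = mean)
  cat("mean scores:\n"); print(agg, ...)
  cat("paired one-sided tests:\n"); print(x$tests, ...)
  invisible(x)
}

#' Wall-clock timing sweep
#'
#' Times [mutex_sort()] (or another sorter) on random matrices over a grid of
#' sizes and densities. Purely informational: runtimes are hardware-dependent
#' and are reported, never asserted. With `fine_grid = TRUE` the density grid
#' `seq(0.001, 0.1, by = 0.001)` is appended, which resolves the runtime peak
#' near the permutation-matrix worst case at very low densities.
#'
#' @param sizes integer vector of square-matrix sizes.
#' @param densities numeric vector of densities.
#' @param reps replicates per condition.
#' @param method one of `"mutex"`, `"memo"`.
#' @param seed master seed.
#' @param fine_grid append the fine low-density grid.
#' @return a data.frame: size, density, mean_seconds, sd_seconds, reps.
#' @export
timing_sweep <- function(sizes = c(100L, 200L), densities = c(0.05, 0.1),
                         reps = 3L, method = c("mutex", "memo"),
                         seed = 1L, fine_grid = FALSE) {
  method <- match.arg(method)
  if (fine_grid) densities <- sort(unique(c(densities, seq(0.001, 0.1, by = 0.001))))
  grid <- expand.grid(size = as.integer(sizes), density = densities,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, nrow(grid) * reps),
           nrow(grid), reps))
  sorter <- if (method == "mutex") mutex_sort else memo_sort
  out <- lapply(seq_len(nrow(grid)), function(ci) {
    t <- vapply(seq_len(reps), function(r) {
      bm <- random_bm(grid$size[ci], grid$size[ci], grid$density[ci],
                      seed = seeds[ci, r])
      unname(system.time(sorter(bm))["elapsed"])
    }, numeric(1L))
    data.frame(size = grid$size[ci], density = grid$density[ci],
               mean_seconds = mean(t), sd_seconds = stats::sd(t), reps = reps)
  })
  do.call(rbind, out)
}
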