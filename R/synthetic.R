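#' Random binary matrix of prescribed density
#'
#' Each entry is independently 1 with probability `density` (iid Bernoulli).
#' With `exact_count = TRUE`, exactly `floor(n * m * density)` ones are placed
#' uniformly at random instead, for variance-sensitive uses. Reproducible
#' given `(n, m, density, seed)`; the caller's RNG state is restored.
#'
#' @param n,m numbers of rows (genes) and columns (samples).
#' @param density probability of a non-zero entry, in `[0, 1]`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param exact_count place an exact number of ones instead of iid sampling.
#' @return a [binmat] with row ids `g1..gn` and column ids `s1..sm`.
#' @export
random_bm <- function(n, m, density, seed = NULL, exact_count = FALSE) {
  if (!is.numeric(density) || is.na(density) || density < 0 || density > 1)
    stop("density must be in [0, 1]", call. = FALSE)
  ent <- with_seed(seed, {
    if (exact_count) {
      k <- floor(n * m * density)
      v <- integer(n * m)
      if (k > 0L) v[sample.int(n * m, k)] <- 1L
      matrix(v, n, m)
    } else {
      matrix(stats::rbinom(n * m, 1L, density), n, m)
    }
  })
  binmat(ent, row_ids = paste0("g", seq_len(n)), col_ids = paste0("s", seq_len(m)))
}

#' Shuffled diagonal (permutation) matrix
#'
#' An n x n matrix with exactly one 1 per row and per column, at a uniformly
#' random permutation of positions. This is the heuristic's worst case: each
#' phase-1 iteration can cover only a single sample, and the density `1/n`
#' decreases linearly as the matrix scales up.
#'
#' @param n matrix size (`n >= 1`).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a [binmat].
#' @export
shuffled_diagonal <- function(n, seed = NULL) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  ent <- matrix(0L, n, n)
  ent[cbind(seq_len(n), perm)] <- 1L
  binmat(ent, row_ids = paste0("g", seq_len(n)), col_ids = paste0("s", seq_len(n)))
}

#' Specification of a synthetic matrix with injected patterns
#'
#' Bundles the parameters of [inject_patterns()]: matrix size, background
#' density, the mutually exclusive (ME) row set and the co-occurrent row set.
#' Defaults emulate a cohort carrying one maximally exclusive gene set and
#' one recurrent co-occurring gene set on top of independent background
#' mutations:
#' \itemize{
#'   \item `me_ones = floor(m / n_me)`: the ME supports are pairwise disjoint
#'     and tile (almost) all samples — the extreme "no vertical overlap"
#'     configuration — making each ME gene at least as frequent as the
#'     expected background gene at any background density up to `1/n_me`.
#'   \item `cooc_core = clamp(floor(3 * m * density), me_ones, floor(m / 4))`:
#'     the co-occurring set shares a common core of samples sized to stay the
#'     most recurrent feature of the matrix (above the maximal background
#'     marginal and at least the ME support size) while remaining a sparse
#'     feature (at most a quarter of samples).
#'   \item `cooc_noise = max(1, ceiling(cooc_core / 10))` private extra ones
#'     per co-occurring row, so the set overlaps largely but not identically.
#' }
#'
#' @param n,m matrix dimensions.
#' @param density background Bernoulli density in `[0, 1]`.
#' @param n_me,n_cooc numbers of injected ME / co-occurrent rows.
#' @param me_ones ones per ME row (pairwise-disjoint supports must fit:
#'   `n_me * me_ones <= m`).
#' @param cooc_core size of the shared support of the co-occurrent rows.
#' @param cooc_noise private ones per co-occurrent row
#'   (`cooc_core + cooc_noise <= m`).
#' @param seed integer seed.
#' @return an object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n = 1000L, m = 1000L, density = 0.1,
                           n_me = 10L, me_ones = NULL,
                           n_cooc = 10L, cooc_core = NULL, cooc_noise = NULL,
                           seed = NULL) {
  if (is.null(me_ones)) me_ones <- floor(m / max(n_me, 1L))
  if (is.null(cooc_core))
    cooc_core <- min(floor(m / 4), max(floor(3 * m * density), me_ones))
  if (is.null(cooc_noise)) cooc_noise <- max(1L, ceiling(cooc_core / 10))
  spec <- list(n = as.integer(n), m = as.integer(m), density = density,
               n_me = as.integer(n_me), me_ones = as.integer(me_ones),
               n_cooc = as.integer(n_cooc), cooc_core = as.integer(cooc_core),
               cooc_noise = as.integer(cooc_noise),
               seed = if (is.null(seed)) NULL else as.integer(seed))
  if (spec$density < 0 || spec$density > 1)
    stop("density must be in [0, 1]", call. = FALSE)
  if (spec$n_me < 0L || spec$n_cooc < 0L)
    stop("n_me and n_cooc must be non-negative", call. = FALSE)
  if (spec$n_me * spec$me_ones > spec$m)
    stop(sprintf("infeasible spec: n_me * me_ones = %d exceeds m = %d (disjoint supports must fit)",
                 spec$n_me * spec$me_ones, spec$m), call. = FALSE)
  if (spec$cooc_core + spec$cooc_noise > spec$m)
    stop(sprintf("infeasible spec: cooc_core + cooc_noise = %d exceeds m = %d",
                 spec$cooc_core + spec$cooc_noise, spec$m), call. = FALSE)
  if (spec$n_me + spec$n_cooc > spec$n)
    stop("infeasible spec: more injected rows than matrix rows", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' Generate a matrix with injected mutual-exclusivity and co-occurrence
#'
#' Builds an `n x m` background of iid Bernoulli(`density`) rows, then
#' replaces `n_me` rows with mutually exclusive patterns (each carrying
#' `me_ones` ones in pairwise-disjoint random sample subsets) and `n_cooc`
#' rows with co-occurrent patterns (a common random core of `cooc_core`
#' samples plus `cooc_noise` private random ones each). Injected rows are
#' placed at random positions. The ground-truth labels are returned alongside
#' the matrix.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `bm` (a [binmat]), `truth` (data.frame
#'   `row_id`, `label` in `{"me", "cooc", "background"}`) and `spec`.
#' @export
inject_patterns <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("spec must be a synthetic_spec", call. = FALSE)
  res <- with_seed(spec$seed, {
    n <- spec$n; m <- spec$m
    ent <- matrix(stats::rbinom(n * m, 1L, spec$density), n, m)
    where <- sample.int(n, spec$n_me + spec$n_cooc)
    me_rows <- where[seq_len(spec$n_me)]
    cooc_rows <- where[spec$n_me + seq_len(spec$n_cooc)]
    if (spec$n_me > 0L && spec$me_ones > 0L) {
      cols <- sample.int(m, spec$n_me * spec$me_ones)
      for (i in seq_len(spec$n_me)) {
        ent[me_rows[i], ] <- 0L
        ent[me_rows[i], cols[(i - 1L) * spec$me_ones + seq_len(spec$me_ones)]] <- 1L
      }
    }
    if (spec$n_cooc > 0L) {
      core <- sample.int(m, spec$cooc_core)
      rest <- setdiff(seq_len(m), core)
      for (i in cooc_rows) {
        ent[i, ] <- 0L
        ent[i, core] <- 1L
        if (spec$cooc_noise > 0L && length(rest))
          ent[i, sample(rest, min(spec$cooc_noise, length(rest)))] <- 1L
      }
    }
    label <- rep("background", n)
    label[me_rows] <- "me"
    label[cooc_rows] <- "cooc"
    list(ent = ent, label = label)
  })
  bm <- binmat(res$ent, row_ids = paste0("g", seq_len(spec$n)),
               col_ids = paste0("s", seq_len(spec$m)))
  list(bm = bm,
       truth = data.frame(row_id = rownames(bm), label = res$label,
                          stringsAsFactors = FALSE),
       spec = spec)
}
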