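# mutexsort

Mutual-exclusivity sorting of binary matrices.

Binary (0/1) matrices summarising genomic alterations — somatic mutations
across a patient cohort, or gene essentialities across a cell-line panel —
often hide *mutual-exclusivity* patterns: sets of genes that are frequently
altered collectively but rarely in the same sample. Such sets point at genes
acting in the same oncogenic pathway and, in dependency screens, at
synthetic-lethal partners. To make these patterns visible, rows and columns
must be reordered so that *runs* (maximal blocks of consecutive 1s within a
row) are long and do not overlap vertically. Finding the optimal such
ordering is NP-hard; `mutexsort` implements a fast deterministic two-phase
greedy heuristic, plus everything needed to evaluate it.

## The algorithm

For a binary matrix **B** with uncovered gene set *G* and uncovered sample
set *S*:

**Phase 1** repeatedly appends the *best-in-class* gene

&nbsp;&nbsp;&nbsp;&nbsp;g\* = argmax<sub>g∈G</sub> Σ<sub>s∈S</sub> ( B<sub>g,s</sub> − Σ<sub>g′∈G, g′≠g</sub> B<sub>g′,s</sub> )

and covers the samples in which it is mutated; genes left when samples run
out are appended in original order. The score equals 2·cov(g) − T (cov(g) =
uncovered samples hit by g; T = 1s remaining), so phase 1 is a greedy
maximum-coverage row ordering.

**Phase 2** resets samples and, per gene in phase-1 order, appends its
still-uncovered samples sorted by decreasing exclusive coverage
L<sub>s</sub> = B<sub>g,s</sub>(1 − Σ<sub>g′≠g</sub> B<sub>g′,s</sub>),
making each gene's samples contiguous with exclusively-hit samples first.

The package also provides: the MEMo matrix sort as a comparator (rows by
decreasing marginal, columns by their bit pattern read as a binary-notation
number); the overall mutual-exclusivity coverage score and the top-k
pairwise joint-entropy score; run/overlap diagnostics; ranking of curated
gene pairs in a sorted matrix; seedable generators for random, shuffled
diagonal and pattern-injected matrices with ground truth; and a replicated
benchmark harness with paired one-sided signed-rank tests. See the methods
vignette (`vignettes/mutex-sorting.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(mutexsort)

b <- binmat(rbind(g1 = c(1, 1, 0, 0),
                  g2 = c(0, 0, 1, 1),
                  g3 = c(1, 0, 1, 0)),
            col_ids = paste0("s", 1:4))
r <- mutex_sort(b)
print(r)
#> sort_result [mutex]: 3 rows, 4 columns (input 3x4:6:162)
#>  rows: g1, g2, g3
#>  cols: s2, s1, s4, s3
permute_matrix(b, r)
#> binary matrix: 3 rows (genes) x 4 columns (samples), 6 non-zero (density 0.5)
#>    s2 s1 s4 s3
#> g1  1  1  0  0
#> g2  0  0  1  1
#> g3  0  1  0  1
```

g1 and g2 (mutually exclusive, jointly covering all samples) rise to the
top with non-overlapping runs; g3, co-occurring with both, sinks. The
coverage score of this row order, `overall_me_coverage(b)`, is `-1`: each
gene is scored by its exclusive coverage of the remaining submatrix (g1:
−2, g2: +1, g3: 0) and the gene scores are summed — larger is better, and
the unsorted order here is already optimal for this tiny fixture.

On synthetic matrices with known structure (200×200, background density
0.05, 10 injected mutually exclusive rows, 10 co-occurring rows):

```r
res <- inject_patterns(synthetic_spec(n = 200, m = 200, density = 0.05, seed = 1))
sr <- mutex_sort(res$bm)
me <- res$truth$row_id[res$truth$label == "me"]
sum(me %in% sr$row_order[1:10])
#> [1] 9
topk_pair_entropy(res$bm, sr, 10)$mean
#> [1] 0.6656511
topk_pair_entropy(res$bm, memo_sort(res$bm), 10)$mean
#> [1] 0.5703105
```

Nine of the ten planted exclusive genes land in the top 10 rows (the tenth
slot goes to the denser co-occurring core), and the mean pairwise joint
entropy of the top rows — larger when frequency-matched exclusive pairs sit
at the top — exceeds the MEMo arrangement's.

## Command line

```sh
exec/mutexsort simulate --mode inject --n 200 --m 200 --density 0.05 --seed 1 --out m.tsv --truth t.tsv
exec/mutexsort sort --input m.tsv --output sorted.tsv --orders orders.json
exec/mutexsort score --input sorted.tsv --metric coverage
exec/mutexsort rank-pairs --orders orders.json --pairs pairs.tsv --top-k 25
exec/mutexsort bench --metric coverage --sizes 100 --densities 0.05,0.1 --reps 50
```

Exit code 2 signals a validation error (non-binary token, duplicate ids,
ragged rows, ...) with the offending coordinates named.

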