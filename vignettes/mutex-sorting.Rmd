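---
title: "Mutual-exclusivity sorting of binary matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-exclusivity sorting of binary matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutexsort)
```

## The problem

Presence/absence matrices are a workhorse representation in cancer genomics:
rows are genes (or other functional events), columns are samples, and a 1
records a somatic mutation, a copy-number event, or a fitness dependency in
that sample. A set of genes is *mutually exclusive* when its members tend not
to carry 1s in the same sample — a pattern associated with genes acting in
the same pathway (one hit suffices) and with synthetic lethality in
dependency screens.

Defining a *run* as a maximal block of consecutive non-zero entries within a
row, a layout exposes mutual exclusivity when runs are long and do not
overlap vertically across rows. Finding the row/column ordering that
minimises vertical run overlap exactly is NP-hard, so this package implements
a deterministic two-phase greedy heuristic, together with the tools needed to
evaluate it: a comparator sort (the one used by the MEMo tool), two scoring
statistics, seedable synthetic-data generators with ground truth, and a
replicated benchmark harness.

## The two-phase heuristic

Let $B \in \{0,1\}^{n \times m}$ with gene set $G$ (rows) and sample set $S$
(columns).

**Phase 1 (row order).** All genes and samples start *uncovered*. While
uncovered genes and uncovered samples remain, the *best-in-class* gene is

$$ g^\* \;=\; \arg\max_{g \in G}\; \sum_{s \in S}\Big( B_{g,s} \;-\;
   \sum_{g' \in G,\, g' \ne g} B_{g',s} \Big), $$

where $G$ and $S$ here denote the *uncovered* sets. $g^\*$ is appended to
the output and every uncovered sample with $B_{g^\*,s} = 1$ becomes covered.
If samples run out first, the remaining genes are appended in their original
order.

Writing $\mathrm{cov}(g)$ for the number of uncovered samples in which $g$
is mutated and $T$ for the total number of 1s in the uncovered submatrix,
the selection score equals $2\,\mathrm{cov}(g) - T$. The subtracted mass is
the same for every candidate, so the argmax is the argmax of
$\mathrm{cov}(g)$ — phase 1 is a greedy maximum-coverage (set-cover-style)
ordering. The implementation exploits this identity (with incremental
coverage updates, so phase 1 is $O(nm)$ after the initial scan in the
typical case and $O(n^2 m)$ worst case) but the exported
`best_in_class_score()` evaluates the printed sum, and the test suite checks
the two against each other exhaustively on small matrices.

Two consequences of the identity are worth noting. First, when the maximal
coverage drops to zero the uncovered submatrix is all-zero, every remaining
score is tied, and the loop would append the remaining genes in original
order one at a time; the implementation breaks out early and appends them in
one step, which is output-identical. Second, all-zero rows can never win
while any uncovered gene still covers an uncovered sample, so they sink to
the leftover block.

**Phase 2 (column order).** All samples are reset to uncovered. For each
gene $g$ in the phase-1 order (while uncovered samples remain), the
uncovered samples with $B_{g,s} = 1$ are sorted by decreasing *exclusive
coverage*

$$ L_s \;=\; B_{g,s}\Big(1 - \sum_{g' \in G',\, g' \ne g} B_{g',s}\Big), $$

appended to the column order, and marked covered. Here $G'$ is the full
phase-1 gene sequence, so on a candidate sample $L_s = 2 - c_s$ with $c_s$
the column marginal: samples exclusively mutated in $g$ come first, heavily
co-mutated samples last. Samples claimed by no gene (all-zero columns) are
appended at the end in original order. This phase makes each gene's samples
contiguous, maximising run lengths.

Both phases are deterministic; ties are always broken by original row/column
position (a stable rule chosen because it guarantees reproducibility — any
fixed rule would do, and the tie pattern is the one point where other
implementations of the same formulas could legitimately differ).

## The MEMo comparator

The comparator implements the matrix-sorting step of MEMo (a tool for
discovering mutually exclusive gene modules; only its sorting step is in
scope here): rows by decreasing marginal, then columns by decreasing value
of their 0/1 pattern read as a number in binary notation, top row most
significant. Rather than materialising $2^n$-scale integers, columns are
compared lexicographically as bit strings under a C-locale radix sort, which
is bit-exact for any $n$; the tests verify equivalence against exact integer
values for $n \le 30$.

## Evaluation scores

**Overall mutual-exclusivity coverage** (`overall_me_coverage()`): visit the
rows of the arranged matrix top to bottom; score the current gene with the
phase-1 sum over the *remaining* genes and samples; then delete the gene and
every remaining sample in which it is mutated. The total (possibly negative;
larger is better) depends only on the row order, never on column adjacency,
so it is a pure row-ordering quality score. On the $n \times n$ identity in
natural order it telescopes to $n - n(n-1)/2$, a useful closed-form check.

**Joint-entropy pair score** (`joint_entropy()`, `topk_pair_entropy()`): the
plug-in empirical joint Shannon entropy (nats) of a pair of binary rows,
averaged over all pairs among the top $k$ rows of the arranged matrix
(default $k = 10$). For two rows of equal marginal frequency, disjoint
supports give strictly larger joint entropy than identical supports, which
is what lets the score separate exclusive from co-occurring pairs placed at
the top by a sorter. Two caveats are intrinsic to this metric and documented
here deliberately: at *fixed* marginals it is maximised by independence (a
mutually exclusive pair is dependent, so it scores slightly below an
independent pair of the same frequencies), and it increases with marginal
frequency up to 0.5, so it rewards methods that top-rank frequent genes. It
is therefore an *orthogonal* check on exclusivity-aware sorting, not a
direct objective — the benchmark design below takes both caveats into
account.

**Run diagnostics** (`run_stats()`): per-row run counts and mean lengths,
plus the consecutive-row overlap $\sum_{i<n} \#\{j : B_{i,j} = B_{i+1,j} =
1\}$. These quantify the stated layout goal directly but are not optimised
by any sorter; they are reported for inspection.

**Pair ranking** (`rank_pairs()`): for externally curated gene pairs (e.g.
synthetic-lethal pairs with a confidence score), the worse of the two
positions in the sorted row order decides whether the pair is visible "in
the top $k$ rows"; pairs with an absent member are flagged, not fatal.

## Synthetic data

Three generators cover the input classes used in the evaluations, all pure
functions of their seed (the caller's RNG state is saved and restored):

* `random_bm(n, m, density)` — iid Bernoulli entries; an `exact_count` mode
  places exactly $\lfloor nmd \rfloor$ ones for variance-sensitive uses.
* `shuffled_diagonal(n)` — a random permutation matrix, the heuristic's
  worst case: one coverable sample per gene per iteration, density exactly
  $1/n$.
* `inject_patterns(synthetic_spec(...))` — an iid background in which
  `n_me` rows are replaced by mutually exclusive patterns and `n_cooc` rows
  by co-occurring patterns, with ground-truth labels returned.

Default injected-set sizes (all overridable) encode the scenario the
generator is meant to emulate — one maximally exclusive gene set and one
recurrent, largely overlapping gene set on top of featureless background:

* `me_ones = floor(m / n_me)`: the ME supports are pairwise disjoint and
  tile the sample set — the extreme of "no vertical overlap" — which also
  makes each ME gene at least as frequent as a typical background gene at
  any background density up to $1/n_{me}$. A smaller choice would make ME
  genes rare relative to background at the higher densities, and sorters
  would then be tested on frequency detection rather than exclusivity
  detection.
* `cooc_core = clamp(floor(3 m d), me_ones, floor(m/4))` shared samples,
  plus `cooc_noise = ceiling(cooc_core/10)` private ones per row: the
  co-occurring set is the most recurrent feature of the matrix (above the
  maximal background marginal and at least the ME support size, like a
  clonal driver event) while staying below a quarter of samples. The scaling
  keeps the set's pairwise joint entropy *between* the background level and
  the exclusive/frequent alternatives at every default density — which is
  precisely the regime in which a marginal-only sort (MEMo) top-ranks the
  co-occurring clique while an exclusivity-aware sort does not, so the
  entropy score can distinguish them. Outside this regime (e.g. a core near
  $m/2$) the entropy score saturates and stops discriminating, a limitation
  of the metric discussed above.

What the generator does **not** emulate: heterogeneous per-gene mutation
rates, per-sample mutational burden (hypermutators), clonal structure,
copy-number segments, or partially overlapping ("soft") exclusivity.
Passing benchmarks on these matrices therefore demonstrate that the sorters
behave as designed under controlled signal/background separation, not that
the heuristic dominates on any real cohort.

## Benchmark harness

`compare_methods()` runs each requested sorter on the same seeded replicate
matrices and tests consecutive method pairs with a paired one-sided Wilcoxon
signed-rank test (`paired_onesided_p()`): scores are paired by replicate
and not normal, so a rank test is the natural choice; an exact sign-flip
permutation test is available via `method = "signflip"`. Zero differences
are dropped (degenerate all-zero comparisons return $p = 1$ with a flag);
the null is exact for up to 25 untied differences and a
continuity-corrected normal approximation beyond. Calibration under the
null (two independent random sorts) is checked in the test suite.

Problem sizes: the package's reference comparisons are run at desk scale —
$100 \times 100$ random matrices (four densities, 200 replicates) for the
coverage score, and $200 \times 200$ injected matrices (three background
densities, 100 replicates) for the top-10 entropy score. These sizes keep
the full suite in the minutes range on a single core while leaving the
paired tests massively powered; larger, slower configurations are reachable
through the same function arguments. `timing_sweep()` reports wall-clock
summaries over size/density grids (with an optional fine low-density grid
that resolves the runtime peak near the permutation-matrix worst case);
runtimes are hardware-dependent and are never asserted.

## Numerical and design choices

* **Formula reading.** The phase-1 selection sum is implemented exactly as
  defined above, with the penalty running over *all* uncovered samples. An
  alternative reading restricts the penalty to samples where the candidate
  itself is mutated (the phase-2 gating applied to phase 1); it changes the
  argmax in general and is available everywhere as `variant = "restricted"`
  (CLI `--bic-variant restricted`), off by default.
* **Leftover order.** Genes left uncovered when samples run out (phase 1)
  and columns claimed by no gene (phase 2) are appended in original order —
  the simplest deterministic rule; any fixed rule would serve.
* **Degenerate inputs.** Empty matrices are rejected at construction, so the
  algorithms never see them. All-zero rows and columns are legal and land in
  the leftover blocks. Constant vectors have zero joint entropy.
* **Tolerances.** All sorting is integer/lexicographic — no floating-point
  comparisons enter any ordering decision. Entropy values are plain double
  arithmetic with the $0 \log 0 = 0$ convention.
* **Fingerprints.** `sort_result` objects carry a lightweight structural
  fingerprint (dims, count of ones, positional checksum) of their input, an
  integrity aid when orders are serialized and re-applied, not a
  cryptographic hash.

## Known limitations

The heuristic is greedy and makes no optimality claim — the underlying
seriation problem is NP-hard, and adversarial inputs exist where a different
row order scores higher. The joint-entropy score's frequency sensitivity
(above) means comparisons using it should match injected-set frequencies, as
the default generator does. Real-data workflows (reading a cohort matrix,
sorting, ranking curated pairs) are fully supported through the file
interfaces and CLI, but no real dataset ships with the package.
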