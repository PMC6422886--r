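---
title: "Dynamic multi-seeds OTU clustering: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic multi-seeds OTU clustering: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

De novo OTU picking bins 16S rRNA amplicon reads into operational
taxonomic units at a user-chosen dissimilarity threshold $\theta$
(0.03 for the conventional 97% identity definition). Greedy heuristic
clusterers (CD-HIT/UCLUST-style) stream reads against a single seed per
cluster; they are fast but sensitive to which read happens to become the
seed, and sequencing errors push them toward over-splitting: a noisy seed
misrepresents its cluster, and reads that belong with it fall just outside
$\theta$.

This package implements a dynamic multi-seeds variant of that greedy
scheme. Once a cluster is large enough to be trusted, it is represented
not by one seed but by its *multi-core sequences* (MCS): a clique of at
least three members whose pairwise distances all lie strictly below
$\theta$. Membership decisions then use the *average* distance to the MCS
and the empirical spread of distances inside it, which damps the influence
of any single noisy sequence.

## The procedure

1. **Dereplication and sorting.** Identical reads are collapsed into
   records with abundance counts; records are streamed in abundance-descending
   order, ties broken by the sequence string itself. The stream is
   therefore a pure function of the input multiset: permuting the input
   file cannot change the result.
2. **Greedy pass.** Each record joins a qualifying cluster or founds a new
   one. A single-seed cluster qualifies a record at seed distance
   $\le \theta$. Under the default best-fit policy the qualifying cluster
   with the smallest relevant distance wins (ties by creation order);
   first-fit is available.
3. **MCS selection.** When a cluster reaches $\eta$ members (default 25),
   a deterministic greedy clique scan runs over members in arrival order,
   starting from the seed: a member joins the core if it is within
   $\theta$ (strictly) of every current core member. If the core reaches
   `min_core` (default 3) members it becomes the MCS; otherwise the
   cluster keeps its single seed and re-attempts selection after every
   later merge.
4. **Assignment to an MCS cluster.** With $d(s, M_i)$ the mean distance
   of candidate $s$ to the core members, $\bar d_{M_i}$ the mean and
   $\sigma_i$ the standard deviation of all within-core pairwise
   distances, $s$ qualifies iff
   $$ d(s, M_i) \le \theta \quad\text{or}\quad |d(s, M_i) - \bar d_{M_i}| \le \mu\,\sigma_i , $$
   with $\mu = 3$ by default. The second branch is the model-based
   relaxation: clusters whose internal spread is wide admit reads a little
   beyond $\theta$. A literal variant of the rule,
   $|d(s, M_i)| \le \mu\sigma_i$ alone, is available as `eq1_literal`;
   with an all-identical core ($\sigma_i = 0$) it rejects everything, which
   is why it is not the default reading.
5. **Dynamic update.** After every merge the MCS is refreshed. A new
   member strictly within $\theta$ of every core member joins the core
   directly; because the clique scan runs in arrival order, this
   incremental step is provably identical to a full re-scan, and the
   package's test suite also verifies that equivalence against a
   straight-line reference implementation.
6. **Singleton rescue.** After the stream ends, isolated reads — clusters
   whose total read abundance is 1 — are reassigned to the nearest
   non-singleton cluster (seed distance or mean-to-MCS as appropriate,
   ties by creation order). If every cluster is a singleton, nothing
   moves. Each surviving cluster becomes one OTU; its representative is
   the seed, or for MCS clusters the most abundant core member.

### The distance

All comparisons use a global pairwise alignment under unit edit cost.
The distance is the number of difference columns (mismatches plus gap
columns) divided by the alignment length. Several optimal alignments can
exist; among cost-optimal ones the package uses the one with the fewest
gap columns, which fixes the alignment length at $(|a| + |b| + g)/2$
without a traceback and makes the distance a deterministic, symmetric
function of the pair. `N` bases never match anything, including other
`N`s, so ambiguous bases cannot glue clusters together. Switches exist
for normalizing by the shorter sequence, free end gaps, and excluding gap
columns from the difference count; the defaults are the ones described
above.

### The spread statistic

$\sigma_i$ is defined as
$\sqrt{\sum_{\text{pairs}} (d_{jk} - \bar d_{M_i})^2 / (|M_i| - 1)}$ —
the deviation sum runs over all $\binom{|M_i|}{2}$ pairs but the divisor
is the core *size* minus one. This is implemented as stated, with the
pair-count-minus-one variant behind `sigma_divisor = "pairs"`. The stated
form makes $\sigma_i$ grow roughly like $\sqrt{|M_i|/2}$ times the
typical deviation, so very large cores acquire wide acceptance windows;
under the default best-fit policy this is harmless (a read's own cluster
is nearly always closer), but under first-fit large clusters become
progressively more absorbent. This interaction is a property of the
stated formula, not of the implementation, and is one reason best-fit is
the default.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `theta` | user-set (0.03 typical) | dissimilarity fraction | cluster admission and clique threshold |
| `eta` | 25 | dereplicated records | cluster size at which MCS selection activates; gates the reliability of the distance sample |
| `mu` | 3 | multiples of $\sigma_i$ | width of the deviation relaxation |
| `min_core` | 3 | records | smallest admissible MCS |
| `max_core` | unlimited | records | optional speed cap on the clique scan (approximation) |
| `assign_policy` | `"best"` | — | best-fit vs first-fit acceptance |
| `rescue_singletons` | `TRUE` | — | final nearest-neighbour rescue of isolated reads |

Cluster sizes are counted in dereplicated records, not raw reads:
$\eta$ exists to guarantee enough *distinct* sequences for a stable
distance sample, and duplicate reads would inflate that count without
adding information.

## Exactness of the optimized engine

The production engine uses banded alignment with adaptive band doubling
(always run until the optimum is provably inside the band), a
$\theta$-cutoff for comparisons that only need "is $d \le \theta$"
decisions (cutoff chosen so every distance at or below $\theta$ is exact),
and triangle-inequality lower bounds on raw edit costs — anchored at the
first core member — to skip cluster evaluations that provably cannot
qualify or cannot win best-fit. Every shortcut is conservative, so the
optimized engine's partition is *identical* (not approximately equal) to
the bundled straight-line reference implementation `dmsc_reference()`,
which precomputes the full unbanded distance matrix and re-selects every
MCS from scratch after every merge. The test suite asserts identity on
randomized datasets; summation orders are fixed so even the floating-point
statistics agree bitwise.

## What the simulator emulates — and what it does not

`dmsc_preset()` regenerates three study designs from their stated summary
properties: a 59-genus "stacked" community (98 bp V6-like references,
abundance proportions drawn in $[0.001, 0.003]$, 2,614 reads, pairwise
divergences in $[0.06, 0.38]$), an 11-taxon community (500 bp, 2,000
reads/taxon at scale 1) in which exactly three taxa are mutually within
1% divergence — so a $\theta = 0.03$ clustering is expected to find 9
OTUs — and a ten-step error series (30 taxa, 120 bp, 5,000 reads/taxon at
scale 1) whose total per-base error rate steps through 0.21–0.42%.

References are built as a star around a random root with controlled
substitution counts, verified against the package's own distance and
regenerated until every pairwise divergence is in tolerance (±0.005).
Reads add i.i.d. per-base substitutions and single-base indels, split
90/10 by default. The stacked design's divergence floor is 0.06 (twice
the usual threshold) so the 59-OTU ground truth is identifiable; the
historically used 0.01 floor can be requested, which makes that
expectation approximate.

Real amplicon data differ in ways the generator deliberately ignores:
errors are not i.i.d. (homopolymer and motif effects), chimeras exist,
reference taxa are not star-related, length variation is larger, and
abundance distributions are heavier-tailed. Passing the simulated
recovery checks therefore demonstrates correctness of the machinery under
the stated designs, not field performance.

## Numerical and design choices

- **Tie-breaks.** Equal-abundance records are ordered by sequence string
  (C locale); the clique scan uses member arrival order. Both choices
  keep every decision a pure function of the sequence multiset — a
  record-id tie-break would leak input order into the result. They also
  make the incremental MCS update provably equal to full re-selection.
- **Strictness.** The clique property uses strict $< \theta$; cluster
  joining uses $\le \theta$, exactly as the two rules are stated.
- **Isolated reads.** A cluster is "isolated" when it holds a single raw
  read (abundance one), not a single dereplicated record: a record
  carrying dozens of identical reads is strong evidence of a real
  template, and rescuing it away would silently delete a taxon whose
  reads happen to be error-free.
- **Degenerate inputs.** Empty input yields an empty partition; a single
  record yields one OTU; `eta` or `min_core` beyond reach degrade the
  method to plain single-seed greedy clustering (verified against an
  independent implementation of that baseline).
- **Pruning margins.** All bound comparisons carry a $10^{-9}$ safety
  margin on the conservative side, so floating-point rounding can only
  make the engine do extra work, never skip a viable cluster.
- **Alignment-call complexity.** With $N$ records, $K$ clusters and
  cluster cores of size $O(\eta)$, alignment calls grow as
  $O(NK + K\eta^2)$; the suite asserts an instrumented run stays within a
  small constant factor of this on a design whose clusters are a few
  multiples of $\eta$. Cores much larger than $\eta$ (they are uncapped
  by default) add a term proportional to the accepting cluster's core
  size per assignment; `max_core` caps this at the cost of approximating
  the stated procedure.

## Problem sizes used by the checks

The bundled tests and the acceptance script run entirely from simulated
data at desk scale: the 11-taxon design at scale 0.1 (2,200 reads of
500 bp, three seeds), the stacked design at full depth (2,614 reads of
98 bp), the error series at scale 0.04 (6,000 reads per rate step, ten
steps, three seeds, with and without MCS), and ten randomized
communities of at most 200 dereplicated records for the
optimized-vs-reference identity check. These sizes were chosen so the
whole suite exercises every code path, including full MCS dynamics, in a
few minutes on one core.

## Known limitations

- The deviation window inherits the stated $|M_i|-1$ divisor; see above
  for its growth with core size and the first-fit caveat.
- Distances are exact edit-alignment distances; there is no k-mer
  prescreen by default, so very large inputs pay the full alignment cost
  (the engine's pruning reduces, but does not eliminate, this).
- Rescue is unconditional: an isolated read joins its nearest
  non-singleton cluster no matter how far away it is. Disable with
  `rescue_singletons = FALSE` if distant singletons should stand.
- Multithreading is not used; results are defined to be independent of
  any internal execution order by construction.
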