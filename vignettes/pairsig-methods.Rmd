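---
title: "Methods: gene-pair signatures and weighted over-representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-pair signatures and weighted over-representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The problem and the model

Over-representation analysis asks whether a query gene list (differentially
expressed genes, GWAS hits, ...) contains more members of a pathway than
chance predicts. Its classic failure mode is component sharing: a handful
of multifunctional genes annotated across dozens of pathways drag every one
of those pathways over the significance line as soon as they appear in a
query. `pairsig` shifts the unit of evidence from single genes to
*gene-pair signatures* (GPS): unordered pairs of genes co-annotated in
exactly one pathway. Observing both genes of a signature in a query is
evidence for that specific pathway, and the contribution of a
multifunctional gene is realised only through the partners that pin down
its contextually relevant role.

Formally, the repository is a bipartite graph of genes and pathways whose
edges are annotations. In the weighted one-mode projection onto genes
(`project_one_mode()`), two genes are adjacent iff co-annotated, with edge
value the number of co-annotating pathways; the value-1 edges are the
signatures (`find_signatures()`). A gene annotated in exactly one pathway
(a pathway-unique gene, PUG) enters as a weight-1 self-pair; self-pairs can
be disabled (`include_self_pairs = FALSE`) to restrict the analysis to
genuinely distinct pairs.

### Signature weights

A signature's reliability depends on how committed its genes are to the
shared pathway. With constituent membership counts $i$ and $j$, the default
weight is the average inverse membership

$$w_{i,j} = \tfrac12\Bigl(\tfrac1i + \tfrac1j\Bigr) = \frac{i+j}{2ij} \in (0,1],$$

which is 1 exactly when both genes are PUGs and decays toward 0 for pairs
of promiscuous genes (e.g. $w_{4,3} = 7/24 \approx 0.29$). Two alternative
schemes ship (`"unit"`, all 1, reducing to unweighted pair counting, and
`"min_inverse"`, $1/\max(i,j)$, which penalises a pair by its least
committed member); `register_weight_scheme()` accepts user-defined schemes.
The default is the only scheme used by the package's own defaults and
benchmarks.

### The weighted hypergeometric test

For a query $Q$ a signature is *present* when both of its genes (or the
single PUG gene) are in $Q$. Per pathway, `run_sigora()` sums weights into

* $k$ — present signatures of the tested pathway,
* $n$ — all possible signatures of the tested pathway,
* $m$ — all present signatures repository-wide,
* $N$ — all possible signatures repository-wide,

rounds the four sums to integers and computes the upper tail
$P(X \ge k)$ of the hypergeometric distribution with mass
$\binom{m}{x}\binom{N-m}{n-x}/\binom{N}{n}$ (`hyper_upper_tail()`,
evaluated through the distribution function in log space and clamped to
$[0,1]$; $k = 0$ returns exactly 1). Both Bonferroni and
Benjamini–Hochberg adjusted p-values are always computed; the significance
filter uses the configured one.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `scheme` | `"reciprocal"` | average inverse membership, the weight model above |
| `include_self_pairs` | `TRUE` | PUGs are maximally specific evidence |
| `level` | max compiled level | use the full hierarchy unless asked otherwise |
| `rounding` | `"nearest"` | the sums are rounded to the closest integer; see below |
| `mtc` / `significance` | `"bonferroni"` / 0.001 | the signature universe is orders of magnitude larger than a gene universe, so p-values run far smaller than in gene-level ORA and a strict corrected cut-off is appropriate |
| baseline `mtc` / `significance` | `"bh"` / 0.05 | the convention of gene-level ORA practice |
| `background` | none | restricts present sets, possible sets and the universe to assayed genes |

A background excludes every signature with a constituent gene outside it,
from both the present and the possible sums; pathways whose possible set
becomes empty are omitted from the table and from the number of tests used
by the corrections. The Bonferroni factor is the number of pathways
actually tested (possible weight > 0 at the chosen level and background),
not the repository's pathway count — documented here because tools differ
and the choice changes adjusted p-values.

## Hierarchical repositories

Where a child pathway's genes are all included in a more general parent,
every child pair is co-annotated at least twice and the child would never
receive a signature. `build_gps_db()` therefore iterates: compile
signatures (level 1), remove all current root pathways — those with no
parent among the surviving pathways — together with their annotations,
increment the level and recompile; stop once no hierarchy edges remain
among the survivors (they all get the final level). A (pair, pathway)
signature is emitted only at the first level at which it qualifies, which
keeps per-pathway signature sets disjoint at every level threshold and
makes the level-restricted universe sums well defined. At analysis time
`level` bounds which signatures (and hence which pathways) participate.

Two details the level-wise procedure leaves open were decided as follows:

* **Degrees for weights.** The membership counts $(i, j)$ of a signature
  emitted at level $L$ are computed within the repository remaining at
  level $L$ (`degrees = "level"`, default): after the general pathways are
  gone, a gene's remaining memberships are what determines its commitment
  among the surviving, more specific pathways. `degrees = "global"` keeps
  full-repository counts for users who prefer weights that are invariant
  across levels.
* **Removed annotations.** A pathway removed at level $L$ contributes
  nothing to degree counts at later levels; its annotations leave with it.

## The synthetic repository generator

`generate_repo()` is the package's study-condition generator, not a test
fixture: private gene blocks (sizes uniform in `size_range`, disjoint by
construction, so every private gene has degree 1) plus shared blocks of
`block_size` genes injected into `pathways_per_block` random pathways —
genes of exactly that degree, emulating the observed situation where a
small set of kinases recurs in ~10% of a repository's pathways. With
`hierarchy_depth >= 2`, parents are pure unions of randomly grouped
children, reproducing semantic redundancy. What it does *not* emulate:
real repositories' long-tailed size distributions, partial (non-nested)
overlaps of varying sizes, and correlated annotation errors. Passing
benchmarks on these repositories therefore demonstrates that the method
suppresses sharing-induced false positives under controlled sharing, not
that any particular real-data analysis will reach a given precision.

The simulation protocol plants `n_pathways = 5` pathways, marks a fraction
`alpha` (0.5 or 0.15 in the shipped benchmarks) of each one's genes as
differentially expressed — `max(1, round(alpha * size))` genes, rounded
half away from zero, with the `max(1, .)` floor keeping every planted
pathway represented — and scores each method's significant calls as true
positives (planted), false positives (not planted) and false negatives
(planted but not called). Precision is averaged only over replicates with
at least one significant call (the count is reported as
`replicates_used_for_precision`); the F1 summary is the harmonic mean of
mean precision and mean recall; a planted pathway absent from a method's
table (no possible signatures) is assigned rank $T+1$, one past the table
end. The reduced-scale benchmark shipped in the tests and in
`scripts/acceptance.R` uses 60 pathways of 10–30 genes with 8 shared
blocks of 5 genes × 6 pathways and 100 replicates, sizes chosen so the
whole benchmark runs in seconds while leaving dozens of sharing-coupled
pathway pairs for false positives to arise from.

## Numerical choices

* **Rounding.** Weight sums must be rounded before the hypergeometric test
  is defined. `"nearest"` (default) rounds half away from zero — unlike
  base `round()`, whose round-half-to-even rule would make parameter values
  depend on representation subtleties. `"floor"`, `"ceiling"` and
  `"phyper_compat"` (successes rounded down, the rest to nearest — exactly
  how R's `phyper` treats non-integer input) are provided; the choice
  rarely moves ranks because pathways with very few possible signatures
  are rare.
* **Ties.** Rows are ordered by raw p-value, then larger $k$, then pathway
  id (C-locale radix order), so output is deterministic across platforms.
* **Degenerate inputs.** A query with no overlap with the considered
  signature genes is a hard error reporting the dropped count; unknown ids
  are dropped with a message. A query completing no signature yields all
  p-values exactly 1. Empty result tables export as header-only CSV.
* **Determinism.** All randomness (generation, sampling, benchmarking)
  flows from explicit integer seeds through R's default generator; equal
  seeds give byte-identical outputs.

## Relationship to individual-gene ORA

`run_ig_ora()` is the classic comparator: per pathway, $k$ = query genes
in the pathway, $n$ = pathway size, $m$ = query size, $N$ = annotated
genes, same tail test, sorting and export. On a repository of singleton
pathways (every signature set a single weight-1 self-pair) the weighted
sums coincide with the gene counts and the two engines agree exactly —
the package's reduction check. Note the reduction is *not* exact for
sharing-free pathways of two or more genes: such a pathway of size $s$
owns $\binom{s}{2}$ pair signatures plus $s$ self-pairs, so its possible
weight is $s(s+1)/2$, not $s$; pair evidence is intrinsically richer than
gene evidence even without sharing.

## Limitations

* Signatures are pairs only; higher-order tuples would explode the
  universe for marginal benefit and are not implemented.
* No identifier mapping: query and repository must share an id space.
* Pathways whose genes are entirely shared with others carry no signatures
  and are undetectable by design — the price of specificity.
* P-values inherit ORA's independence assumptions; no permutation or
  expression-level (GSEA-style) scoring is provided.
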