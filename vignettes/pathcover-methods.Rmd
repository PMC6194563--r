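---
title: "Greedy set cover for pathway redundancy reduction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy set cover for pathway redundancy reduction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcover)
```

## The problem

Pathway databases draw arbitrary boundaries around overlapping biology, and
consolidated collections inherit every boundary at once: the same gene can
belong to dozens of pathways describing the same process at different
granularities. This redundancy makes collections hard to browse and floods
pathway-enrichment output with near-duplicate hits. `pathcover` treats the
problem as classical **set cover**: pathways are sets, genes are elements,
and we want a small sub-collection of *unaltered* pathways whose union still
covers the genes of interest. No merging takes place, so every selected
pathway retains its curated identity, and the algorithms remove overlap
between arbitrarily many pathways at once rather than thresholding pairs.

## The greedy cover and its three scores

Let $s_i$ be pathway $i$'s gene set, $U = \bigcup_i s_i$ the universe, $C$
the covered and $R = U \setminus C$ the uncovered genes. The loop scores
every *candidate* pathway -- one with $s_i \cap R \neq \emptyset$ -- and
adds the argmax to the cover until $|C| \ge \lceil GC \cdot |U| \rceil$:

* **standard**: $v_i = |s_i \cap R|$. The textbook greedy heuristic with
  the $H(\max_i |s_i|)$ approximation guarantee (a property the test suite
  checks against brute-force optima on exhaustively enumerable instances).
  It shrinks the cover count fastest but is biased toward very large,
  functionally unspecific pathways.
* **proportional**:
  $v_i = \dfrac{|s_i \cap R|}{|s_i|} +
  \dfrac{1}{\max(\lvert\,|s_i| - \overline{|s|}\,\rvert,\ 0.5)\cdot k}$,
  $k = 10000$. Ranking by the *proportion* of uncovered genes penalises
  overlap directly and removes the large-pathway bias; the second term
  breaks the ubiquitous first-iteration ties (every pathway starts at
  proportion 1) toward pathways of mean size. With $k = 10000$ the term is
  at most $2\times10^{-4}$, so it can never override a proportion gap of
  $3\times10^{-4}$ or more.
* **hitting**: genes are valued by rarity, $v_j = 1/f_j$ with $f_j$ the
  number of pathways containing gene $j$, and
  $v_i = \sum_{j \in s_i \cap R} v_j \,/\, |s_i|$. The dual (set-hitting)
  view: genes found in a single pathway force that pathway into any full
  cover, so pathways holding rare genes should be taken early, and dividing
  by $|s_i|$ avoids rewarding size as such. Scores live in $[0, 1]$,
  reaching 1 only for a pathway whose genes are all uncovered and unique
  to it.

Two run constants are computed **once** over the full input collection and
frozen: the mean pathway size $\overline{|s|}$ and the frequencies $f_j$.
They describe the data set, not the shrinking candidate pool; recomputing
them during the run would make scores depend on the selection history in a
way the model does not intend.

### Gene coverage (GC)

The final iterations of a full cover are the worst ones: the few remaining
genes often live only in pathways that largely duplicate what is already
selected. `gc_fraction` ($GC$) stops the loop once
$\lceil GC \cdot |U| \rceil$ genes are covered, trading a small loss of
coverage for a disproportionate gain in redundancy and size control. Under
deterministic tie-breaking a lower-GC result is always a prefix of a
higher-GC result, which the test suite asserts; useful values in practice
are 0.90--1.00.

### Numerical and tie-breaking choices

* Scores are floating-point; the argmax uses a relative tolerance of
  `1e-12`, so mathematically equal scores computed along different
  arithmetic paths tie reliably across platforms.
* Residual ties resolve deterministically by default: largest
  newly-covered count, then lexicographically smallest pathway id. A
  `tie_policy = "random"` mode (mandatory seed) exists to explore how early
  tied selections propagate -- the proportional score's first iteration is
  the canonical case -- while keeping runs reproducible.
* Only candidates (pathways adding $\ge 1$ new gene) are ever scored, in
  all three algorithms. This guarantees progress, keeps the selection log's
  "new genes" column positive, and prevents the proportional score's size
  term from selecting an already-covered pathway.
* If a user-supplied `universe` contains genes no pathway provides, a full
  cover is impossible: the run terminates, flags the result
  (`complete = FALSE`) and warns, rather than erroring -- partial output is
  still meaningful, and the command-line wrapper should degrade gracefully.
  With the default universe (derived from the collection) this branch is
  unreachable.
* The engine updates per-pathway uncovered counts incrementally through a
  gene-to-pathway index; an intentionally naive full-rescan reference
  implementation lives in the test helpers, and equality of the two
  selection sequences is asserted over randomized instances for all three
  algorithms and several GC values.

## Enrichment set cover

Enrichment results come pre-scored: each pathway has an adjusted p-value,
and the universe is the set of differentially expressed (DE) genes mappable
to at least one enriched pathway. All cover logic is restricted to
$s_i \cap \mathrm{DE}$ -- pathway members that were not differentially
expressed play no role. Define $b = 1$ if $s_i \cap R \neq \emptyset$ and
$0$ otherwise, and $v_i = (1 - p_i) \cdot b$. Repeatedly taking the argmax
of $v_i$ keeps the lowest-p pathway that still covers something new, which
is equivalent to a single pass over the p-sorted list retaining every
pathway with an uncovered DE gene. Both formulations are implemented
(`method = "walk"` and `"argmax"`) and cross-checked on random studies; the
walk is the default. Consequences, all asserted as properties:

* the retained list is the input order with deletions -- p-value ranking is
  never disturbed;
* every retained pathway has a witness DE gene absent from all
  more-enriched retained pathways;
* after the full walk the retained pathways cover the entire DE universe;
* for every $n$, the top-$n$ retained pathways cover at least as much as
  the top-$n$ input pathways, so a reader of the "top 10" sees strictly
  more of the gene set.

Ties in $p$ make the argmax ambiguous; the package orders entries by
$(p, \text{id})$ and applies the walk rule, which is deterministic. No
significance threshold is applied inside the module -- callers pre-filter
(conventionally adjusted $p < 0.05$). The removed-pathway report annotates
each casualty with the earliest retained pathway whose gene set, unioned
with the retained pathways before it, covers the removed one; this is
bookkeeping for the reader, not part of the algorithm.

## Redundancy metrics

* **Overlap score**: $\sum_i |s_i| \,/\, |\bigcup_i s_i|$, identically the
  mean per-gene membership count (the two computations are compared to
  `1e-12` in the tests). A disjoint collection scores exactly 1. For a
  cover result the denominator counts only genes the result covers:
  counting genes a GC < 1 run deliberately left out would let scores dip
  below 1 and break the discrete-set anchor.
* **Reduction percentage**:
  $100 (\text{orig} - \text{new}) / (\text{orig} - 1)$. Normalising by the
  *removable* redundancy (everything above the discrete-set score of 1) is
  the convention consistent with reporting a drop from 12.4 to 4.1 as 73%;
  naive normalisation by the original score would give 67%.
* **Jaccard distribution**: all unordered pairs, histogrammed over 20
  right-closed bins by default, with exactly-zero pairs in their own row
  (they dominate sparse collections and would otherwise swamp the first
  bin); the maximum is reported separately as the single most redundant
  pair.
* **Size statistics** use the sample standard deviation ($n-1$); at
  realistic collection sizes the choice is immaterial, but it is fixed and
  documented.
* **Source composition** relies on the GMT description field: it is taken
  as the source-database label when it matches a configurable vocabulary
  (the major databases of consolidated human collections by default),
  otherwise `"unknown"`. Gene identifiers are treated as opaque
  case-sensitive strings -- the package is namespace-agnostic -- with an
  opt-in upper-casing flag at parse time.

## The synthetic generator

Real consolidated collections cannot be bundled, so the package generates
collections whose *structure* matches what the algorithms care about. A
`collection_recipe()` describes:

* **latent modules** -- shared gene blocks standing in for real functional
  units; pathways assemble an `overlap_intensity` share of their genes from
  sampled modules, which produces the partial-overlap backbone;
* **a long-tailed peripheral pool** -- each remaining gene slot reuses an
  existing peripheral gene with probability proportional to
  `overlap_intensity` and the gene's current frequency (a Chinese-
  restaurant-process scheme), otherwise mints a new synthetic token
  (`G000001`, ...). This yields the skewed gene-frequency distribution of
  real collections: a few very frequent genes, many singletons that force
  specific pathways into any full cover. At `overlap_intensity = 0` every
  draw is fresh and the collection is disjoint in expectation;
* **subset pathways** -- with probability `subset_rate` a pathway is a
  random strict subset of an earlier one, planting exactly the redundancy
  the cover algorithms exist to remove;
* **log-normal sizes** and **weighted source labels** mirroring the size
  heterogeneity and multi-database character of consolidated human
  collections.

Generation is a pure function of the recipe (seed included): identical
recipes give byte-identical GMT output. The fixed benchmark,
`cpdb_like_recipe()` (600 pathways, log-normal sizes of meanlog 3.4 and
sdlog 0.9, `overlap_intensity` 0.9, `subset_rate` 0.15, 80 modules of 4--40
genes, seed 20150924), produces roughly 2400 genes at overlap score ~10.6 --
a desk-scale analogue of a collection whose genes average double-digit
pathway membership. On it the three algorithms separate as they should:
standard needs the fewest pathways, proportional has the smallest size
standard deviation, hitting reaches the lowest residual overlap, and every
algorithm's overlap falls further at GC 95%.

Enrichment studies are simulated by declaring some modules "differentially
expressed": DE genes are drawn from those modules plus a uniform noise
fraction, and every pathway gets a p-value from the one-sided upper
hypergeometric tail of its DE overlap given the universe size, the DE count
and the pathway size (`stats::phyper`). The hypergeometric is the canonical
over-representation model and gives the realistic joint structure of
(gene set, p-value) the enrichment cover needs; length-bias-aware testing
(GOseq-style) is deliberately *not* emulated, because the cover consumes
p-values rather than producing them. A pathway disjoint from the DE set
receives $p = 1$.

What passing tests on these collections does **not** show: behaviour under
real identifier namespaces and mapping noise, curation biases that
correlate pathway size with database of origin, or topology-aware pathway
semantics -- the generator emulates set structure only.

## Problem sizes

The shipped suites run at sizes chosen to exercise every code path while
keeping a full check quick on a laptop: oracle-equivalence instances up to
50 pathways by 200 genes across 100 seeds; brute-force optimality instances
up to 12 pathways (exhaustive subset enumeration); property suites over
100 random enrichment studies; and the 600-pathway benchmark for the
behavioural signatures. The acceptance script regenerates the benchmark
and recomputes all reported quantities end to end in a few seconds.

## Known limitations

* Greedy set cover approximates, never guarantees, the minimum cover; the
  harmonic bound is the only worst-case statement available.
* The proportional score's first iteration is decided almost entirely by
  the size-preference term; with many pathways near the mean size the
  deterministic id tie-break (or the seeded random policy) decides, and
  early choices propagate.
* Overlap scores of GC < 1 runs use the covered-gene denominator; comparing
  them against full-universe scores from other tools requires care.
* `enrichment_cover()` trusts its input p-values: no multiple-testing
  correction, no re-testing, and identical gene sets with identical
  p-values are ordered by id.
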