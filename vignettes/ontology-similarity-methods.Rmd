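---
title: "Semantic similarity over is-a ontologies: models and design choices"
author: "ontosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic similarity over is-a ontologies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosim)
```

## The problem

Controlled vocabularies such as the Disease Ontology organise their terms in
a rooted directed acyclic graph whose only edge type is "is-a": a child term
is a subtype of each of its parents, and the deeper a term sits, the more
specific it is. Two questions recur in practice. How similar are two terms,
given where they sit in the DAG and how often genes are annotated to them?
And how similar are two *genes*, given the sets of terms each is annotated
with? `ontosim` answers both, and adds the standard downstream machinery:
hypergeometric enrichment of a gene set, module detection on a similarity
matrix, and subgraph extraction for visualisation.

## Information content

For a term $t$, let $p(t)$ be the fraction of the annotated gene universe
annotated to $t$ *or any of its descendants* (distinct genes, not annotation
rows). Its information content is

$$IC(t) = -\log p(t).$$

Three choices here are deliberate:

* **Universe.** The denominator of $p(t)$ is the number of genes with at
  least one annotation in the corpus, not a genome-wide count. This keeps
  $p(\mathrm{root}) = 1$ and $IC(\mathrm{root}) = 0$ by construction.
  Enrichment allows a user-supplied universe size for strict replication of
  analyses that used a genome total.
* **Log base.** Natural log by default, configurable. Ratio measures (Lin,
  Rel, GIC, CoutoLin) are provably invariant to the base — the tests check
  this — but Resnik values and the Jiang–Conrath clamp are not, so the base
  is recorded in every IC table and output file.
* **Zero counts.** A term no gene reaches has $p(t)=0$ and no defined IC; it
  is excluded from the IC domain and IC-based measures refuse it with a
  clear error. The structural Wang measure still accepts it.

## The ten term-term measures

Write $I_1, I_2$ for the ICs of the two terms, $I_M$ for the IC of the most
informative common ancestor (MICA; ancestors include the term itself), and
$p_M$ for the MICA's annotation probability. The implemented measures are

| measure | formula | range |
|---|---|---|
| Resnik | $I_M$ | $[0, \max IC]$ |
| Lin | $2I_M/(I_1+I_2)$ | $[0,1]$ |
| JC | $1-\min(1,\, I_1+I_2-2I_M)$ | $[0,1]$ |
| Rel | $\mathrm{Lin}\cdot(1-p_M)$ | $[0,1]$ |
| GIC | $\sum_{a \in CA} IC(a) \,/\, \sum_{a \in A_1 \cup A_2} IC(a)$ | $[0,1]$ |
| simIC | $\mathrm{Lin}\cdot(1-1/(1+I_M))$ | $[0,1]$ |
| CoutoResnik / CoutoLin / CoutoJC | as above with $Share$ for $I_M$ | as above |
| Wang | shared semantic contributions over $SV_1+SV_2$ | $[0,1]$ |

**GraSM shared information.** Two ancestors $a_1, a_2$ of a term $t$ are
*disjunctive* when each can reach $t$ by a directed path avoiding the other —
they encode genuinely independent interpretations of $t$. A common ancestor
$a$ of a pair $(t_1,t_2)$ is a *disjunctive common ancestor* (DCA) when every
common ancestor of strictly higher IC is disjunctive with $a$ for $t_1$ or
for $t_2$; the MICA qualifies vacuously. $Share(t_1,t_2)$ is the mean IC over
the DCA set. Conventions worth stating:

* A path passes through its endpoints. Consequently no pair involving $t$
  itself is ever disjunctive, $DCA(t,t)=\{t\}$, and in the containment case
  (one term an ancestor of the other) the DCA set is the MICA alone.
* Equal-IC ancestors never exclude one another (the comparison is strict),
  and since ties then all enter the DCA set at the same IC, $Share$ is
  unaffected by tie order.
* On a tree — where all common ancestors form a chain and no disjunctive
  pair exists — the DCA set collapses to the maximal-IC common ancestors and
  the three Couto variants reduce *exactly* to Resnik, Lin and JC. The test
  suite asserts this to 1e-12 and checks the full DCA machinery against an
  exhaustive all-paths enumeration oracle on hundreds of small random DAGs.

**Jiang–Conrath as a similarity.** JC is natively a distance
($I_1+I_2-2I_M$); we clamp it with $1-\min(1,\cdot)$ so the reported value is
a similarity in $[0,1]$. The clamp interacts with the log base (a distance
of 1 nat is not a distance of 1 bit), which is the second reason the base is
recorded in output metadata.

**Wang contributions.** Within the sub-DAG of a term $A$ and its ancestors,
each edge carries the factor $w_e$ (default 0.7, the conventional value for
is-a edges); the contribution of an ancestor $a$ to $A$ is the maximum over
directed paths $a \rightsquigarrow A$ of the product of edge factors, computed
by dynamic programming over a topological order of the ancestor sub-DAG, and
$SV(A)$ is the sum of contributions. The pair similarity adds both terms'
contributions over their shared ancestors and divides by $SV(A)+SV(B)$.
Because every edge carries the same factor, the best path is the shortest
path — which gives an independent oracle ($w_e^{\text{shortest path}}$) that
the tests exploit.

**Degenerate input.** When both terms are the root, $I_1+I_2=0$ and the
ratio measures return 1 (identical terms are maximally similar); GIC returns
1 by the same convention when the ancestor-union IC sum is zero. MICA ties
are broken by lexicographically smallest accession, which only matters for
reporting — every downstream value is tie-invariant.

**Resnik normalisation.** Resnik and CoutoResnik are reported on the raw IC
scale by default; `normalize_resnik = TRUE` divides by the corpus-wide
maximum IC. Off by default because the raw scale is what the measure's
definition produces and rescaling is a presentation choice.

## Gene-gene similarity

A gene is represented by its set of **direct** annotations — no ancestor
propagation, since propagation would make every gene similar to every other
through the upper ontology. Given the $m \times n$ matrix $S$ of term
similarities between two genes' sets, with `rowScore`/`columnScore` the
means of row/column maxima:

* `Max`, `Mean`: grand maximum / grand mean of $S$;
* `funSimMax`, `funSimAvg`: max / mean of the two directional scores;
* `BMA`: best-match average, $(\sum_i \max_j s_{ij} + \sum_j \max_i s_{ij})/(m+n)$.

These obey `Mean ≤ funSimAvg ≤ funSimMax ≤ Max` and `Mean ≤ BMA ≤ Max` for
every matrix, which the suite property-tests on a thousand random matrices.
Genes with no usable annotation are dropped with a report, not scored zero —
an unannotated gene is unknown, not dissimilar. The diagonal of a gene
matrix is each gene's computed self-similarity, not a forced 1, so
unnormalized measures stay meaningful; the choice is recorded in output
metadata.

## Enrichment

For a candidate term with $M$ of the $N$ universe genes annotated to it
(propagated), and $x$ of the $k$ query genes, the p-value is the
hypergeometric upper tail $P(X \ge x)$, computed via `stats::phyper` (which
works on log scales internally and is numerically stable). Two pre-specified
criteria pick the candidates *before* testing: `filter` (minimum propagated
count — terms annotated by almost nobody are untestable) and `layer`
(minimum depth — terms near the root are uninformatively general; "beneath
depth $m$" is read as $depth \ge m$ with the root at 0). FDR is
Benjamini–Hochberg **across the candidate set only**: the filter is part of
the pre-registered design, not a data-dependent selection, so correcting
over never-tested terms would be misleadingly conservative. `enrich_map()`
exposes the same engine over any flat term→gene list, which is how module
annotation against external vocabularies plugs in without the DAG.

## Module detection

Similarities become distances by $d = 1 - s$ (matrices whose maximum
exceeds 1 are rescaled by that maximum first; the scale is recorded).
Clustering is average-linkage (UPGMA) via `stats::hclust`. Two cuts are
offered:

* **Static**: components of merges strictly below a height $h$; components
  smaller than `min_size` go to the grey group (module 0). Strictness makes
  `height = 0` mean "no merge at all" rather than "merges at exactly 0".
* **Dynamic (gap-based)**: the dendrogram is recursively split at the
  largest gap in its sorted merge heights, but only when that gap exceeds
  `gap_frac` (default 0.3) of the *root* height; branches that cannot split
  further and hold ≥ `min_size` leaves become modules. Judging gaps against
  the root height rather than the local subtree height is deliberate: local
  relative gaps inside a tight cluster are dominated by noise and would
  shatter genuine modules. The cost is insensitivity to nested structure at
  very different scales, which a static cut at a second height can recover.
  Every returned module is by construction a contiguous dendrogram branch —
  a structural invariant the tests check directly.

Module significance is by permutation: the observed statistic is the mean
off-diagonal within-module similarity; the null redraws label subsets of the
same size from the matrix at hand (not from any larger population — the
inference is conditional on the analysed set), and
$p = (b+1)/(\text{reps}+1)$ with add-one smoothing so that finite replication
never reports $p = 0$; the floor $1/(\text{reps}+1)$ is the honest resolution
limit. The pairwise significance threshold mirrors the same idea at the pair
level: pool all pairwise similarities from repeated random subsets and take
a high percentile (99th by default) as the cutoff.

All randomness flows through explicit integer seeds; the RNG state of the
calling session is saved and restored, so library calls never perturb user
code.

## What the synthetic generators emulate — and what they do not

* `random_ontology()` builds layered DAGs (each term's parents come from
  strictly shallower layers), which guarantees acyclicity and a single root
  and reaches every multi-parent topology the similarity measures care
  about. It does not emulate the size (thousands of terms), the heavy-tailed
  fan-out, or the depth imbalance of a real disease vocabulary.
* `random_corpus()` draws annotations uniformly; real corpora are strongly
  skewed toward a few well-studied genes and shallow terms. Uniformity is
  the right null for correctness testing but says nothing about measure
  behaviour under realistic annotation bias.
* `planted_similarity()` produces block matrices (within-block similarity
  0.9, between 0.1, Gaussian noise sd 0.02 by default — far crisper than
  any real gene-similarity matrix). Exact recovery there demonstrates that
  the cutting machinery is correct, not that it will resolve the much
  subtler module structure of real data.

Passing tests on these generators therefore certify the *algorithms*;
conclusions about any real ontology still require that ontology and its
annotation corpus as inputs.

## Problem sizes and numerical conventions

The shipped test suite and the acceptance script run on deliberately small
problems — the 9-term worked fixture, two hundred random DAGs of at most 12
terms for the brute-force oracle comparisons, planted matrices of 22–53
items over 20 seeds, permutation runs of 100–4000 draws — sizes at which
exhaustive enumeration oracles are feasible, every quantity can be verified
independently, and the whole suite completes in about a minute. All
comparisons against 4-decimal reference values use absolute tolerance 1e-4;
algebraic identities (tree reductions, log-base invariance, oracle
equivalence) are asserted to 1e-12. Percentiles use R's default type-7
quantile. Similarity matrices are symmetrised defensively after floating
arithmetic; symmetry violations above 1e-8 on input are an error, not
silently repaired.

## Known limitations

* Only "is-a" edges are interpreted; `part-of`/`regulates` relationship
  lines are ignored with a warning rather than modelled.
* GraSM's disjunctive-pair computation does one reachability pass per
  ancestor and scales as roughly ancestors² per term pair — fine up to
  thousands of terms, but no cross-process caching is attempted.
* The dynamic cut exposes `min_size` and `gap_frac` only; it is a
  single-scale method by design (see above).
* Obsolete terms are parsed and retained for bookkeeping but excluded from
  every analysis; no semantics (replaced-by chains) are resolved beyond
  `alt_id` mapping.
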