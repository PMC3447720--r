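---
title: "Scoring the functional coherence of biclusters: methods and design"
author: "BicScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the functional coherence of biclusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BicScore)
```

# The problem

A bicluster is a set of genes together with a set of experimental conditions
under which those genes are co-expressed. Different biclustering algorithms
applied to the same expression matrix return very different biclusters, and
the obvious summaries of biological quality are biased: counting enriched GO
terms rewards large biclusters, and taking the single best enrichment
p-value rewards them too, while genes without any annotation distort both.
BicScore implements two size-robust coherence scores — one from Gene
Ontology annotation, one from a protein–protein interaction (PPI) network —
plus the filtering, pooled ranking, random baseline and consistency analysis
needed to compare algorithms on equal footing.

# The weighted enrichment score

For a bicluster $B$ and an annotation map over a gene universe of size $N$,
every term with at least one annotated bicluster gene is tested with the
upper-tail hypergeometric probability

$$p = \sum_{i \ge x} \frac{\binom{PN}{i}\binom{N-PN}{X-i}}{\binom{N}{X}},$$

where $x$ is the observed overlap, $PN$ the term size in the universe, and
$X$ the number of genes drawn. The Benjamini–Hochberg step-up procedure is
applied across the tested terms (the family is the terms of one bicluster,
matching per-cluster enrichment practice), and terms with adjusted
$q \le \alpha$ (default $\alpha = 0.05$) are retained. Each significant term
$i$ receives $s_i = -\log_{10} p_i$ and the bicluster scores

$$\mathrm{WE} = \frac{x_1 s_1 + \dots + x_n s_n}
                     {x_1 + \dots + x_n + \mathit{non}},$$

with $\mathit{non}$ the number of bicluster genes that carry annotation but
belong to no significant term. The score is a weighted mean of the terms'
$-\log_{10} p$ values diluted by annotated-but-unenriched genes; it is
bounded by the largest term score and does not grow with bicluster size.

## What enters the hypergeometric draw

$X$ is taken to be the number of bicluster genes *carrying at least one
annotation*, not the raw bicluster size. A gene with no annotation cannot
contribute to any overlap $x$, and counting it in $X$ would let unannotated
genes shift every p-value. With the annotated count as $X$, the WE score is
exactly invariant to adding or removing unannotated genes — the defining
robustness property of the score — and the test suite asserts this
invariance on randomized fixtures.

## Which p-value is scored

Significance is decided on the BH-adjusted $q$, so by default the same
adjusted value enters $s_i = -\log_{10} q_i$; scoring one quantity and
selecting on another would make the score discontinuous at the significance
boundary. A `scoreOn = "raw"` mode scores the unadjusted p-value instead.
The logarithm base is 10 by default, making $s_i$ read as orders of
magnitude of significance; `logBase` accepts any base (e.g. `exp(1)`).

## Numerical choices and degenerate inputs

* The upper tail is computed with the hypergeometric survival function
  (`phyper(..., lower.tail = FALSE)`), never as $1 - \mathrm{CDF}$, so
  p-values far below $10^{-12}$ remain accurate.
* p-values are floored at $10^{-300}$ before the logarithm, keeping term
  scores finite.
* Terms covering the whole universe ($PN = N$) are tested like any other;
  they yield $p = 1$ and drop out naturally.
* A bicluster with no significant term scores WE $= 0$ — the lowest possible
  value — rather than being dropped, so it ranks last; the result carries a
  `noEnrichment` flag. A bicluster none of whose genes is annotated also
  scores 0, with a warning and a `noAnnotation` flag.
* Ties in the enrichment table are broken by adjusted p then term id, so the
  output is deterministic.

# The PPI score

Against an interaction network retaining edges with combined confidence
strictly greater than a cutoff (default 0.7, the conventional
high-confidence setting for STRING-style combined scores),

$$\mathrm{PPI} = \frac{I}{N - M},$$

where $N$ is the bicluster gene count, $I$ the number of bicluster genes
with at least one retained edge to *another gene of the same bicluster*
(genes are counted, not edges), and $M$ the number of bicluster genes
unknown to the interaction source. The score is the fraction of
database-known bicluster genes that actually interact within the bicluster,
in $[0, 1]$.

Two membership conventions for $M$ are provided. The default,
`mMode = "database"`, counts a gene toward $M$ only when it is absent from
the *pre-threshold* identifier roster of the source file — i.e. the database
has never seen it interact with anything; a gene whose every edge falls
below the cutoff still counts as known. `mMode = "graph"` instead uses the
thresholded graph's node set, for interaction sources that ship no full
roster. When $N = M$ (no bicluster gene known at all) the ratio is
undefined; it is reported as 0 with an `undefined` flag so such biclusters
rank last instead of disappearing.

STRING-style files carry combined scores either as integers in 0–999 or on
the unit scale; `readPPINetwork(scoreScale = "auto")` divides by 1000
whenever any score exceeds 1. Self-loops are dropped silently and parallel /
reversed duplicate edges collapse to the maximum weight.

# Filtering, ranking and consistency

Before scoring, biclusters with fewer than `minGenes` genes or
`minConditions` conditions are removed ("fewer than" is strict: a bicluster
with exactly the threshold counts is retained). The conventional settings
are 5 genes / 2 conditions for a large compendium and 5 genes / 3 conditions
for a small pathway-focused matrix; both are ordinary parameters, not
constants.

All scored biclusters — regardless of source algorithm — are pooled and
sorted by one score, descending. Ties take the mean rank; presentation order
breaks ties deterministically by (algorithm, id). Entries are then cut into
`nSections` contiguous rank bands whose sizes differ by at most one; four
sections (quartiles) is the default, chosen as the coarsest binning that
still separates "top" from "upper-middle" behaviour, and it is
configurable. The per-algorithm section-count matrix is the comparison
diagnostic: a good algorithm concentrates its biclusters in section 1.

Agreement between the WE and PPI views is measured with Kendall's tau-b on
the paired score lists. Tau-b is used because realistic score lists are
heavily tied (many exact zeros from unenriched or non-interacting
biclusters) and tau-b corrects for ties in both lists; the p-value comes
from the exact distribution for small tie-free samples and otherwise from
the normal approximation with tie-adjusted variance. When several datasets
are scored, their score tables are pooled into a single consistency estimate
by default, with per-dataset estimates available by ranking each report
separately.

# The synthetic world

The generators exist so that every scoring stage can be exercised, end to
end and through the file formats, without any external download. One
`synthConfig()` fixes a consistent world:

* **Annotation map** — `nTerms` disjoint terms partition a seeded random
  subset of the universe covering `annotationCoverage` of the genes; the
  universe is the full gene set, so unannotated genes exist whenever
  coverage < 1.
* **Interaction network** — the interaction modules *are* the annotation
  terms (by default): within-module pairs get an edge with probability
  `withinModuleEdgeProb` and weight above the confidence cutoff, while
  cross-module pairs receive sparse sub-threshold background edges
  (`backgroundEdgeProb`) whose endpoints still register in the database
  roster. After thresholding, retained edges are within-module.
* **Expression matrix** — Gaussian background noise (`noiseSd`) with
  `nImplanted` blocks shifted by `signalShift`, each block's genes drawn
  from a single term/module, so the implanted truth biclusters are
  functionally coherent under both scores.
* **Random baseline** — `randomGeneGroups()` samples genes and conditions
  uniformly, copying the size pair of a random reference bicluster, so the
  baseline is size-matched and any score contrast is attributable to
  coherence, not size.

The default conditions are a universe of 1000 genes under 16 conditions,
80% annotation coverage in disjoint terms of 20 genes, within-module edge
probability 0.6, five implanted biclusters of 10 genes, and 15 random
groups. With terms of 20 genes covering 80% of a 1000-gene universe, the
partition requires 40 disjoint terms; the generator validates this
feasibility and rejects configurations whose coverage cannot be realised
within the term-size range. The background edge probability (0.002) gives a
typical gene one or two sub-threshold edges, so most random-group genes are
"known to the database" — without this, random groups would be scored
undefined rather than low, which is the less informative failure mode.

The `separationStudy()` driver runs this comparison over independently
seeded replicates and records, per replicate, the median scores of truth and
random groups and the fraction of truth biclusters in the top half of each
unified ranking. The acceptance checks run 100 replicates; with five
10-gene implants drawn from 20-gene terms in a 1000-gene universe the
enrichment signal is strong, which is intended — the study validates the
machinery's direction and determinism, not its power near the detection
boundary.

## What the synthetic world does not emulate

Real annotation is hierarchical and nested (a gene annotated to a term is
implicitly annotated to its ancestors), term sizes span orders of magnitude,
and terms overlap heavily; the generator uses disjoint, equally-sized terms.
Real interaction networks have hubs and scale-free degree structure; the
generator plants clean modules. Real biclusters overlap and follow richer
coherence models than an additive shift — irrelevant here, since the scores
never read expression values, but it means passing tests say nothing about
how well any *biclustering algorithm* would recover these implants. GO
true-path propagation is therefore off by default and out of scope for the
generator; enrichment against a propagated annotation map works unchanged
if the caller supplies one.

# Problem sizes

The bundled tests run the exhaustive hypergeometric oracle for all parameter
combinations with universe size up to 30, the BH step-up oracle on 1000
random vectors, the tau-b brute-force oracle on 500 tied vectors of length
up to 50, PPI enumeration on networks of up to 12 nodes, and the separation
study on 100 replicates of the default configuration — sizes chosen so the
full suite completes in well under a minute while covering every code path
and boundary case.

# Known limitations

* The WE score inherits the annotation's biases: a bicluster of genes from a
  poorly annotated process scores low regardless of its real coherence.
* With `mMode = "database"`, $M$ depends on the completeness of the source
  file's roster; for a sub-networked edge list, graph mode is the honest
  choice.
* Section assignment cuts tied ranks at band boundaries by the deterministic
  presentation order; with massive ties the boundary placement is arbitrary
  (though reproducible).
* The per-bicluster multiple-testing family means WE scores of different
  biclusters are corrected over different family sizes; this matches
  per-cluster enrichment practice but is not a global FDR across the whole
  bicluster collection.
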