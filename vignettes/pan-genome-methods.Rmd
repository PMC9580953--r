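---
title: "Pan-genome partitioning and accumulation-curve models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome partitioning and accumulation-curve models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangenomics)
```

## The analysis in one paragraph

A bacterial species' pan-genome is the union of gene families across a
panel of genomes. Starting from per-strain protein sets, the package
builds a protein similarity graph, partitions it into gene families with
Markov clustering, projects families onto a presence/absence matrix,
classifies them into core / accessory / strain-specific subsets, and
models the growth of the pan-genome and the shrinkage of the core genome
as genomes are added. Downstream, externally produced annotations
(functional categories, trait genes, localization and adhesin scores,
host-interaction edges) are summarized over the subsets. This vignette
explains each model, its assumptions, and the numerical choices; the
README shows a worked run.

## Similarity graph and Markov clustering

Two input routes exist. An imported all-vs-all hit table (the common
12-column tabular dialect) is filtered at an e-value cutoff of 1e-5 —
the customary ortholog-detection significance level — self-hits dropped,
and reciprocal hits merged into one undirected edge. The default edge
weight is min(−log10 e-value, 200): monotone in significance and bounded,
so a single exact duplicate pair cannot dominate the flow matrix. A bit
score weight is available as an option. The built-in scorer instead
screens candidate pairs by a shared 5-mer and scores them by global
alignment under BLOSUM62 with affine gaps (open 11, extend 1, the common
protein-search defaults); it computes no e-value statistics and is meant
for self-contained runs and simulations, not as a search-engine
replacement.

MCL parameters follow the range customary for ortholog graphs: expansion
2, inflation 2.0, pruning at 1e-5, convergence when the largest entrywise
change falls below 1e-6, capped at 100 iterations (non-convergence
returns the current partition with a warning flag rather than failing the
run). Regularizing self-loops — each node's loop weighted by its maximum
incident edge — are added before iterating, the standard damping of
period-2 oscillations. Cluster read-out keeps the column-stochastic
matrix's attractors (rows retaining mass); attractors that reach each
other merge; every remaining node attaches to the attractor system
pulling it hardest, with exact ties broken toward the lexicographically
smallest cluster id so the partition is deterministic and invariant to
input order. Inflation controls granularity: larger values cut the graph
finer, and clusters can never span disconnected components because matrix
powers preserve the block structure.

## Partition conventions

Core = present in all G genomes; unique = present in exactly one;
accessory = at least two but fewer than all. The three subsets are
disjoint by construction — note that an inclusive reading of "shared by
two or more strains" would let accessory swallow core; the disjoint
definition is the one under which published subset counts add up to the
pan-genome total. Two reporting conventions matter for reproducing
printed tables and are therefore fixed defaults:

* subset percentages are **truncated** to two decimals (449/2609 →
  17.20, where rounding would print 17.21), with a 1e-9 nudge before
  truncation to absorb binary floating-point representation error;
* genome-features summaries use the **population** standard deviation
  (divisor n, not n − 1), the convention matching descriptive "mean ±
  SD" lines for a fixed strain panel rather than a sample estimate.

With a single genome every family is formally both core and unique; the
partition reports them as core and sets a degenerate flag, keeping the
subsets disjoint.

## Accumulation curves and their models

For each random genome ordering, pan(N) is the number of distinct
families among the first N genomes, core(N) the number present in all of
them, and new(N) the families first seen at position N. The aggregate
over orderings is the median (robust to the occasional ordering that
front-loads an atypical genome); 100 seeded permutations are the default,
a conventional choice that leaves the median's Monte-Carlo error well
below one gene family at the panel sizes involved. An exhaustive mode
enumerates all N! orderings for small panels and is what the tests
compare against.

**Heap's law** `n = k·N^γ` is fitted by ordinary least squares of log n
on log N. On noise-free power-law data this is exact, and it is the
standard estimator for Heap's exponent; a direct nonlinear fit
(`method = "nls"`, seeded from the log-log estimates) is available for
heteroscedastic series but is not the default because it changes the
error model without changing the call in practice. With α = 1 − γ the
pan-genome is called open when α < 1 and closed when α > 1; |α − 1| ≤
1e-9 is reported as "boundary" rather than forcing a call, since at the
boundary the data cannot distinguish the two regimes.

**Offset exponential** `n = k·exp(−x/t) + tgθ` is fitted by separable
least squares: the model is linear in (k, tgθ) once t is fixed, so each
of 400 log-spaced candidates for t (0.05–500 in units of the series'
x-spacing) is scored by its linear-subproblem residual, and the best
candidate is refined by golden-section search between its grid
neighbours to a 1e-9 tolerance. This is deterministic and globally
robust, which is why it is preferred over random-start nonlinear
optimization; on exact model data it recovers parameters to better than
1e-3 relative error (the tests sweep k, t and tgθ grids). A constant
series makes t unidentifiable (k ≈ 0); the fit then returns the series
mean as the asymptote with the identifiability flag cleared, and the
flag propagates into the stabilization summary. The core fit's
asymptote tgθ is the expected core-genome plateau; the new-genes fit's
asymptote is the expected number of novel genes per additional genome.
Whole-gene phrasings of these asymptotes are truncated (1182.675 →
"approximately 1,182"), matching how such estimates are quoted. When the
new-genes series is fitted, its N = 1 point (the first genome's entire
repertoire, not a "new genes" observation) is excluded by the pipeline.

## The synthetic generator

`simulatePanGenome()` emulates exactly the structure the analysis
assumes: a fixed core present everywhere, accessory families each
assigned to f genomes drawn uniformly without replacement (2 ≤ f < G),
and per-genome Poisson counts of strain-specific families. All draws
come from one seeded stream, so a seed fully reproduces a dataset.
`simulateProteinFamilies()` generates each family as a uniform-random
amino-acid seed sequence plus members with i.i.d. per-site substitutions
(uniform over the 19 alternative residues), member j assigned to genome
j. What the generator deliberately omits: phylogenetic correlation
between genomes, gene-frequency spectra estimated from real panels,
paralogs, indels, gene order and plasmids. Green tests on synthetic data
therefore demonstrate that the machinery is correct — partitions match
truth labels, clustering recovers families, fits recover generating
parameters — not that any particular real panel's counts will be
reproduced; real orthogroup counts also depend on the upstream search
tool and its defaults, which is why published family counts from real
assemblies are treated as documentation references rather than test
assertions.

## Annotation summaries

Functional-category distributions are shares of the *annotated* genes of
a subset, rounded to whole percent as such figures are reported; genes
missing from the annotation table are counted separately rather than
silently diluting the denominator. The adhesin cross-tab applies a
strict score > 0.7 cutoff (the conventional high-confidence adhesin
call) per localization class (CYT, ME, PSE, SE); the interaction-network
filter keeps edges with score ≥ 0.9765, a minimum-score semantic.
Threshold semantics (strict vs inclusive) follow how each cutoff is
customarily stated, and both are configurable. Most-connected nodes are
reported with lexicographic tie-breaks for determinism.

## Pipeline and reproducibility

`runPipeline()` executes cluster → partition → curves → fits → profiles,
skipping stages whose inputs arrive precomputed (a presence/absence TSV
or an orthogroup table short-circuits clustering, and the manifest
records the stage as imported). The manifest also records the package
version, the seed, an MD5 of the analysis configuration (excluding the
output destination) and of every input file; outputs contain no
timestamps, so identical configuration and inputs give byte-identical
bundles. The seed is mandatory for every stochastic stage.

## Problem sizes used in the test suite

The suite favours small, fully checkable problems: fixture graphs of ~10
nodes against an independently coded dense MCL reference, 3-genome
matrices against exhaustive enumeration of all 6 orderings, 5 × 4-member
protein families at 2% substitution for exact family recovery
(adjusted Rand index 1.0), 9-point curve fits across parameter grids,
and Monte-Carlo suites of 200–1000 replicates for distributional checks.
These sizes make the oracles exact while keeping the whole suite fast on
one CPU.

## Known limitations

The built-in scorer is quadratic in the number of proteins that share a
k-mer and is intended for panels of thousands, not millions, of
proteins. MCL granularity depends on inflation; no automatic selection
is attempted. Heap's-law fits assume multiplicative error (log-log OLS);
series with zero counts cannot be fitted on that scale. The offset
exponential's t is only searched within 0.05–500 x-units, an intentional
cap: outside it the exponential is indistinguishable from a constant or
a line on a 9-point series.
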