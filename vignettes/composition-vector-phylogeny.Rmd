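---
title: "Composition-vector phylogeny: model, choices, and limits"
author: "dlphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-vector phylogeny: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlphylo)
```

## The model

dlphylo reconstructs phylogenies from whole genomes or proteomes without
alignment. The unit of information is the K-mer spectrum of a genome. For a
genome with sequences $j = 1, \dots, m$ of lengths $L_j$, the observed
frequency of a K-mer $\alpha_1\cdots\alpha_K$ pools counts and windows over
all sequences:

$$p(\alpha_1\cdots\alpha_K) \;=\;
  \frac{\sum_j n_j(\alpha_1\cdots\alpha_K)}{\sum_j (L_j - K + 1)}.$$

Raw K-mer frequencies are dominated by lower-order composition (G+C
content, amino-acid usage, codon bias), which reflects mutational pressure
more than phylogeny. The dynamical-language background model removes this
signal: a K-mer $s_1\cdots s_K$ can be formed by appending $s_K$ to the
observed $(K{-}1)$-mer $s_1\cdots s_{K-1}$, or by prepending $s_1$ to
$s_2\cdots s_K$, and the expected frequency averages the two constructions,

$$q(s_1\cdots s_K) \;=\;
  \tfrac12\left[\,p(s_1\cdots s_{K-1})\,p(s_K) + p(s_1)\,p(s_2\cdots s_K)\,\right],$$

with every frequency estimated at its own window denominator ($L-K+2$ for
the $(K{-}1)$-mers, $L$ for single letters, summed over sequences). The two
constructions are weighted equally: the model names exactly these two
one-letter extensions and gives no reason to prefer either, and equal
weights are the only symmetric choice (the vignette flags this as a design
decision; nothing downstream depends on small reweightings). The
composition vector is the relative difference

$$X_i = \frac{p_i}{q_i} - 1,$$

indexed by all $N = |\Sigma|^K$ K-mers in alphabetical order. Components
with $q_i = 0$ are defined as $X_i = 0$: the background assigns them no
mass, so they carry no signal. Components with $q_i > 0$ but $p_i = 0$ get
$X_i = -1$, and the identity $\sum_i q_i X_i = \sum_i p_i - \sum_i q_i = 0$
holds to rounding error — the package's tests verify it at $10^{-10}$
together with $\sum p = \sum q = 1$.

Two genomes are compared by treating their $N$ components as paired
samples:

* **correlation distance** $D = (1 - C)/2 \in [0, 1]$, with $C$ the
  centered Pearson sample correlation over all $N$ components. This is the
  classic flavour. It is a *pseudo*-distance: the triangle inequality can
  fail.
* **chord distance** $\sqrt{2 - 2\cos\theta} \in [0, 2]$, the Euclidean
  distance between the unit-normalised vectors — a proper metric, used by
  the modified variant of the method.

"Sample correlation ... in the usual way" admits a centered and an
uncentered reading; the package implements centered Pearson as primary and
keeps the uncentered cosine behind `type = "cosine"`, since the choice
cannot be settled from the method's description alone.

Trees are built with a from-scratch Saitou–Nei neighbor-joining
implementation (`nj_tree()`), so the pipeline has no external tool
dependency and its tie-breaking is fully specified.

## Sparse full-space algebra

For protein K = 5 the component space already has $20^5 = 3.2\times10^6$
entries; at the supported maxima (DNA K = 13, protein K = 8) dense vectors
are out of the question. All storage is sparse, keyed by K-mer string, but
every statistic is computed over the **full** $N$-component space: means
are (sum of stored entries)/$N$, and cross products over the union of
stored supports carry the analytic $-N\bar{x}\bar{y}$ correction for the
implicit zeros. This is exact, not an approximation — the test suite checks
agreement with a dense oracle at DNA K = 3 to $10^{-12}$. The multi-genome
distance matrix routes through a union-of-supports table and one Gram
product, which is the same arithmetic batched.

## Parameters that matter

* `k` — the word length, the method's resolution knob. Longer words carry
  more phylogenetic signal until the spectrum becomes too sparse for the
  genome length at hand ($N$ grows geometrically while windows grow
  linearly). Guards: `k <= 13` for DNA and `k <= 8` for protein in
  `run_config()`, the ranges within which the method is normally explored;
  `k >= 2` everywhere, because the background needs $(K{-}1)$-mers — at
  K = 1, $q \equiv p$, $X \equiv 0$, and every correlation is undefined.
* `method` — `"correlation"` (classic) or `"chord"` (metric). On
  well-separated data the two give the same topology; the acceptance script
  reports their Robinson–Foulds disagreement on simulated data.
* `B` — bootstrap replicates, default 100. Supports are percentages of
  replicate trees containing each reference-tree bipartition.
* ambiguity handling — windows containing any non-canonical character
  (IUPAC ambiguity codes, gaps, stops) are dropped from counts *and*
  denominators, preserving $\sum p = 1$ exactly. Sequences shorter than K
  contribute zero windows rather than erroring, so short genes degrade
  gracefully.

## The modified bootstrap

Alignment-column bootstrapping does not exist for alignment-free methods,
and gene resampling is meaningless for genomes with a handful of genes. The
modified bootstrap resamples the columns of the genome × K-mer table: $N$
columns are drawn with replacement from the full component space and
recorded as integer multiplicities, and distances are recomputed with each
column weighted by its multiplicity.

Two implementation points deserve note:

1. **What is resampled.** The table holds the transformed vectors $X$, not
   raw frequencies: the background $q$ cannot be coherently recomputed from
   resampled K-mer columns (the $(K{-}1)$-mer counts are untouched by the
   resampling), while resampled $X$ columns remain a valid vector in the
   same space.
2. **The all-zero complement.** Columns stored in no genome are still part
   of the $N$-column sample space. The draw is performed exactly in two
   parts: the number of draws landing in the complement is
   $\mathrm{Binomial}(N, 1 - u/N)$ with $u$ the union support size, and the
   remaining draws are multinomial over the $u$ observed columns. Zero
   columns contribute only to the weight total in the means and variances.

A historical variant keeps each drawn column at most once ("fewer columns,
same frequencies"); it is available as `variant = "distinct"` but the
same-width scheme is primary. Supports annotate the reference tree's edges
by default; `majority_rule_consensus()` provides the consensus-tree view,
with the consensus topology delegated to `ape::consensus()` and the
percentage labels computed from the package's own bipartition counts.
Replicates with undefined distances (a genome whose resampled vector has
zero variance) are discarded with a warning; more than 10% discarded is a
hard failure.

## Numerical choices

* NJ ties in the Q-criterion are broken by the lowest index pair, making
  tree construction deterministic; merged clusters are appended after the
  original taxa so the order is well defined.
* Negative NJ branch estimates are clamped to zero with the deficit
  transferred to the sister branch, preserving the joined pair's
  distance — the common convention; the final trifurcation clamps at zero.
* Zero-variance detection in the correlation uses an absolute-or-relative
  test ($v \le 0$ or $v < 10^{-12}\sum x^2$) so that constant-by-value
  vectors are caught despite rounding.
* Correlations are clipped to $[-1, 1]$ and $2 - 2\cos\theta$ floored at 0
  before the square root, so distances never leave their ranges by
  floating-point hairs.
* PHYLIP matrices print 6 decimals (the dialect standard); internal
  computation is full double precision. Newick branch lengths print with 15
  significant digits so roundtrips hold to $10^{-9}$.

## What the simulator emulates — and what it does not

`simulate_genomes()` draws a uniform random unrooted binary topology
(sequential uniform attachment of each new leaf to a random edge) with
i.i.d. exponential branch lengths, then evolves i.i.d.-uniform root genes
site-independently under the symmetric $s$-state (Jukes–Cantor-type) model:
along a branch of length $t$ expected substitutions/site, each site
substitutes with probability
$p_{sub} = \frac{s-1}{s}\bigl(1 - e^{-\frac{s}{s-1}t}\bigr)$, the new state
uniform over the other $s-1$. This is deliberately minimal: the method
under test uses no substitution model, so simulator realism beyond
controllable divergence would add nothing to the tests. Real genomes have
compositional heterogeneity, rate variation, indels, gene gain/loss and
horizontal transfer, none of which are modelled — passing simulation tests
shows the machinery is correct and the method resolves clean divergence,
not that it will resolve any particular real data set.

Problem sizes in the tests and acceptance script — 8-taxon proteomes of 10
genes × 2000 aa at K = 4, 100 random trees of 4–20 leaves, 1000 distance
triples — are chosen as the smallest sizes at which each property is
convincingly exercised.

## Known limitations

* **The distances are not additive.** $D = (1-C)/2$ and the chord distance
  grow concavely with true divergence and contain no multiple-hit
  correction, so they are not patristic distances on any tree. NJ is
  therefore not consistent for them: internal edges much shorter than the
  surrounding branches can be resolved wrongly *systematically*, not just
  noisily — adding sequence data does not help. The acceptance script
  measures exactly this: under exponential branch lengths (mean 0.05
  substitutions/site), where most 8-taxon trees contain an internal edge
  below ~0.01, end-to-end topology recovery sits far below the near-certain
  recovery seen on well-separated clades, and alternative distance-based
  builders (ape's NJ, FastME) reconstruct the same wrong topologies from
  the same matrices. The method is at its best where its published record
  lies: taxa groups separated by substantial divergence.
* Correlation distance can violate the triangle inequality (the chord
  flavour exists for exactly this reason and its metric property is tested
  on random triples).
* Only the given strand is counted for DNA; no reverse-complement
  canonicalisation.
* The bootstrap resamples vector columns, so its supports measure
  robustness of the tree to the K-mer composition sampling — not to gene
  content or alignment uncertainty.
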