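---
title: "Methods: characterizing extrachromosomal replicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing extrachromosomal replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrtools)
```

This vignette documents the models behind each analysis stage, the
tunable parameters and their defaults, the design decisions taken where
the methodology was genuinely open, and what the synthetic-data
generators do and do not emulate.

## Codon usage and chromid/plasmid classification

For codon $c$ in a synonymous family of size $n_{aa}$ with observed
counts $x_c$,

$$\mathrm{RSCU}_c = \frac{x_c \, n_{aa}}{\sum_{c' \in \text{family}} x_{c'}},$$

so the family mean is exactly 1 whenever the family is observed at all.
We use the bacterial genetic code (translation table 11, identical to
the standard code on all sense codons), and exclude ATG and TGG —
single-codon families carry no usage signal — and the stop codons,
leaving 59 informative codons. Families with zero observations have
undefined RSCU and are recorded as missing, not zero; when profiles are
assembled into a matrix for clustering, missing values are imputed at
the no-bias value 1. Codons containing ambiguous IUPAC bases are skipped
during counting rather than guessed.

Per-replicon profiles pool codon counts over all CDSs before a single
normalization (not per-gene averages); pooling weights genes by length,
which matches how a replicon-level "genomic imprint" is usually read,
and makes the profile invariant to duplicating every gene. Whether
per-gene or pooled profiles should be clustered is a genuinely open
choice; we chose pooling and expose `rscu_of_counts()` so per-gene
profiles remain available.

Clustering uses Euclidean distance on the 59-dimensional replicon
vectors with average linkage (UPGMA); both are configurable because
neither choice is canonical in the literature. Visual dendrogram reading
is replaced by a reproducible rule: a replicon is a *chromid* when its
cophenetic distance to the chromosome is at most $\tau$ times the
maximum cophenetic distance in the tree, else a *plasmid*. The default
$\tau = 0.5$ splits the bimodal structure the generator (and real
multipartite genomes) produce: chromids sit at sampling-noise distance
from the chromosome while xenologous plasmids sit at an order of
magnitude farther. Ties in agglomeration are made deterministic by
sorting profiles lexicographically by replicon id before clustering.

## Coverage, copy number, prevalence

Bulk DNA sequencing of an unsynchronized population measures copies per
cell averaged over the population, hence the model $r = c \cdot p$: the
depth ratio of a replicon to the chromosome is the product of its
integer per-cell copy number $c$ and its prevalence $p$ (carrier
fraction). The two factors are not identifiable from $r$ alone; the
decomposition therefore uses two pieces of prior knowledge:

* a ratio within `tol` (default 0.1) of a positive integer is read as
  that copy number at full prevalence (`integer_copy`);
* replicons listed as single-copy — RepABC-type replicons are held at
  one copy per cell by their partitioning machinery — with $r < 1$ are
  read as $c = 1,\ p = r$ (`single_copy_partial`). The single-copy list
  is a user input, never inferred from sequence.

Everything else is flagged `ambiguous` with $c = \max(1,
\mathrm{round}(r))$ and $p = r/c$. The ratio itself is the ratio of
*median* window depths — robust against repeat-region pileups, which
inflate a mean — with a percentile bootstrap (default 2,000 resamples,
windows resampled independently within replicon and chromosome) for the
95% interval. No GC-bias correction is applied; depth tables are taken
as supplied, including however the upstream mapper distributed
ambiguous reads.

Agreement between a sequencing-derived prevalence and a colony screen is
tested with a two-sided exact binomial test by minimum-likelihood
summation (the p-value sums the probabilities of all outcomes no more
likely than the observed one). The definition is stated because
two-sided exact tests differ between packages; ours is validated against
both direct enumeration and `stats::binom.test`.

## Assay statistics and prevalence dynamics

Colony counts get exact Clopper–Pearson intervals via Beta quantiles;
zero-event assays additionally report the rule-of-three bound $3/n$.
Retention $R$ after $G$ generations converts to a per-generation
segregational loss rate $\lambda = 1 - R^{1/G}$, with the interval
obtained by transforming the retention interval endpoints (the transform
is monotone). $G$ is a **required** user input: cultivation time alone
does not determine generations, and refusing to guess is the honest
contract. In examples we use $G = 50$ for a week of continuous rich-medium
culture (~7 doublings/day), stated as an assumption wherever it appears.

The prevalence-dynamics model is the deterministic recursion

$$p_{t+1} = \frac{p_t(1-\lambda)}{p_t(1-\lambda) + \big(1 -
p_t(1-\lambda)\big)(1+s)},$$

with $s$ the selective advantage of plasmid-free cells. With $s = 0$ the
denominator is identically 1 and the recursion collapses to
$p_t = p_0(1-\lambda)^t$, which the tests verify exactly. The model is
deliberately deterministic — drift enters only through the binomial
bottlenecks of the passaging simulator — because at typical culture
sizes demographic noise is negligible between transfers.

In-silico PCR matches the forward primer on the plus strand and the
reverse primer's reverse complement downstream; mismatches are counted
uniformly along the primer (no 3′-end weighting — a deliberate
simplification; a 3′ rule would only tighten specificity). Circular
templates are scanned across the origin by linear extension, and
origin-spanning products are reported with modular length.

## RepABC typing

Compatibility grouping follows the partitioning proteins only: RepA and
RepB p-distance matrices are averaged, clustered with average linkage,
and cut at a user-chosen height; the replicase is scored separately.
Congruence is quantified with the Robinson–Foulds distance between
neighbor-joining trees: RF(RepA, RepB) should be 0 (synchronous
evolution of the *repAB* operon), while RF(RepAB, RepC) > 0 signals
replicase exchange. We use distances + NJ rather than likelihood
phylogenetics with bootstrap: clade co-membership of RepA/RepB survives
that simplification, the result is fully deterministic, and every step
is checkable against small exact oracles (NJ recovers additive matrices
exactly; RF is validated against independent bipartition counting).
Negative NJ branch lengths are clamped to zero with a warning.

Unaligned input is globally aligned pairwise with match +1, mismatch
−1, gap open 5, gap extension 1 (no substitution matrix by default);
the p-distance is mismatching columns over columns where both sequences
have a residue. Note that an uncorrected p-distance saturates: beyond
roughly 0.5 substitutions per site it compresses differences and NJ
topology estimates degrade. The rep-family generator keeps its default
divergences below that range for exactly this reason.

Palindromes (inverted repeats) are found by growing arms outward from
every loop placement (loop length 0..`max_loop`) while the cumulative
mismatch count stays within budget, reporting the maximal arm per
placement when it reaches `min_arm`. Defaults `min_arm = 5`,
`max_loop = 10`, `max_mismatch = 1` reflect the short diagnostic
palindromes adjacent to *repB*; there is no canonical definition of a
"maximal" degenerate inverted repeat, so ours is stated operationally
and verified against an exhaustive scan. The search window relative to
*repB* is a user decision — the package searches whatever sequence it is
given. Consensus building center-aligns sites and reports per-column
majorities, with ties as IUPAC ambiguity codes.

## Regulon overlap

Significant sets default to raw $p \le 0.05$ with no fold-change
threshold, mirroring the plain threshold rule common in comparative
transcriptomics figures; a Benjamini–Hochberg mode is provided and
recommended when the sets feed further inference. Correlation between
strains is computed on **all** shared genes, not only significant ones —
regulatory similarity shows up genome-wide, below any significance
threshold. Enrichment is the upper-tail hypergeometric probability
$P(X \ge k)$ per category with BH adjustment across categories; RPKM is
$\text{reads} \times 10^9 / (\text{length}_{bp} \times
\text{library size})$ with per-replicon medians and a
replicon:chromosome median ratio.

## What the generators emulate — and what they do not

Each generator reproduces the statistical structure one analysis stage
assumes, under a fixed seed:

* **Genomes** (`simulate_replicon_set()`): per-replicon synonymous-codon
  distributions drawn from a symmetric Dirichlet($\alpha$) per family
  ($\alpha = 0.3$ by default — strong, realistic bias; $\alpha \to
  \infty$ approaches uniform usage), with chromids inheriting the
  chromosome's distribution and plasmids drawing independently. The
  default genome is a scaled-down six-ECR organism (120-gene chromosome,
  20–35-gene ECRs of 200 codons each) whose 102-kb-like plasmid has
  $c = 1, p = 0.5$.
* **Depth** (`simulate_depth()`): window depth $\sim$ Poisson with mean
  $\text{depth per copy} \times c \times p$ (default 100 per copy, 500
  windows of 1 kb). Real depth is overdispersed by mappability and GC
  effects; a negative-binomial knob exists but defaults to off because
  the analysis makes no distributional assumption beyond a stable
  median.
* **Assays and passaging**: Binomial colony counts; the deterministic
  recursion plus binomial bottlenecks at transfers.
* **DE tables** (`simulate_de_tables()`): a shared regulon (default 900
  of 3,668 genes) with equicorrelated normal effects, the effect
  correlation solved in closed form so the expected whole-table Pearson
  correlation equals the target (default 0.76); effect SD 2, null SD
  0.5 (log₂ units), p-values Beta(0.05, 1) for effect genes and uniform
  for nulls. Infeasible targets are rejected with the attainable range.
* **Rep families** (`simulate_rep_families()`): site-independent uniform
  substitutions over 20 letters, Poisson per branch, on a two-clade
  guide topology (8 taxa, 400 sites, 0.08 within / 0.3 between
  substitutions per site); RepC evolves on the same topology after the
  configured taxon swaps; each group's DNA segment embeds its consensus
  palindrome with at most one mutation.

Passing tests on these inputs show the *inference machinery* is correct
under its stated model. They do not show robustness to what real data
add: mappability and GC structure in depth, amino-acid substitution
preferences and indels in proteins, alignment uncertainty, batch
structure in expression tables. The module boundaries accept real data
in standard formats precisely so those effects can be brought in.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale: 500 windows
per replicon and 20 replicates for prevalence recovery, 2,000 bootstrap
resamples, 2,000 simulated assays for interval coverage, random trees up
to 12 leaves for NJ recovery, 2-kb sequences for the palindrome oracle.
All coordinates are 0-based half-open internally, converted at the GFF3
boundary (1-based inclusive); depth windows default to 1 kb with a
trailing partial window kept when it spans at least half a window. All
randomized functions take a `seed` argument and are bit-reproducible
under it.
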