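---
title: "Network enrichment analysis in crosslink: model, null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network enrichment analysis in crosslink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslink)
```

## The model

`crosslink` scores the association between an **altered gene set**
(AGS) — genes selected from a paired case/control expression contrast —
and a **functional gene set** (FGS) — a pathway or ontology category —
by their connectivity in an undirected gene network rather than by
membership overlap. The statistic is the cross-link count `n_AF`: the
number of network edges with one endpoint in A and the other in F. An
edge with both endpoints in the intersection counts once; the statistic
is symmetric in A and F.

Whether a given `n_AF` is large depends strongly on the degrees of the
genes involved: hub-rich sets accumulate links by chance. The null
model therefore preserves every gene's degree exactly: networks are
randomized by **double-edge swaps** (replace a random edge pair
(a,b),(c,d) with (a,d),(c,b) or (a,c),(b,d); reject proposals that
would create a self-loop or duplicate edge). The null mean and SD of
`n_AF` over `n_perm = 50` independently rewired networks give

    Z = (n_AF - mu_AF) / sigma_AF,

converted to a two-sided normal p-value, with the direction (enriched
or depleted) carried by the sign of Z. Benjamini-Hochberg FDR is
computed across the whole AGS x FGS result list. One shared pool of
rewired networks serves all pairs in a run: the randomization permutes
the network, not individual pairs, and this is also what makes
catalog-scale runs tractable.

### Small sets and the empirical FDR

The normal approximation degrades when either set has fewer than 5
network-resident genes; such results are flagged `small_set` (never
silently dropped). Significance can also be established without the
normal assumption: the **empirical FDR** at a threshold t is

    FDR(t) = mean over random sets of #{|Z_random| >= t} / #{|Z_real| >= t},

where the random sets match the AGS in size *and* degree composition —
network nodes are binned into quintiles of the degree distribution
(`degree_bins = 5`, configurable) and each random set reproduces the
AGS's per-bin counts, sampled without replacement within bins. Random
and real tests share the same rewired-network pool. A zero null SD with
`n_obs != mu` has no defined Z (`zero_sigma` flag); such pairs are only
assessable by this empirical machinery.

### Gene-level calls

`gene_level_nea()` treats a single gene as a one-element AGS against a
gene list: a call requires at least `min_gene_links = 3` observed links
*and* NEA p < 0.05. Single genes are always `small_set`-flagged.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_perm` | 50 | rewired networks per null; SD of the Z-null then behaves like a t with ~49 df |
| `swap_factor` | 10 | accepted swaps per permutation, x edge count (burn-in of the swap chain) |
| `top_n` | 100, 900 | AGS sizes by ascending q (ties: larger fold change, then symbol) |
| `fc_cut`, `q_cut` | 1.5, 0.05 | threshold-mode AGS selection (fold change unitless, signed) |
| `min_fgs_size` | 5 | below this many network-resident genes a set is flagged `small_set` |
| `min_gene_links` | 3 | gene-level call requirement |
| `n_random` | 50 | degree-matched random sets for the empirical FDR |
| `degree_bins` | 5 | degree-distribution bins used for matching |

Defaults mirror the two-contrast microarray study design this pipeline
implements (paired triplicates; top-100/900 AGS; 50 permutations;
FC/q cutoffs 1.5 / 0.05).

## Differential expression choices

Tests are paired two-sided t on `log2` intensities (pairing by
replicate, df = n_pairs - 1); fold changes are linear-scale ratios of
per-condition means under the signed convention (r if r >= 1, else
-1/r, so |FC| >= 1 always and swapping conditions flips the sign).
Testing on the log scale while reporting linear-scale FC matches
microarray practice and keeps the two quantities decoupled. q-values
are Benjamini-Hochberg; the empirical-Bayes FDR machinery used by some
array pipelines is deliberately replaced by this transparent, testable
procedure, recorded in every output header. Zero-variance differences
get p floored at 1e-12 and a flag rather than p = 0, keeping downstream
ranking finite. With triplicates the test has 2 degrees of freedom:
power is intrinsically modest, which is why AGS selection by rank
(top-N) is the primary mode and why roughly half of 2-fold planted
effects make a top-100 list in simulation (about 60% at 2.8-fold).

## Numerical and degenerate-input policy

* `rewire()` runs until `swap_factor * |E|` *accepted* swaps, with a
  proposal cap of 10x that to terminate on rigid graphs (a triangle
  admits no valid swap and is returned unchanged with a warning).
* Running the chain for a fixed number of accepted swaps samples the
  *jump chain* of the randomization: each reachable realization is
  visited proportionally to its number of admissible swaps. On
  networks of realistic size this is indistinguishable from the uniform
  null (move counts are essentially constant across realizations), but
  on tiny graphs it is measurably non-uniform, and the test-suite
  oracle therefore weights enumerated realizations by their exact move
  counts. Regular degree sequences are additionally parity-locked
  (their swap graphs are bipartite), so the enumeration fixture uses a
  path degree sequence, whose swap graph is aperiodic.
* Permutation sub-seeds derive from the master seed by a single
  `sample.int` draw, making permutations independent and runs
  bit-reproducible.
* AGS/FGS pairs with no network-resident members give `z = NA` and a
  `no_coverage` flag; empty GMT member lists are kept but flagged.
* Confidence scores on edge lists are used only as an optional read
  filter (default: none); networks are unweighted thereafter.
* Complexes are expanded to full cliques (the symmetric, conservative
  binarization); spoke models are out of scope.

## What the synthetic generator emulates — and what it does not

`simulate_expression()` reproduces the statistical skeleton of a paired
triplicate array study: log2 intensity = gene baseline (N(7, 1.5)) +
pair effect (N(0, noise_sd)) + condition effect (+/- `effect_log2` for
a `frac_de` minority) + noise (N(0, noise_sd)), exponentiated to a
positive linear scale. Pair effects make the paired design genuinely
advantageous. `simulate_network()` is a configuration model (Poisson or
truncated power-law degrees; leftover stubs after bounded re-matching
are dropped). `plant_enrichment()` adds known extra A-F cross-links;
`make_study()` wires the true DE genes to a designated FGS so the whole
pipeline has a recoverable ground truth.

Not emulated: probe-level artifacts, background correction and
summarization of raw arrays, batch effects beyond pair effects,
correlated expression between network neighbours, and the curated
structure of real pathway catalogs (synthetic FGS are random draws, so
they overlap less than real pathways do). Passing tests demonstrate
that the statistics are calibrated and recover planted structure under
this idealized design — not that any particular biological claim holds
on real arrays.

## Study conditions used by the test suite and acceptance script

Sizes were chosen once, by power analysis, to run on one CPU in
minutes:

* **Null calibration**: 2000-node configuration model (mean degree 8),
  10 AGS x 20 FGS = 200 random pairs, `n_perm = 50`. Z should be
  centred (|mean| < 0.15) with SD in [0.8, 1.25] — the width reflects
  estimating sigma from 50 permutations (t-like with 49 df).
* **Planted recovery**: 1000 nodes, mean degree 12, AGS of 50, catalog
  of 10 FGS sized 40-60. Expected baseline cross-links
  |A| x E|F| x d / n = 30, so tripling them (adding 2x the baseline)
  yields Z of roughly 8-10; `n_random = 300` keeps the empirical-FDR
  estimator's Monte-Carlo SE near 0.015.
* **End-to-end**: `study_config()` defaults — 2000 genes, 5% DE at
  1.5 log2 units, noise 0.25, mean degree 8, 12 FGS, 200 planted
  links. The designated FGS should rank first by |Z| in >= 90% of
  seeded runs.
* **Enumeration oracle**: the 5-node path degree sequence (7 simple
  realizations) with move-count-weighted exact moments, against
  2000-permutation estimates.

## Known limitations

* The empirical FDR is mildly conservative when random degree-matched
  sets include genes of the AGS itself (their genuine links inflate
  random Z, especially toward a planted/true pathway); excluding AGS
  genes would bias the other way, and matched sampling is the
  documented, literature-consistent choice.
* With `n_perm = 50`, Z tails are heavier than normal (t-49): p-values
  below ~1e-3 should be read as strong evidence, not exact
  probabilities. Raise `n_perm` for sharper tails.
* Degree matching by quantile bins is coarse for extreme hubs; bin
  count is configurable.
* The pipeline treats gene identifiers as opaque case-sensitive
  symbols; identifier mapping is upstream of this package.
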