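---
title: "Measuring cladistic information in alignments and trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cladistic information in alignments and trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcite)
```

## The problem

A phylogenetic tree can only be as resolved as its input data allow. When a
multiple sequence alignment does not carry enough character variation to
separate its taxa, tree-building programs still emit trees — but with
*soft polytomies*: multifurcating nodes that reflect missing signal rather
than simultaneous speciation. This package quantifies, before any tree is
built, how much clade-splitting ("cladistic") information an alignment
carries, so that candidate genes or gene combinations can be ranked and
datasets that lack the *necessary cladistic information* can be flagged.

## The dCITE score

For an alignment of $n$ taxa, every site (column) $i$ partitions the taxa by
the character state they carry. The raw score sums per-site Shannon
entropies:

$$\mathrm{CITE} = -\sum_i \sum_{j=1}^{m_i} p_j \log_2 p_j$$

where the inner sum runs over the $m_i$ states at site $i$ that are present
in at least `min_state_count` taxa, and $p_j$ is the proportion of the
$j$-th state at the site. The default threshold is 2 — the parsimony
argument: a state seen once cannot witness a split between two clades.
Setting `min_state_count = 1` includes singletons, which is how the small
worked examples are scored. A balanced site ($n/2$ vs $n/2$) scores more
than a skewed one ($2$ vs $n-2$), reflecting the larger number of taxa its
split separates.

Two deflations then produce dCITE:

1. **Duplicate taxa.** Sequences character-identical to an earlier sequence
   are removed (first occurrence kept, removals reported). Identical taxa
   are indistinguishable on this evidence, and leaving them in would skew
   every site's proportions.
2. **Duplicate splits.** A site whose induced taxon partition equals that of
   an earlier retained site contributes 0: it confirms a known split but
   adds no new grouping information. Sites are scanned left to right, so the
   first site carrying each pattern is the retained one. Partition equality
   is canonical — invariant to which characters label the blocks — so a
   `b,a,a` column deflates against an earlier `c,a,a` column.

On the standard 4-taxon illustration:

```{r worked}
a <- alignment(c(Tax1 = "abaca", Tax2 = "abaca",
                 Tax3 = "aaaac", Tax4 = "aacad"),
               alphabet_kind = "categorical")
cfg <- metric_config(min_state_count = 1)
cite(a, cfg)$per_site      # 0, 1, 0.8113, 1, 1.5 -> 4.3113 bits
dcite(a, cfg)              # 3.4216 bits from 3 taxa
```

## Companion alignment metrics

* $\Delta_{min}$ (`delta_min`): per site, the number of states present in at
  least two taxa, minus one (floored at 0), summed. The $\ge 2$ threshold is
  intrinsic to its definition and independent of `min_state_count`.
* Total CIC (`total_cic`, `i_chi`): per-character information based on the
  number of trees on which the character fits without homoplasy,
  $I(\chi) = \sum_{j=3}^{n-r+1} (1-b_j)\log(2j-3)$ with $b_j$ the number of
  states having at least $j$ instances. We implement the printed summation
  limit as-is even though individual terms can be negative when $b_j \ge 2$
  (a warning is raised if a site's total goes negative); `i_chi` also offers
  a `homoplasy_oracle` mode that evaluates the underlying verbal definition
  exactly, by enumerating all rooted binary topologies (up to 8 taxa) and
  Fitch-scoring the character on each. The two modes are distinct
  estimators: the oracle is exact but exponential, the formula is the
  published closed-form comparator.
* Character diversity (`character_diversity`): at each variable site, the
  number of states divided by min(non-gap taxa, alphabet size) — a
  site-specific proxy for mutational saturation. `metric_config(diversity_cap
  = 0.75)` makes `dcite` exclude sites above the cap entirely (contribution
  0, flagged `cap_excluded`). Exclusion, rather than down-weighting, is the
  simplest mechanism that realises "limiting diversity at a site"; capped
  sites also do not serve as deflation references, since an ignored site
  should not silently absorb a later site's contribution.

## Gaps, denominators and other numerical choices

* **Gap policy.** Default `ignore_gaps`: gaps are uncounted, and a site's
  split pattern partitions only its gap-free taxa, so two sites with
  different gap footprints never deflate one another — the most conservative
  notion of one site repeating another's splits. `gap_as_state` instead treats the gap as a
  fifth nucleotide / twenty-first amino acid.
* **Denominator.** With the parsimony threshold active, "the proportion of
  the $j$-th state at site $i$" is ambiguous: we divide retained counts by
  all counted residues at the site (`all_counted`, the literal reading) and
  offer `retained_only` as an option. With `min_state_count = 1` the two
  coincide.
* **Duplicate detection** compares full aligned rows exactly, gaps included,
  case-insensitively (sequences are uppercased on input).
* **Logs** are base 2 throughout (scores in bits), configurable for parity
  with other conventions.
* **Tree counts.** The number of rooted binary trees on $k$ leaves,
  $(2k-3)!!$, exceeds $2^{53}$ beyond $k = 16$, so
  `count_rooted_binary_trees` refuses larger $k$ while `tree_cic` evaluates
  $\log(2k-3)!!$ via `lgamma` — exact in log space at any size.
* Site indices are 1-based everywhere, matching how sites are numbered in
  the worked example.

## Tree-side diagnostics

For a rooted tree (`read_newick`; trees are used exactly as parsed, with
unary nodes collapsed and no rerooting):

* `degeneracy`: $\sum_v (\mathrm{degree}(v) - 2)$ over internal nodes — 0
  for a fully binary tree, $n-2$ for a star. Consensus programs that emit a
  top-level trifurcation therefore have a floor of 1.
* `tree_cic`: $-\log_2(\text{permitted}/\text{possible})$, where permitted
  is the number of rooted binary topologies refining the tree (the product
  over internal nodes of $(2d-3)!!$ for degree $d$) and possible is
  $(2n-3)!!$. A star scores 0; a binary tree scores the maximum,
  $\log_2 (2n-3)!!$. Rooted-tree counting semantics are used throughout;
  the choice of rooted counts and of base 2 affects absolute values but not
  any ordering of trees.
* `min_support`: the smallest numeric internal-node label (e.g. the weakest
  bootstrap count of any clade in a consensus tree).

## Saturation analysis

`incremental_curve` emulates the taxon-addition design for locating
information saturation: starting from 4 randomly chosen taxa, one randomly
chosen taxon is added at a time and all metrics are recomputed on each
sub-alignment (columns that become all-gap are dropped first — they cannot
contribute under `ignore_gaps`, but would distort site counts). A single
user-supplied seed drives all sampling, so curves are reproducible
bit-for-bit. `plateau_point` then finds the first count $\bar N$ whose
forward window is flat:

$$\sum_{j=\bar N}^{\bar N + w} |\mathrm{dCITE}_{j+1} - \mathrm{dCITE}_j| \le \mathrm{tol}$$

with defaults $w = 15$ and $\mathrm{tol} = 15$ bits (16 adjacent-difference
terms, the summation bounds implemented exactly as printed). Both are
exposed because reasonable analyses vary them with the pool size.

## What the fixture generator does (and does not) emulate

`generate_alignment` builds alignments with exact, verifiable structure:
chosen numbers of invariant sites, duplicate taxa (exact appended copies),
duplicate-split sites (state-label permutations of an earlier column — same
partition, different characters, so they exercise the canonical comparison
rather than naive column equality), and saturated sites (near-uniform
full-alphabet columns), with remaining sites drawn at 2–4 states in random
proportions and resampled until all variable non-duplicate sites carry
pairwise distinct patterns. `generate_tree` draws a random rooted binary
tree and collapses internal edges independently at a given rate, spanning
binary (rate 0) through star (rate 1) shapes.

The generator deliberately does **not** simulate evolution on a tree: no
substitution model, no rate heterogeneity, no indel process, no
phylogenetic correlation between sites. Passing tests therefore demonstrate
that the metrics measure the structures they are defined on — not that any
particular score threshold is attainable on real sequence data, where site
patterns are correlated and duplication arises from shared ancestry rather
than construction.

## Problem sizes used in the test suite

Exhaustive oracles keep the suite honest at small scale: all rooted binary
topologies are enumerated up to 7 leaves (10,395 trees) to validate the
refinement-count product behind `tree_cic`, and all 2-state characters on
up to 6 taxa are checked against convexity-based homoplasy counting.
Property checks run on generated alignments of ~10 taxa by ~20–30 sites and
on 1,000 random trees of up to 40 leaves — sizes at which every invariant
can be verified against brute force while the whole suite stays fast.

## Known limitations

* The deflation scan is first-retained left-to-right; the retained total is
  order-invariant (duplicate-pattern sites have identical entropy), but
  *which* site is labelled `retained` versus `deflated` follows input
  order.
* dCITE is bounded by the CITE of the *deduplicated* alignment; removing
  duplicate taxa can raise individual raw per-site entropies, so no
  ordering against the raw-alignment CITE is guaranteed in general.
* The printed $I(\chi)$ formula can yield negative per-site values in
  principle; we reproduce it faithfully and warn, rather than silently
  clamping.
* Confirmed splits are not up-weighted: a deflated site contributes exactly
  0, although it does corroborate the split it duplicates.
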