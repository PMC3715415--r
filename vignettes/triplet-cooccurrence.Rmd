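---
title: "Shared complex subunits and disrupted co-occurrence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared complex subunits and disrupted co-occurrence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccur3)
```

## The problem

Genes whose phylogenetic profiles — their pattern of presence and absence
across a panel of genomes — closely match tend to encode functionally
linked proteins. The converse fails badly: most pairs of interacting or
co-complexed proteins do *not* co-occur cleanly. `cooccur3` implements one
quantitative explanation: a multi-functional protein A shared between two
complexes survives the loss of either partner module, so the profiles of
its partners B and C complement each other with respect to A instead of
matching it. The package classifies pairwise profile relationships, scores
triplets for this complementarity signature, relates the score to triangle
motifs of the interaction network, and tests whether shared subunits are
preferentially retained in duplicate.

## Data model

Profiles are per-species **copy numbers** (in-paralog counts) for
orthologous groups (OGs); presence is `count > 0`. One matrix therefore
serves both the co-occurrence analyses (presence only) and the duplication
analysis (counts). The species tree is a rooted `ape::phylo`; every node
owns the branch above it and the root owns a virtual stem, giving `2N - 1`
indexable branches for `N` species — the stem is where the gain of a
family present on both sides of the root is placed. Interaction data enter
either as complex definitions (expanded to all within-complex pairs, after
removing complexes completely covered by others in a single pass) or as
pair lists; protein-level networks are projected to OG level, retaining
per-edge provenance (which protein pairs realized each OG edge) so that
open triangles realized by two in-paralogs of the central OG can be
recognized.

## Pairwise classification

For each OG the gain and losses are reconstructed by **Dollo parsimony**:
a single gain on the branch above the LCA of the present species, and one
loss on every maximal absent subtree below it. This loss count is provably
minimal given a single origin, and the suite verifies that exhaustively on
every rooted topology with up to six leaves. The method behind the
similarity measure is deliberately event-based rather than profile-based:
shared absences and clade-autocorrelation otherwise dominate.

Similarity of a pair is the **partial correlation** of the two per-branch
event vectors given the global trend (the per-branch sum of events over
all OGs), `r_AB.G = (r_AB - r_AG r_BG) / sqrt((1 - r_AG^2)(1 - r_BG^2))`.
The trend correction removes genome-wide episodes (streamlining, bursts of
invention) and, in practice, the large shared signal of root-origin gains.
If an event vector is collinear with the trend the plain correlation is
returned with a degeneracy flag.

Eligible pairs (at least one member present in `ceiling(N / 2)` species;
26 of 51) are classified with strict precedence:

1. **matching** — partial correlation strictly above the background
   cutoff;
2. **taxonomic** — one profile's present-species LCA is a strict
   descendant of the other's (a later invention, not a dependency), tested
   *before* the generic subset, as a taxonomic nesting also produces high
   subset scores;
3. **subset** — subset score (species with the wider gene but not the
   narrower, minus the converse; ties on width broken lexicographically)
   strictly above its cutoff;
4. **other**.

Cutoffs are nearest-rank percentiles (default 90, also run at 85/95) of
the background distribution over *all* pairs of proteins that have at
least one interaction — the vast majority of which do not interact.
"Strictly above" means a value equal to the cutoff does not pass.

## Triplet scoring

For a centered triplet (A; B, C) over the panel:

- `n_good_b = #{species: A & B & !C}`, `n_good_c = #{A & !B & C}` — the
  complementary coverage of A by exactly one partner;
- `n_bad` counts species (once each) where A is present with neither
  partner, or absent while a partner is present;
- `score = min(n_good_b, n_good_c) - n_bad`.

The min rewards balanced complementation; the score is symmetric in B and
C, bounded by `floor(present(A) / 2)`, and `<= 0` whenever B = C. A
central-protein filter (A in at least half the species) keeps the analysis
on global trends; it is applied at pipeline level so the scorer stays a
pure function. Triplets with two identical OGs are excluded.

Triangle types on the OG network: **closed** (all three edges), **open**
(A–B and A–C but no B–C — the shared-subunit signature), **open2A** (open,
with the two edges realized exclusively by disjoint sets of A's member
proteins: a duplicated A whose in-paralogs took the two roles), **none**
(no internal edges; sampled at random as the background universe, with the
most widespread member designated the center — the most favorable choice
under the central filter). Closed triangles enter once per choice of
center, since the score depends on which OG is central. Open triangles in
which B or C is a *taxonomic subset* of A are tracked as their own display
class in the binning, because a late invention mimics complementarity
without a shared-subunit cause.

The scored universe (all triangles plus `n_none` sampled non-interacting
triplets, default 1e5 at desk scale versus roughly 1e7 in the full-data
setting) is sorted by score with a stable canonical-id tie-break and cut
into `n_bins = 20` equal-count bins (bin sizes differ by at most one; the
bin count is a package choice, not stated in the source analysis). The
trend statistic is the Spearman correlation between bin index and the
per-bin fraction of a triangle type, with a two-sided p; a constant
fraction is reported as undefined rather than coerced to a number.

## Feeding triplets back into the pairwise picture

Pairs appearing on the A–B or A–C side of at least one open triangle with
`score > 0` ("positive") are cross-tabulated against their pairwise
category; per-category over-representation is the observed in-triplet
fraction against the category-blind expectation, as percent excess, with
an uncorrected chi-square on the 2x2 table (a Yates option exists). The
2-D enrichment grid bins all background pairs by partial correlation and
by their triplet score — the **maximum** complementarity score over
triplets containing the pair, an aggregation the source analysis leaves
unstated; pairs in no triplet occupy a sentinel lowest bin — and reports
`log2(cell interacting fraction / overall fraction)`, with empty cells
`NA`, never 0.

## Duplication retention

An OG is *eligible* when at least 5 species carry exactly one copy (a
guard against out-paralog contamination) and *duplicated* when at least 5
species carry two or more. Rates are contrasted between role A and roles
B/C of open triangles; closed and unconnected triplets have no central
gene and pool all three members, the unconnected pool serving as the
background rate. Counting is per role-occurrence by default (an OG in many
triangles counts each time, so N matches the number of triangles); a
per-unique-OG mode is provided and labelled, since the source text does
not fully determine which was used.

## The synthetic world

`sim_config()` states one world and the defaults are not revisited:

| parameter | default | why |
|---|---|---|
| `n_species` | 51 | the published panel size |
| `n_ogs` | 2000 | desk-scale stand-in for ~58k clusters |
| `p_origin_root` | 0.7 | most families ancestral, a tail of later inventions |
| `p_loss` | 0.05/branch | mean presence ~2/3 of species on a Yule tree |
| `p_dup` | 0.0125/branch | puts the background duplication call rate near the 5-species threshold |
| `dup_mult_A` | 2 | the retention hypothesis under test |
| `n_arch` | 50 | planted shared-subunit architectures (two complexes each) |
| `p_complementary` | 0.5 | fraction of architectures whose B/C losses are confined to disjoint lineage sets |
| `comp_strength` | U(0.3, 0.95) | per-architecture lineage-loss probability; heterogeneity spreads open-triangle scores |
| `lineage_frac` | U(0.15, 0.35) | fraction of species in each side's loss lineages |
| `noise` | 0.01 | per-species presence flips (annotation error analogue) |

Losses and duplications are independent per-branch Bernoulli events (no
rate heterogeneity beyond the A-role multiplier; a hook exists via
`dup_mult`). All-absent OGs are regenerated and counted. Architectures
plant a broadly present shared subunit A in two complexes whose partner
modules copy A's presence minus clade-level losses; with probability
`p_complementary` the two lineage sets are disjoint (the true
shared-subunit signature), otherwise drawn independently so overlap
produces open triangles *without* the signature — without these, open
triangles crowd the top bins only and the rank trend is tie-degenerate,
which is not what interaction data look like. Truth labels (origins,
roles, architecture class per triplet) are returned in a separate element
so analysis code cannot consume them accidentally.

What the generator does **not** emulate: correlated loss rates across
lineages, horizontal transfer, out-paralogs, orthology-clustering
artifacts, and the size/shape heterogeneity of real complexes. A green
recovery test therefore establishes that the statistics detect the planted
signal in a world obeying the model's assumptions — not that real CORUM /
IntAct / BioGRID data would reproduce the published dataset-level numbers,
which need the original databases and the full 51-genome ortholog set.

One measured limitation, left as-is rather than tuned away: in the planted
pair cohort the "subset" partners (8–14 scattered extra losses, the scale
of the published worked example) rarely exceed the 90th-percentile subset
cutoff, because the cohort's background mixes broad with clade-confined
profiles and its upper subset-score tail sits near 35. Matching recovery
is ~98–100% and the four categories always partition the eligible pairs;
overall per-category recovery is ~65–70%. This mirrors the small subset
slice in the source analysis and is documented rather than patched.

## Numerical and degenerate-input choices

- Nearest-rank percentiles; strict exceedance at cutoffs.
- Partial correlation clamped to [-1, 1]; degeneracy (collinearity with
  the trend, or a constant trend) degrades to plain correlation with a
  flag; zero-variance event vectors are an error.
- Width ties in the subset score and all binning ties break
  lexicographically / by canonical id, so every output is deterministic.
- Empty networks, all-absent profiles, singleton complexes, self-pairs,
  unmapped proteins and fewer records than bins are errors, not warnings;
  unknown CLI config keys abort.
- Every stochastic step takes an explicit seed and restores the caller's
  RNG state.
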