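# cooccur3

Most pairs of interacting proteins do *not* show the matching phylogenetic
profiles naïve co-occurrence logic predicts. `cooccur3` implements a
triplet-based explanation: a protein **A** shared between two complexes
survives the loss of either partner module, so the profiles of its
partners **B** and **C** complement each other with respect to A instead
of matching it. The package is aimed at comparative genomicists working
with ortholog presence/absence matrices and protein-complex or
interaction data.

## What it computes

* **Pairwise classification.** Gains and losses of each orthologous group
  (OG) are reconstructed on a rooted species tree by Dollo parsimony
  (single gain at the LCA of the present species, minimal losses). Pair
  similarity is the partial correlation of event vectors given the global
  per-branch trend, `r_AB·G = (r_AB − r_AG r_BG) / √((1−r_AG²)(1−r_BG²))`.
  Eligible pairs (one member present in ≥⌈N/2⌉ species) are classified
  **matching / taxonomic / subset / other** against nearest-rank
  background percentiles (default 90th).
* **Complementarity score.** For a centered triplet (A; B, C),

  ```
  score = min(#{A∧B∧¬C}, #{A∧¬B∧C}) − #{(A∧¬B∧¬C) ∨ (¬A∧(B∨C))}
  ```

  counted over species. High scores flag shared subunits of two
  complexes.
* **Triangle analysis.** Open / open-with-2-in-paralogs / closed triangles
  of the interaction network versus sampled non-interacting triplets,
  binned into equal-count score bins, with Spearman trends of type
  fractions.
* **Integration.** Which classified pairs sit inside positive-scoring open
  triangles, per-category over-representation (χ²), and a log2 enrichment
  grid over pair similarity × triplet score.
* **Duplication retention.** Whether shared subunits (role A) are kept in
  duplicate (in-paralogs in ≥5 species, among OGs with ≥5 single-copy
  species) more often than partner proteins.
* **Synthetic data.** A seeded gene-content simulator (gain, loss,
  duplication on a Yule tree; planted shared-subunit architectures with
  complementary lineage losses) with ground-truth labels, used by the
  recovery tests.

## Worked example

The two published example triplets ship as packaged data
(`inst/extdata/`): the TOR-complex triplet (MTOR central, with RPTOR and
RICTOR) and an emerin-related triplet (HNRNPK central, with PDCD4 and
CDC37) over a 51-species eukaryote panel.

```r
library(cooccur3)
fx <- triplet_examples()
complementarity_score(fx$profiles["HNRNPK", ], fx$profiles["PDCD4", ],
                      fx$profiles["CDC37", ])
#> $n_good_b   12     # species with HNRNPK and PDCD4 but no CDC37
#> $n_good_c   13     # species with HNRNPK and CDC37 but no PDCD4
#> $n_bad       4     # species violating the pattern
#> $score       8     # min(12, 13) - 4: a strong shared-subunit signature
```

The TOR triplet scores `min(11, 3) − 4 = −1`: RPTOR is nearly ubiquitous,
so the complementation is one-sided.

A full pipeline run on simulated data:

```r
cfg <- sim_config(n_ogs = 800, n_arch = 20, n_indep = 10)  # 51 species
sim <- simulate_cooccur(cfg, seed = 1)
rep <- run_cooccur(sim$profiles, sim$tree, pairs = sim$og_network,
                   n_none = 20000, seed = 1)
rep
#> co-occurrence analysis report
#>   pairs: 300 (293 eligible)
#>   pie fractions: matching 79.2%, taxonomic 9.6%, subset 1.0%, other 10.2%
#>   triplets: 20725 (open 153, open2A 27, closed 558, none 19987)
#>   open-fraction trend over 20 bins: rho = 0.759 (p = 0.0001)
rep$duplication
#>   category n_triplets   n_A  n_BC pct_dup_A pct_dup_BC
#> 1     open        153   144   303      50.0       19.8
#> 2   open2A         27    27    54       0.0       22.2
#> 3   closed        558  1635  1635      23.9       23.9
#> 4    other      19987 58303 58303      20.9       20.9
```

Reading the output: co-complex pairs in this synthetic world are mostly
"matching" (module members share loss histories); the open-triangle
fraction rises with the complementarity score (Spearman ρ = 0.76 on this
small run; ~0.85 at the default 2000-OG scale); and the central OGs of
open triangles, simulated with doubled duplication pressure, are called
duplicated in 50% of role occurrences versus ~20% for their partners
(χ² p = 1.2e-07) — the planted retention signal. The unconnected-triplet
row is the background rate.

A command-line interface mirrors the stages
(`exec/cooccur3 <net-stats|classify-pairs|score-triplets|bin-analysis|
duplication|simulate|run>`), reading TSV/Newick/JSON and writing TSV/JSON.

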