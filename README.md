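# toxmodmine

Mining gene co-expression modules from toxicogenomic log-ratio matrices —
and turning them into kidney-injury biology: module clusters, phenotype
activation scores, an early-injury gene signature, protein-interaction
sub-network statistics, and frequent co-expression neighbourhoods of
biomarker genes such as *Havcr1* (KIM-1).

## Who this is for

Computational toxicologists and systems biologists who start from a genes
× conditions matrix of log2(treatment/control) expression ratios (e.g.
derived from a repeated-dose rat study) plus condition metadata
(chemical, dose, duration, histopathology scores), and want a tested,
deterministic, end-to-end implementation of the module-mining workflow
rather than a pile of one-off scripts.

## The method in brief

1. **ISA bi-clustering.** Modules are signed fixed points of the Iterative
   Signature Algorithm: alternating gene/condition scoring on row- and
   column-standardized matrices under sd-scaled thresholds
   (`|score| > t · sd`). Thresholds sweep the 5 × 5 grid
   {2.0, …, 4.0}² (25 combinations); per-combination results pass
   redundancy, shuffled-matrix robustness, and size/coherence filters
   (≤ 200 genes, mean pairwise intra-module correlation ≥ 0.4), then merge.
2. **Module clusters.** Pairwise overlap score
   `OS(A,B) = 2|G_A∩G_B|/(|G_A|+|G_B|) + 2|E_A∩E_B|/(|E_A|+|E_B|)` ∈ [0,2];
   complete-linkage clustering of `d = 1 − OS/2`, tree cut at 0.5.
3. **Activation and enrichment.** Per-gene Z-scores
   `Z_ij = (X_ij − μ_i)/σ_i`; cluster-by-phenotype activation
   `A_mp = mean |Z|` over the cluster's genes and the phenotype's
   conditions (null value √(2/π) ≈ 0.798); one-sided hypergeometric
   enrichment of target gene sets in clusters.
4. **Injury signature.** Random forest (1,001 trees) on labelled
   exposures; permutation importance ranks genes; the top 30 are refitted
   and evaluated by out-of-bag votes (sensitivity, specificity, ROC/AUC).
5. **Sub-network statistics.** Largest connected component of the injury
   gene set in a protein-interaction network; node/edge counts tested
   against 1,000 random-draw and 1,000 exact-degree-preserving rewiring
   nulls; degree and normalized betweenness with hub (> 5) and
   high-traffic (> 0.09) calls.
6. **Frequent co-expression.** For a query gene: top-20% correlates within
   each module containing it; genes appearing in ≥ 3 lists are its
   frequently co-expressed partners, validated by gene-label-shuffle and
   leave-conditions-out controls and Spearman concordance with external
   fold changes.

A synthetic-data module (`generate_matrix`, `generate_metadata`,
`generate_ppi`, `synthetic_study`) plants known bi-clusters, metadata,
labels and network structure so every stage is testable against ground
truth.

## Worked example

```r
library(toxmodmine)

res <- run_pipeline(default_config(seed = 1), out_dir = "demo_out")

res$manifest$stages$isa$n_modules
#> [1] 12
length(res$clusters)
#> [1] 4
round(unclass(res$activation), 2)
#>       P1   P2   C1   C2
#> MC1 1.13 1.36 0.59 0.63
#> MC2 0.60 0.59 1.79 0.52
#> MC3 0.61 0.66 0.58 2.15
#> MC4 1.36 1.05 0.57 0.63
```

The synthetic study plants its injury modules in the conditions of
phenotypes P1/P2, so clusters MC1 and MC4 are activated there
(≈ 1.1–1.4, well above the null value 0.798) and stay near baseline in
the chemical classes C1/C2 — the specificity pattern the activation
screen is designed to detect. Those two clusters are also the ones
enriched for the planted injury gene set (p ≈ 3e−52 and 9e−39).

```r
res$signature$model$oob_error          # 30-gene signature, OOB estimate
#> [1] 0.08333333
res$signature$performance$auc
#> [1] 0.9145
igraph::vcount(res$network$subnetwork); igraph::ecount(res$network$subnetwork)
#> [1] 18
#> [1] 72
res$network$degree_preserving$p_edges  # rewiring null, 1,000 iterations
#> [1] 0.000999001
```

The planted dense subgraph on the injury genes is recovered as an
18-node / 72-edge sub-network whose edge count no rewiring replicate
matched (p = 1/1001, the smallest value 1,000 iterations can report).

All stage outputs are also written to `demo_out/` as TSV/GMT/JSON plus a
`manifest.json` with every parameter, per-stage counts and timings; the
same config and seed reproduce every file byte-identically.

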