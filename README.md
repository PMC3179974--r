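# coevotree

Tree-similarity co-evolution analysis of protein interactions, with the
organism set as a first-class experimental variable.

Interacting protein families co-evolve, and their phylogenetic trees
mirror each other more closely than speciation alone explains.  The
*mirrortree* family of methods turns this into a predictor of
interaction: score a pair of proteins by the Pearson correlation between
their inter-ortholog distance matrices, taken over the organisms present
in both trees.  How well this works depends strongly on *which*
organisms the trees are built from — how many, how phylogenetically
spread, how redundant — and on whether the interaction is ancient
(conserved taxonomy-wide) or recent (conserved only among close
relatives).  `coevotree` is a pipeline for studying exactly that
dependence, end to end, for whom the question matters: method developers
benchmarking co-evolution predictors and practitioners deciding which
reference genomes to feed them.

The package implements:

* **Taxonomy sampling** — NCBI-dump and simplified-TSV taxonomy parsing,
  plus the two sampling criteria: *nearest* (growing clades around a
  reference organism) and *level* (one largest-proteome genome per group
  at each taxonomic depth).
* **Orthology** — reciprocal best hits from 12-column tabular hit files,
  with E-value ≤ 1e-5 and two-sided alignment coverage ≥ 70% filters.
* **Phylogenetics** — p-distances with pairwise gap deletion, a native
  deterministic Saitou–Nei neighbor-joining, patristic distances,
  Newick and PHYLIP-square I/O.
* **Three scorers** — mirrortree (MT): correlation of distance matrices
  over ≥ 15 shared organisms with P ≤ 1e-5; profile-correlation (PC):
  correlation of two proteins' co-evolutionary profiles; context-mirror
  (CM): order-*k* partial correlations that remove the *k* strongest
  third-party signals ("level" of specificity).
* **Coverage-aware evaluation** — gold standards with all-pairs
  negatives; ROC with TPR = Tp/P, FPR = Fp/N computed against the
  *original* totals so low-coverage methods yield shorter curves;
  F-measure curves and max-F; per-protein interactor ranking with
  in-list (Mann–Whitney) AUC.
* **A synthetic benchmark generator** — Yule species trees, per-family
  log-normal distance noise d(i,j) = t(i,j)·exp(σz) with pairwise
  correlated perturbations for interacting families (correlation ρ),
  optional ε-strain redundancy and clade-confined ("recent")
  co-evolution, consistent taxonomies, hit tables with known ortholog
  truth, and gold standards — so the whole pipeline is testable with no
  downloads.

## Worked example

Simulate a small benchmark with planted co-evolution, score it with the
three methods, and evaluate:

```r
library(coevotree)

cfg <- sim_config(n_organisms = 30, n_families = 20,
                  n_interacting_pairs = 5,
                  coevolution_strength = 0.9, noise_sd = 0.3, seed = 42)
bench <- simulate_benchmark(cfg)
bench
#> sim_benchmark: 30 organisms, 20 families, 5 interacting pairs (rho = 0.90, sigma = 0.30)

sm <- build_score_matrix(bench$family_matrices, min_common = 15, p_max = 1e-5)
mt <- score_matrix_to_table(sm)
head(mt[, c("protein_a", "protein_b", "score", "n_common", "p_value")], 3)
#>     protein_a protein_b     score n_common       p_value
#> 82     fam004    fam014 0.9642287       27 2.510890e-203
#> 102    fam011    fam015 0.9593992       28 9.026792e-209
#> 156    fam003    fam019 0.9589582       26 7.298716e-179

roc_curve(mt, bench$gold)
#> roc_curve: AUC = 1.0000, coverage = 1.000, 45 thresholds
```

The three top-scoring pairs are all planted interactions (`fam004`–
`fam014` is the strongest), and with full coverage and a strong planted
signal the totals-based ROC reaches AUC 1.0.  Asking for one protein's
best partner reproduces the per-protein ranking view:

```r
rank <- rank_interactors(mt, "fam004", bench$gold)
rank[c("n_candidates", "n_positives", "auc_local", "top_partner", "top_score")]
#> $n_candidates [1] 19   $n_positives [1] 1
#> $auc_local    [1] 1    $top_partner "fam014"   $top_score 0.964
```

i.e. among the 19 scored candidates for `fam004`, the single true
interactor ranks first (in-list AUC 1.0) with correlation 0.96.

## The analysis workflow

The study itself lives in `analysis/`, five thin drivers over the
package functions, run in order from the repository root:

```sh
Rscript analysis/01_simulate_benchmark.R   # benchmark bundle -> results/benchmark/
Rscript analysis/02_organism_sets.R        # nearest_* / level_* sets
Rscript analysis/03_score_methods.R        # MT / PC / CM score tables, orthology demo
Rscript analysis/04_evaluate_grid.R        # organism-set x method grid -> results/grid/
Rscript analysis/05_redundancy_and_clade.R # strain-redundancy and interaction-age scenarios
```

Step 04 writes the grid summary (`results/grid/summary.tsv`: AUC, max-F
and coverage per organism set × method); step 05 writes
`results/properties.tsv` and prints the two qualitative findings, e.g.:

```
redundancy: mean background rise MT +0.0120 vs PC -0.0063 (MT > PC in 9/10)
recent interactions: AUC clade-only 0.983 vs all organisms 0.663 (clade wins 10/10)
old interactions:    AUC clade-only 0.983 vs all organisms 1.000
```

— ε-strain redundancy inflates mirrortree's background correlations
while profile-correlation filters them, and clade-confined ("recent")
interactions are detected far better from clade-only organism sets,
while taxonomy-wide ("old") ones favor the full set.

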