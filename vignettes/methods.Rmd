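---
title: "Organism-set sampling and tree-similarity co-evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organism-set sampling and tree-similarity co-evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevotree)
```

## The scientific question

Interacting or functionally coupled protein families tend to co-evolve:
their phylogenetic trees are more similar than the underlying speciation
process alone would make them.  Tree-similarity ("mirrortree") methods
exploit this by correlating the inter-ortholog distance matrices of two
families over a reference set of organisms.  The performance of every
variant of the idea depends on that organism set — its size, its
phylogenetic spread, and its redundancy — and on the *age* of the
interaction being sought: an interaction conserved across the whole
taxonomy leaves its trace in distant genomes, while a recently rewired
one is visible only among close relatives.

`coevotree` implements the full pipeline needed to study these effects —
taxonomy-based organism sampling, reciprocal-best-hit orthology,
distance/tree reconstruction, three co-evolution scorers, and
coverage-aware evaluation — together with a synthetic benchmark
generator so that every claim the package makes is testable without any
external database.

## The three scorers

**Mirrortree (MT).**  For families A and B with patristic distance
matrices $d_A$ and $d_B$, the score is the Pearson correlation $r$
between the vectors $\{d_A(i,j)\}$ and $\{d_B(i,j)\}$ over all pairs of
organisms present in *both* families.  Two admissibility rules are
applied throughout: at least 15 organisms must be shared by the two
trees, and the correlation's two-sided t-test P-value (with
$\binom{n}{2}-2$ degrees of freedom) must be $\le 10^{-5}$.  The
P-value treats distance pairs as independent observations even though
pairs sharing a leaf are not; this is the method's standard
approximation and is kept deliberately, as a documented caveat rather
than a bug.

**Profile correlation (PC).**  The matrix of significant MT correlations
over all families in a genome defines, for each protein, a
*co-evolutionary profile*: its row of correlations with everyone else.
PC re-scores a pair as the Pearson correlation of the two profiles,
excluding the pair itself.  Profile entries masked by the significance
rule are treated as missing and the correlation is computed over the
jointly available positions (pairwise-complete); a `zero_fill` mode that
substitutes 0 instead is provided for comparison because the choice is
genuinely open.  We require at least 3 joint positions — the minimum for
a defined correlation plus one degree of freedom.

**Context mirror (CM).**  CM separates specific from general
co-evolution with partial correlations: for a pair (A, B) the candidate
"controllers" C are the proteins whose correlations with both A and B
are available; they are ranked by $|r_{AC} \cdot r_{BC}|$ and the top
*k* (the *level*, 10 by default in the analyses) are partialled out at
once by inverting the $(k+2)\times(k+2)$ correlation submatrix:
$\rho_{AB\cdot S} = -P_{12}/\sqrt{P_{11}P_{22}}$ with $P = R^{-1}$.
Controllers are admitted greedily, requiring each new controller's
correlations with A, B and the already chosen controllers to be
available; if the submatrix is numerically singular the largest
non-singular leading subset is used, and a pair with no usable
controller falls back to the raw correlation and is flagged.  The exact
construction of CM "levels" is not fully pinned down in the literature
describing the approach; top-k confounders with order-k partial
correlation is this package's explicit interpretation, and both the
ranking rule and the estimator are exposed rather than hidden.

## Organism sampling

The sampling operates on an NCBI-style taxonomy: a rooted hierarchy of
ranked nodes with genomes attached, carrying no branch lengths.

* **nearest** — walk from a reference genome's attachment node up to the
  root; at each visited node take every genome in its subtree.  The sets
  are nested by construction (strains of the reference species first,
  then its family, and so on to the full genome set) and always contain
  the reference.
* **level** — cut the hierarchy at each successive depth; at depth *k*
  the genomes partition into the groups induced by their depth-*k*
  ancestors and one genome is taken per group: the one with the largest
  proteome, maximizing the odds of finding orthologs downstream.  Ties
  are broken by lexicographic genome id for determinism.

Depth is counted in explicit tree levels rather than named ranks, since
rank names are irregular across lineages; this keeps the cut
well-defined on arbitrary trees.  A genome attached above the cut forms
its own singleton group (nothing is silently dropped), and cuts below a
genome's attachment key the genome by itself, so the deepest level
always returns the complete genome set.

## Orthology

Orthologs are taken as BLAST-style best bidirectional hits from a
precomputed all-vs-all hit table (the package parses the 12-column
tabular layout; it does not run the search itself).  Hits are filtered
at E-value $\le 10^{-5}$ and alignment coverage $\ge 70\%$.  The
coverage denominator is ambiguous in common usage; we require 70% of
*both* the query and the subject length — the symmetric, strictest
reading — and expose the threshold.  When a protein pair has several
HSPs only the lowest-E-value row is kept.  "Best" is lowest E-value,
tie-broken by bit score and then lexicographic subject id, making the
whole stage deterministic.

## Trees and distances

Sequence distances are uncorrected p-distances with pairwise gap
deletion ("exclude gaps" taken literally); a Kimura correction switch
exists but is off by default, since distance-method choices at this
stage matter far less than the organism set under study.  Trees come
from a native Saitou–Nei neighbor-joining implementation whose
tie-break on the Q-criterion (lexicographically lowest label pair,
merged nodes inheriting the smaller label) makes output Newick strings
reproducible; negative branch-length estimates are clamped to zero.  On
additive input the NJ tree reproduces the input metric to numerical
precision, which the test suite exercises against random tree-generated
matrices, and patristic distances are checked against an independent
path-enumeration oracle and the four-point condition.  Trees are
treated as unrooted for path sums, so root placement is irrelevant.

## Evaluation conventions

Gold standards are positive pair sets with negatives constructed as
*all* pairs among the involved proteins minus the positives; the totals
P and N are frozen at construction.  Two evaluation conventions coexist
deliberately:

* **Global (totals-based) ROC** — thresholds sweep the scored list, but
  TPR = Tp/P and FPR = Fp/N use the *original* totals, whether or not
  the method could score a pair with the organism set at hand.  Unscored
  gold pairs can never become Tp or Fp, so a low-coverage method
  produces a curve that terminates before (1, 1): curve length encodes
  applicability.  AUC is the trapezoidal area under the realized curve.
  Tied scores move in a single threshold step.
* **Local (in-list) AUC** — for per-protein interactor ranking the AUC
  is computed over the positives/negatives present in that protein's
  candidate list only, as the normalized Mann–Whitney U with ties
  counting ½.

The F-measure curve reports precision Tp/(Tp+Fp) and recall Tp/P per
threshold; its maximum is the single-number summary used in the
experiment grid.

## The synthetic benchmark

The generator is the package's stand-in for real proteomes and curated
interaction sets, and its defaults *are* the study conditions used by
the tests and the acceptance script.  It emulates:

* a Yule-type species tree (`rphylo`, birth 1, death 0) over
  `n_organisms = 40` leaves;
* per-family multiplicative log-normal distance noise:
  $d_f(i,j) = t(i,j)\,e^{\sigma z_f(i,j)}$ with $\sigma = 0.3$ —
  the simplest model that keeps matrices positive and symmetric while
  giving a tunable tree-correlation;
* co-evolution as a shared perturbation component: interacting pairs
  draw $z = \sqrt{\rho}\,s + \sqrt{1-\rho}\,e$ with a common $s$, so
  their perturbations correlate at exactly $\rho$
  (`coevolution_strength = 0.9`, 20 interacting pairs among 60
  families);
* ortholog absence as independent per-organism retention at probability
  0.9 — a typical cross-bacteria ortholog coverage; families left with
  fewer than 3 organisms are kept but flagged degenerate so downstream
  minimum-organism filters are exercised;
* strain redundancy by replacing random leaves with
  $\varepsilon$-cherries ($\varepsilon = 10^{-3}$) inserted so that all
  other distances are untouched;
* "recent" interactions by confining the shared component to organism
  pairs inside a clade holding `recent_clade_fraction` of the leaves
  (the internal node with leaf count closest to the target, chosen
  deterministically);
* a taxonomy derived by cutting the species tree at its topological
  depths, so taxonomy and tree are consistent by construction, with
  deterministic label-derived proteome sizes for level sampling.

All randomness flows from one root seed through tagged substreams
(`derive_seed`), so a configuration reproduces byte-identical output
files and the stages remain decoupled.

What the generator does **not** emulate: realistic substitution
processes beyond a Jukes–Cantor option for the sequence stage, indels,
horizontal transfer, paralogy, or correlated gene loss.  Passing tests
therefore demonstrate that the machinery is correct and that the
claimed orderings hold under a clean co-evolution signal; they do not
certify performance numbers on real genomes, where the paperwork of
orthology errors and phylogenetic bias is far messier.

## Scenario experiments and problem sizes

Two scenario choices depart from the defaults, both fixed at design
time.  The redundancy and clade experiments use `retention_prob = 1` to
isolate the effect under study from coverage noise.  The clade
experiment uses 60 organisms so that a 30% clade (~18 leaves) clears
the 15-common-organism admissibility rule without touching it; with the
default 40 organisms a 12-leaf clade would be categorically
unevaluable, which is itself the coverage phenomenon measured
separately (context-mirror's evaluable fraction collapses between 20
and 12 organisms, and at 12 the 15-organism rule zeroes every method).

Replicated claims (the redundancy ordering — MT's background
correlation among non-interacting pairs rises more than PC's; the
recent-interaction ordering — clade-only beats all-organisms AUC when
the signal is clade-confined and not otherwise) use 10 seeded
replicates of the 40–60-organism, 60-family benchmark.  These sizes
keep each experiment in the tens of seconds while leaving the orderings
clearly resolved; they were chosen once and the acceptance thresholds
(8/10 replicates) were not revisited afterwards.

## Numerical choices

* Pearson P-values use the closed-form t approximation; `r = ±1` maps
  to `p = 0`.
* Zero-variance distance vectors make a pair's score undefined (masked),
  never an exception.
* NJ Q-ties and proteome-size ties break lexicographically; all sort
  orders in scored tables are total, so outputs are reproducible.
* Correlation submatrix inversions that return a non-positive diagonal
  or a partial correlation outside [-1, 1] beyond rounding are treated
  as singular and trigger the controller-subset fallback.
* The four-point check uses a relative tolerance of 1e-9 on the two
  largest pair sums.

## Known limitations

The admissibility P-value inherits the independence approximation noted
above.  The CM level construction is an interpretation (documented
above), not a verbatim reimplementation of any published code.  The
totals-based ROC makes AUC values from different coverage levels
incomparable as pure ranking statistics — that is by design, since
applicability is part of what is being measured, but it means "AUC"
must always be read together with "coverage" in the grid summaries.
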