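---
title: "Network-neighborhood drug repositioning: model and design notes"
author: "netDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-neighborhood drug repositioning: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netDR)
```

## The model

`netDR` implements a module-similarity view of drug repositioning.  The
premise is that a drug is a plausible treatment when the set of genes it
perturbs occupies the same *network neighborhood* as the genes the
disease perturbs, and when the two perturbations point in opposite
directions (signature reversal).  Exact gene-for-gene overlap between a
drug signature and a disease signature is rare — expression changes
propagate to interaction partners — so both signatures are first
expanded into modules on a weighted functional interaction network
(FIN) and compared there.

The pipeline is:

1. **FIN pruning.** Edge weights encode functional similarity in
   (0, 1]; edges with weight strictly below 0.1 are removed, then genes
   left without any interaction.  The floor reflects that the weight
   mass below 0.1 in literature FINs represents negligible functional
   similarity.

2. **Direct-neighbor modules.** Drug DEGs (|z| > 1, strict inequality)
   and disease DEGs (FDR < 0.01 strict, linear fold-change
   2^|log2FC| ≥ 2) are intersected with the FIN and expanded by one hop:
   module members are the mapped DEGs plus every adjacent gene, with
   the induced subnetwork.  No further weight filtering happens inside
   a module, and metrics are computed module-locally (degrees,
   neighborhoods and random walks are those of the induced subnetwork,
   not the global FIN).

3. **Gene scoring.** Three metrics score module members; each has a
   plain topological base and a z-integration step.

   *Adamic–Adar.* The pairwise similarity of genes x, y is
   $S_{xy} = \sum_{z \in \lambda_x \cap \lambda_y} 1/\log k_z$ with
   $k_z$ the *weighted* degree (strength) of the common neighbor, and
   a gene's base score is $S_x = \sum_{y \neq x} S_{xy}$.

   *PageRank.* Weighted damped PageRank with uniform teleportation,
   damping 0.75 and no personalization; each undirected edge acts as
   two directed edges with transition probability proportional to its
   weight.

   *Neighborhood scoring.*
   $X_i = \alpha x_i + (1-\alpha) \big(\sum_{j:\,w_{ij} > \epsilon} x_j\big)/N_i$
   smooths a gene's z with the mean z of its supra-threshold-weight
   neighbors ($\alpha = 0.7$, $\epsilon = 0.1$; $N_i$ counts only the
   supra-threshold neighbors, and $X_i = \alpha x_i$ when there is
   none).

4. **z-integration.** Every metric uses the same three-branch rule: a
   gene in both modules carries the combined signal
   $z_{drug} + z_{disease}$, a gene in one module carries its own z,
   and an unmeasured gene carries exactly 0 (so it is neutral — the
   same convention the generator uses for unperturbed genes).  AA1 and
   PR1 multiply the base score by $0.5^{|z|}$; AA2 and PR2 divide by
   $e^{|z|}$.  Both factors strictly decrease in |z|: a shared gene
   whose drug and disease z cancel keeps its topological score, while
   one-sided or concordant perturbation is damped.  For neighborhood
   scoring the branch rule supplies the z map itself, and genes are
   ranked by |X| *ascending*: a gene neutralized in the combined signal
   is the configuration the metric rewards, which is what the
   smallest-first ordering expresses.  (A signed ascending order would
   instead put the most strongly down-perturbed genes first and is
   provably uninformative when signature signs are symmetric, so the
   package ranks magnitudes; this is the one place where two readings
   of the ordering convention exist and the package picks the one under
   which the metric measures reversal at all.)

5. **Module-similarity AUC.** The adjusted scores rank one module's
   genes; the ranking is evaluated against the *other* module's
   member set at 100 percent-rank cutoffs (top 1%, 2%, …, 100%), each
   cutoff yielding one confusion matrix and one ROC point.  AUC_DAPN
   ranks the drug module against DGN membership; AUC_DGN swaps the
   roles; the drug's score is the geometric mean
   $\sqrt{AUC_{DAPN} \cdot AUC_{DGN}}$, so a drug must look like the
   disease from both directions.  Precision, recall and F1 are
   reported at the break-even cutoff k = |reference ∩ ranked| on each
   side and combined by the same geometric mean.

## Parameters

| Parameter | Default | Role |
|---|---|---|
| `weightFloor` | 0.1 | minimum FIN edge weight (functional-similarity units) |
| `drugZThreshold` | 1.0 | strict absolute z cutoff for drug DEGs |
| `fdrThreshold` | 0.01 | strict FDR cutoff for disease DEGs |
| `fcThreshold` | 2.0 | non-strict absolute linear fold-change cutoff |
| `damping` | 0.75 | PageRank damping factor |
| `alpha` | 0.7 | NS blend between a gene's own z and its neighborhood mean |
| `epsilon` | 0.1 | NS edge-weight threshold (matches the pruning floor) |
| `nThresholds` | 100 | percent-rank ROC cutoffs |
| `aucCutoff` | 0.6 | combined-AUC candidate threshold (0.7 for long lists) |

The defaults are the method's published operating point and are not
meant to be tuned per run.  The inequality conventions were chosen
once: the drug z filter and the FDR filter are strict; the fold-change
filter is non-strict so a gene printed at exactly the threshold
qualifies.

## Numerical choices

* **Adamic–Adar denominator.** With weights ≤ 1, module-local strengths
  can approach 1, where $1/\log k$ explodes, and fall below it, where
  it turns negative.  The implementation floors the strength inside the
  log: $1/\log(\max(k, f))$ with `strengthFloor` f = 2, capping each
  common-neighbor contribution at the unweighted degree-2 value
  $1/\log 2 \approx 1.44$.  The rule is continuous, monotone, identical
  to the plain inverse-log wherever k ≥ 2, and inert on realistic
  interactomes (strengths well above 2); without it, weakly-weighted
  star neighborhoods in small induced subnetworks dominate every
  ranking.  Natural logarithm throughout.

* **PageRank convergence.** Power iteration to an L1 change below
  1e-12 (at most 1000 iterations, then an error reporting the
  residual); scores are renormalized to sum exactly 1 and checked to
  1e-9.  Dangling vertices redistribute uniformly, though direct-
  neighbor modules cannot contain isolated genes by construction.

* **Ranking ties.** All gene rankings break score ties by C-locale
  lexicographic gene identifier, so every output is deterministic and
  independent of input order.

* **ROC construction.** Percent cutoffs use round-half-up, are floored
  at one gene, and duplicates collapse when the module has fewer than
  100 genes.  Anchor points (0,0) and (1,1) are added because the
  percent grid never includes the empty prediction set; without the
  origin the trapezoid is ill-anchored.  At one-cutoff-per-rank
  resolution the trapezoidal AUC equals the Mann–Whitney statistic
  exactly (a test asserts this).

* **Degenerate references.** If the reference set, restricted to the
  ranked genes, is empty or covers the whole list, one ROC denominator
  is always zero; the drug–metric pair is flagged `NA` and logged
  rather than aborting a batch, and `NA` rows sort last and are never
  candidates.

* **Caching.** The DGN and its AA/PR base scores are drug-independent
  and computed once per run; only the z-adjustment, ranking and AUC are
  per-drug.  Results are identical whether drugs are evaluated singly
  or in a batch, in any order (a test asserts this too).

## The synthetic benchmark

`simulateStudy()` generates data with the statistical shape the method
assumes, so that every stage — and the planted-signal recovery property
— can be exercised without any external download:

* an Erdős–Rényi (or Barabási–Albert) gene network, default 500 genes
  at mean degree 10, with Beta(0.7, 5) edge weights imitating the
  heavily right-skewed weight histograms of literature FINs (most mass
  below 0.1), pruned by the standard path, resampled until ≥ 90% of
  surviving genes share one component;
* a connected disease module of 40 genes grown by BFS from a random
  root — network-localized disease genes being the method's premise —
  with FDR, fold-change and z values constructed so the DEG filter
  recovers exactly the planted set (signs random, |z| one half-normal
  above the threshold);
* 25 drug signatures over the same gene universe with matched DEG-set
  sizes: one *reversal* drug whose z on planted-module genes is
  $-s \cdot z_{disease} + \sqrt{1-s^2}\,N(0,1)$ (s =
  `reversalStrength`; s = 1 negates the disease signature exactly),
  and decoys with uniformly placed supra-threshold DEGs.

Two generator details are deliberate design decisions rather than
emulation:

* the reversal drug keeps a small off-module DEG complement
  (max(4, 15%) of the set): an all-in-module reversal drug would make
  its module a subset of the disease module and both directional AUCs
  undefined;
* unperturbed genes carry near-zero z (sd 0.05, truncated inside the
  DEG filter margin).  This mirrors the z = 0 neutrality convention
  for unmeasured genes.  Real signatures have noisier backgrounds, and
  the noise is not neutral: for any two independent noise terms,
  $|z_1 + z_2|$ stochastically dominates $|z_1|$, so background noise
  systematically damps shared genes slightly more than one-sided ones
  and dilutes the module-overlap signal.  Passing the planted-signal
  tests therefore demonstrates that the method recovers a clean
  reversal embedded in realistic topology, not that it is robust to
  heavy background noise, cell-line effects, or L1000 measurement
  structure, none of which the generator models.

The same mechanism makes the null benchmark (reversal strength 0)
slightly conservative: decoy DEGs landing inside the disease module are
damped reference genes, so decoy combined AUCs center a little below
0.5 rather than on it.  `scripts/acceptance.R` computes the pooled null
median alongside the recovery rates.

Determinism: each generator stage seeds R's RNG from `rngSeed` plus a
fixed offset (network +0, disease +1, drugs +2), so standalone stage
calls and `simulateStudy()` agree and every run is exactly replayable.

## Problem sizes used by the test suite

The property tests run the full pipeline on the default benchmark
(500 genes, 25 drugs) over 20 generator seeds for recovery and null
calibration and 10 seeds × 4 strengths for monotonicity; metric oracles
use 50 random graphs of up to 20 nodes (Adamic–Adar, against a
brute-force triple loop) and 15 nodes (PageRank, against a dense linear
solve), and the AUC calibration uses 500 random rankings of 200 genes.
These sizes were chosen as the smallest at which the module structure
(a module occupying a minority of the network, reference sets of
10² genes) resembles the real regime.

## Known limitations

* The disease z-score is consumed as an input column; the package does
  not derive it from counts (any DE pipeline's signed z or moderated
  statistic will do, as long as its sign convention matches the drug
  signatures').
* Gene identifiers are opaque case-sensitive strings; no symbol/alias
  resolution is attempted, so inputs must share a namespace.
* The one-hop module definition is fixed; weight-aware or multi-hop
  expansions are out of scope.
* Combined AUC has no attached significance estimate; the 0.6/0.7
  cutoff is a fixed operating point, not a p-value.
* F1/precision/recall depend on the break-even cutoff choice; other
  cutoffs can be computed with `confusionMetrics(..., k = )`.
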