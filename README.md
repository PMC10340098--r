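# netDR: network-neighborhood drug repositioning

`netDR` ranks candidate drugs for a disease by asking how similar the
*network neighborhood* of the drug's transcriptional footprint is to the
neighborhood of the disease's differentially expressed genes, on a
weighted functional interaction network (FIN).  It is aimed at
computational drug-repositioning analyses that start from
LINCS-L1000-style drug perturbation z-scores and a cohort-level
differential-expression table (e.g. a TCGA tumor-vs-normal contrast).

## The method

Inputs are (i) a weighted undirected gene–gene FIN with weights in
(0, 1], pruned at a weight floor of 0.1; (ii) one z-score signature per
drug; (iii) a disease table with per-gene log2 fold-change, FDR and a
signed z-score.

1. **Modules.** Drug DEGs (|z| > 1, strict) and disease DEGs
   (FDR < 0.01 and linear |FC| ≥ 2) are mapped onto the FIN as
   direct-neighbor modules: the drug-affected protein network (DAPN)
   and the disease gene network (DGN), each consisting of the mapped
   DEGs plus every gene adjacent to one, with the induced subnetwork.

2. **Gene scores.** On each module subnetwork three metrics score every
   member gene:
   - *Adamic–Adar* (AA): S(x) = Σ_{y≠x} Σ_{z ∈ N(x)∩N(y)} 1/log k_z,
     with k_z the weighted degree of the common neighbor z;
   - *PageRank* (PR): weighted damped PageRank, damping 0.75;
   - *Neighborhood scoring* (NS):
     X_i = α·x_i + (1−α)·mean{ x_j : w_ij > ε }, α = 0.7, ε = 0.1.

   Differential expression enters through a three-branch z rule: a gene
   in both modules carries |z_drug + z_disease| (a drug that reverses
   the disease signature drives this toward 0 — the rewarded
   configuration), a gene in one module carries its own |z|.  AA1/PR1
   multiply the base score by 0.5^|z|, AA2/PR2 divide by e^|z|; NS uses
   the same branch rule as its z map and ranks by |X| ascending
   (neutralized genes first).

3. **Drug score.** Module-gene rankings are turned into ROC curves at
   100 percent-rank cutoffs: AUC_DAPN scores the DAPN ranking against
   DGN membership, AUC_DGN the reverse, and the drug's final score is
   `Combined.AUC = sqrt(AUC_DAPN · AUC_DGN)`.  Drugs at or above a
   combined AUC of 0.6 (configurable) are flagged as repositioning
   candidates.

Because the real inputs (LINCS, TCGA, a literature FIN) are large
external downloads, the package ships a synthetic benchmark generator
(`simulateStudy()`) that emulates their statistical structure — sparse
right-skewed edge weights, a planted connected disease module, one
drug that anti-correlates with the disease signature among random
decoys — so the whole pipeline is testable offline.

## Worked example

```r
library(netDR)

spec  <- simSpec(rngSeed = 1)          # 500 genes, 40-gene disease module,
study <- simulateStudy(spec)           # 25 drugs, reversal strength 0.9
study$network
#> WeightedNetwork: 490 genes, 1074 weighted interactions
#>   weight floor: 0.1

cfg <- runConfig(metrics = c("AA2", "PR2", "NS"))
out <- runPipeline(study$network, study$disease, study$drugs, cfg)
head(out$results[, c("drug", "metric", "auc_dapn", "auc_dgn",
                     "combined_auc", "is_candidate")], 5)
#>       drug metric  auc_dapn   auc_dgn combined_auc is_candidate
#> 1 reversal    AA2 0.7080078 0.6937500    0.7008426         TRUE
#> 2  decoy10    AA2 0.5502030 0.6125992    0.5805635        FALSE
#> 3  decoy11    AA2 0.5429219 0.5548599    0.5488585        FALSE
#> 4  decoy24    AA2 0.5425757 0.5372621    0.5399123        FALSE
#> 5  decoy02    AA2 0.5374410 0.5270810    0.5322358        FALSE
```

The planted reversal drug tops the AA2 ranking with a combined AUC of
0.70 — its drug module overlaps the disease module and its z-scores
cancel the disease z-scores there — while the 24 decoys cluster around
the chance level of 0.5 and fall below the 0.6 candidate cutoff.

Real data go through `loadNetwork()`, `readDiseaseSignature()` and
`readDrugManifest()`, or the shell wrapper:

```sh
netdr simulate --seed 5 --out sim/
netdr run --network sim/fin.tsv --disease sim/disease.tsv \
          --drugs sim/manifest.tsv --out results/
```

which writes `results.tsv`, `candidates.tsv`, `run.log` and
`config.resolved.yaml`.

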