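# mrmrpath

Biomarker discovery for two-class expression studies by
minimum-redundancy-maximum-relevance (mRMR) feature selection and
shortest-path analysis of a protein–protein interaction (PPI) network.

The package is aimed at transcriptomics / systems-biology analysts who want
a compact, mutually complementary gene panel separating tumour from
non-tumour profiles — rather than a long list of individually differential
genes — together with the network context of that panel. The motivating
design is a pancreatic ductal adenocarcinoma cohort of 45 tumour and 45
adjacent non-tumour microarray profiles.

## The method

**Ranking.** Probes are ranked greedily by the mRMR score: the set *S*
starts with the probe of maximal mutual information (MI) with the phenotype
*y*, and each step adds the probe maximizing

    q = I(x_j, y) − (1/|S|) · Σ_{x_k ∈ S} I(x_j, x_k)

MI is estimated by the Gaussian/correlation form −½·ln(1−ρ²) (point-biserial
against the binary phenotype), with an equal-frequency binned plug-in
estimator available as a sensitivity check.

**Subset size.** Incremental feature selection (IFS) scores every nested
prefix s_i = {f_1, …, f_i} of the ranking by jackknife (leave-one-out)
k-nearest-neighbour accuracy under the Chou cosine-type distance
D(e₁,e₂) = 1 − e₁·e₂/(|e₁||e₂|), and keeps the smallest subset within δ
(default 0.01) of the best accuracy — the parsimonious choice near the
curve's maximum. Accuracy is (TP+TN)/(TP+TN+FP+FN) with tumour positive.

**Network stage.** STRING-style edges with combined score strictly above
0.8 form the high-confidence network; the selected genes are mapped through
a gene→protein multimap onto in-network *seed proteins*; one minimal-hop
shortest path is traced per seed pair (BFS, deterministic lexicographic
tie-break) and merged into a sub-network. Each protein's *betweenness* is
the number of seed-pair paths on which it lies as a non-endpoint node.

**Hub test.** 1000 permutations draw random 8-protein seed sets from the
background network and recompute betweenness under identical rules;
per-protein p = (c+1)/(n+1) with significance at p < 0.05.

Simulators for expression matrices (planted informative / redundant / noise
probes) and scale-free PPI networks (planted hubs) provide ground truth so
every stage is testable without external downloads. See
`vignettes/mrmr-shortest-path-methods.Rmd` for the full methods account.

## Worked example

The `analysis/` directory holds the pipeline as numbered stage scripts,
each a thin driver over the package functions, coupled only through files
under `results/` (simulate → rank → ifs/classify → network → permute; the
single-call equivalent is `run_all()`):

```sh
Rscript analysis/01_simulate_data.R --seed 1   # write the simulated study
Rscript analysis/02_rank_features.R            # mRMR ranking (N = 500)
Rscript analysis/03_ifs_classification.R       # IFS curve + jackknife KNN
Rscript analysis/04_subnetwork.R               # shortest-path sub-network
Rscript analysis/05_permutation_test.R --seed 1
```

which prints, stage by stage:

```
wrote results/inputs: 500 probes x 90 samples (45 tumour / 45 non-tumour)
network: 624 interactions among 201 proteins, scores in [0.85, 1.00]

ranked 500 probes; top of the list:
 rank probe_id gene_symbol   q_score
    1   p00015   GENE00015 0.1457491
    2   p00005   GENE00005 0.1234935
    3   p00011   GENE00011 0.1150538
    ...

IFS curve over 500 subset sizes
  max accuracy: 0.9667 at size 12
  selected size: 12 (accuracy 0.9667, tolerance 0.01)
confusion at selected size 12: TP=45 TN=42 FP=3 FN=0 (accuracy 0.9667)

map_seed_proteins: 12 gene(s) -> 13 protein(s) -> 13 in network (...)
sub-network: 39 proteins, 67 interactions from 78 seed pairs
largest betweenness: PRT00003 with 29

16 of 39 sub-network proteins pass the permutation test (p < 0.05)
```

Reading: on the simulated cohort the 12-probe panel selected by IFS
classifies 87 of 90 samples correctly in leave-one-out validation; mapping
the panel's genes into the simulated interaction network and tracing all
pairwise shortest paths yields a 39-protein sub-network in which 16
proteins occur on significantly more seed-pair paths than random 8-protein
seed sets produce.

The same run end-to-end, with a manifest and config-hashed outputs:

```r
library(mrmrpath)
paths <- write_simulation(expression_sim_spec(seed = 1),
                          network_sim_spec(seed = 1), "results/inputs")
cfg <- pipeline_config(paths$expression, paths$labels, paths$edges,
                       paths$gene_map, out_dir = "results/run")
run_all(cfg)
```

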