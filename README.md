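# arcnet

EEG dementia classification from **Angle-Relation Connection (ARC)
networks**: an R package for researchers who want to turn single-channel
EEG segments into directed weighted graphs, extract geometry-aware graph
features, and evaluate Alzheimer's disease (AD) / frontotemporal dementia
(FTD) / healthy control (HC) classification with wrapper feature
selection.

## The method

Every sample $x_t$ of a segment becomes a node. An edge $i \to j$
($j > i$) exists when the chord angle
$\theta_{ij} = \arctan\big((x_j - x_i)/(j - i)\big)$ strictly exceeds
$\theta_{ik}$ for every intermediate $k$ — equivalently, when every
intermediate sample lies strictly below the chord. The resulting graph is
a connected DAG containing the temporal chain. Each edge is weighted by

$$w_{ij} = \alpha\,|x_j - x_i| + \beta\,\tfrac{1}{j-i} + \gamma\,|\theta_{ij}|,
\qquad (\alpha, \beta, \gamma) = (0.5,\, 0.3,\, 0.2)\ \text{by default.}$$

From each network a 15-entry feature vector is computed: 13 classical
graph measures (edge count, weight moments, Gini index, global
efficiency, modularity, degrees, betweenness, strength, path length) plus
two geometric indices — **WAII** (mean coefficient of variation of each
node's outgoing weights) and **CBEFI** (mean normalised second difference
along edges). An Ant Colony Optimization wrapper (30 ants × 50
iterations, subsets of 4–8 features, cross-validated random-forest
accuracy as fitness) selects discriminative subsets, and the evaluation
harness runs five classifiers (random forest, AdaBoost, bagged trees,
kNN, RBF-SVM) over binary and multiclass tasks with subject-grouped
splits.

A synthetic cohort generator (oscillations + AR(1) noise + triangular
spikes, with class profiles encoding oscillatory slowing, curvature
smoothness and transient sharpness) makes the whole pipeline testable
without any external recordings. CSV, EDF and EEGLAB SET files in a BIDS
layout are supported for real data.

## Worked example

The 10-point segment `[156.20, 161.28, 160.55, 161.87, 163.43, 175.29,
169.43, 161.67, 157.32, 162.65]`:

```r
library(arcnet)
x <- c(156.20, 161.28, 160.55, 161.87, 163.43,
       175.29, 169.43, 161.67, 157.32, 162.65)
net <- build_network(x)          # default arc_params(0.5, 0.3, 0.2)
net
#> ARC network: 10 nodes, 19 edges (DAG, left-to-right)
#>   params: alpha = 0.5, beta = 0.3, gamma = 0.2
head(net$edges, 3)
#>   i j    weight      theta  kappa
#> 1 0 1 3.1152862  1.3764311 5.0800
#> 2 1 2 0.7911156 -0.6305778 0.7300
#> 3 1 3 0.5023727  0.2868633 0.5125
round(feature_vector(net), 4)
#> feat_01 feat_02 feat_03 feat_04 feat_05 feat_06 feat_07 feat_08
#> 19.0000 -1.3939  3.6959  0.3106  6.1749  0.3791  0.2832  0.3251
#> feat_09 feat_10 feat_11 feat_12 feat_13 feat_14 feat_15
#> 14.0442  3.8000  0.1139 14.0442  8.9741  0.3793  2.8790
```

The first edge's weight decomposes as
`0.5·|161.28−156.20| + 0.3·1 + 0.2·atan(5.08) = 3.1153`: a large
amplitude step, the maximal temporal-proximity bonus, and a steep chord
angle. `feat_01` is the edge count, `feat_14` (WAII ≈ 0.38) says outgoing
weights vary by ~38% of their mean at a typical node, and `feat_15`
(CBEFI ≈ 2.88) reflects the sharp curvature of this short, spiky
segment.

End-to-end on synthetic data:

```r
cohort   <- generate_cohort(easy_profiles(), subjects_per_class = 10,
                            channels = 2, n = 2000, fs = 500, seed = 1)
features <- extract_features(cohort)
run_experiment(features, task = "AD_FTD_HC", use_aco = TRUE, seed = 1,
               aco = aco_config(n_ants = 10, n_iterations = 15))
#> accuracy 100.00%  sensitivity 100.00%  specificity 100.00%  precision 100.00%  F1 100.00%  (n = 12)
#>   features used: 4 (3, 4, 14, 15)
```

A thin CLI over the same functions lives in `inst/cli/arcnet.R`
(`synth`, `build`, `select`, `run` subcommands).

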