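---
title: "ARC networks for EEG: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ARC networks for EEG: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcnet)
```

## The model

`arcnet` maps a single-channel EEG segment to a directed weighted graph
and classifies dementia subtypes (Alzheimer's disease, frontotemporal
dementia, healthy controls) from graph-level features. Each sample
$x_t$ becomes a node; an edge $i \to j$ ($j > i$) exists under the
**Angle-Relation Connection (ARC) rule** when the chord angle

$$\theta_{ij} = \arctan\!\frac{x_j - x_i}{j - i}$$

strictly exceeds $\theta_{ik}$ for every intermediate $i < k < j$.
Geometrically this is the natural-visibility criterion restricted to the
left-to-right direction: every intermediate sample must lie strictly
below the chord. Adjacent pairs connect vacuously, so the graph always
contains the temporal chain, is connected, and is a DAG. Ties
(collinear points) do **not** connect; strictness is what makes a
constant series reduce to a bare chain.

Each edge carries the composite weight

$$w_{ij} = \alpha\,|x_j - x_i| + \beta\,\frac{1}{j-i} +
  \gamma\,\bigl|\arctan\tfrac{x_j - x_i}{j-i}\bigr|$$

with defaults $\alpha = 0.5$, $\beta = 0.3$, $\gamma = 0.2$ and the
usual exploration ranges $\alpha \in [0.3, 0.7]$, $\beta \in [0.1,
0.4]$, $\gamma \in [0.1, 0.3]$. Time enters in sample-index units, so
weights depend on the amplitude scale relative to the unit sample step
— a consequence we document rather than hide, and why readers carry
units metadata. Absolute values keep weights nonnegative, which the
downstream strength/Gini/efficiency semantics require; signed variants
are available via `arc_params(signed_weights = TRUE)` for sensitivity
checks only. The rendered source of the weighting formula is ambiguous
about where its absolute-value bars sit; we chose the nonnegative
reading and expose the signed one rather than guessing silently.

The builder is the $O(n^2)$ running-maximum sweep (in C++); the literal
$O(n^3)$ transcription `arc_edges_bruteforce()` is kept as a permanent
regression oracle and the chord criterion serves as a second,
independent oracle in the test suite.

## The 15 features

Indices 1–13 are classical: edge count, the four population moments of
the edge-weight distribution (excess kurtosis; skewness and kurtosis of
a zero-variance distribution are defined as 0), the Gini index of the
weights, global efficiency, greedy-partition modularity, weighted
average degree, average degree, average betweenness centrality, average
node strength and average shortest path length. Indices 14–15 are the
geometric indices:

* **WAII** — mean over nodes of the coefficient of variation
  (population SD / mean) of the node's *outgoing* edge weights; nodes
  with out-degree $\le 1$ contribute 0, since the spread of a single
  weight is degenerate (the printed condition "$S_i > 1$" is read as
  out-degree, not mean weight, which would make the index
  amplitude-scale-dependent). WAII is weight-scale invariant.
* **CBEFI** — mean over edges of
  $|x_j - 2x_k + x_i| / (j-i)^2$, $k = \lfloor (i+j)/2 \rfloor$, a
  normalised second difference; time is again in sample units (a global
  $1/f_s^2$ rescaling would not change class contrasts).

Design choices that the formulas alone do not fix:

* Path-based metrics and community detection run on the **undirected**
  weighted view with edge length = raw weight. The ARC digraph is a
  DAG, so directed distances are infinite for half the ordered pairs,
  which would cap efficiency at 0.5 and leave mean path length
  ill-defined; the undirected reading is the one under which the
  formulas' sums over all ordered pairs make sense. WAII alone keeps
  direction. An inverse-weight length is available through the internal
  helpers for sensitivity work but is not the default.
* Modularity needs a partition; the objective does not name an
  algorithm. We use igraph's greedy modularity maximisation
  (deterministic) and report the objective evaluated on that partition.
* Betweenness excludes endpoints and is normalised by
  $(N-1)(N-2)/2$.
* Weighted average degree and average node strength are printed with
  one and the same formula in the source material of this feature
  family; both slots are emitted (indices 9 and 12) so that feature
  indices stay aligned with the canonical 15-entry table.

## Synthetic cohorts

`generate_segment()` builds signal = zero-phase cosines + AR(1)
Gaussian noise + Poisson-placed symmetric triangular spikes.
`noise_sd` is the innovation SD; `ar_coeff` controls smoothness;
triangular spikes create second-difference discontinuities that CBEFI
provably responds to. Seeding is counter-based from the master seed, so
any (subject, channel) cell is reproducible in isolation.

Two profile sets ship as the package's study conditions:

* `easy_profiles()` — HC: 10 Hz (amp 1) + 20 Hz (amp 0.3), AR 0.5,
  SD 0.2; AD: 6 Hz, AR 0.9, SD 0.2 (slowed, smoother); FTD: 10 Hz,
  AR 0.5, SD 0.2, spikes 2/s (amp 3, half-width 5 samples). These
  encode the qualitative contrasts the geometric features are designed
  to detect: oscillatory slowing and reduced curvature in AD, sharp
  transients in FTD.
* `geometry_profiles()` — identical 10 Hz oscillation and noise SD in
  all classes; only AR (0.5 vs 0.95) and spikes differ. This isolates
  the curvature/irregularity axis.

What the generator does *not* emulate: real EEG spectra (1/f
background, band mixtures), artifacts, inter-channel correlation,
non-stationarity, or realistic effect sizes. Passing tests on these
cohorts show the pipeline recovers planted geometric structure; they
say nothing about clinical accuracy on real recordings.

## Selection and evaluation

The ACO wrapper follows the canonical subset-selection colony: uniform
pheromone initialisation $\tau_f = 1$, per-ant subset size uniform in
[4, 8], features drawn without replacement with probability
$\propto \tau_f$, evaporation $\rho = 0.1$, and an iteration-best
deposit $\tau_f \mathrel{+}= Q \cdot \text{fitness}$. No heuristic
desirability term is used — the source material specifies colony size
(30), iterations (50) and the subset range but no pheromone rule, so we
chose the variant with the fewest free parameters. Fitness is the mean
accuracy of a seeded 250-tree random forest over stratified,
subject-grouped 5-fold cross-validation; evaluations are memoised
within a run because ants frequently resample subsets. Selection only
ever sees training data.

Evaluation supports two split modes. `grouped_subject` (default)
assigns whole subjects to one side, matching strict subject-level
separation; `stratified_record` stratifies over rows and reproduces the
80/20-with-shuffling protocol. Binary tasks report the disease class as
positive; the multiclass task reports macro-averaged one-vs-rest
metrics (the averaging scheme is otherwise unstated in the tables this
layout mirrors). Undefined ratios (zero denominators) are reported as 0
and flagged, keeping report tables finite. The RBF-SVM uses C = 1 and
$\gamma = 1/(d \cdot \overline{\operatorname{var}})$ on standardised
features; AdaBoost is SAMME over depth-1 stumps; bagged trees are a
ranger forest with `mtry = p`. kNN and the SVM see z-scored features
(train-fit); tree ensembles see raw columns.

## Numerical conventions and degenerate inputs

* Strict inequality in the ARC condition; ties never connect.
* Series shorter than 2 samples, non-finite values, empty recordings
  and epoched EEGLAB files are rejected with explicit errors.
* Population (1/n) denominators for all weight moments; Gini uses the
  sorted-weights identity to stay $O(m \log m)$.
* Pheromones are floored at $10^{-12}$ so that injected test fitness
  functions with negative values cannot extinguish a feature.
* All randomness (generation, splits, folds, forests, the colony) is
  seeded; the pipeline is a pure function of the master seed and
  configuration. `ranger` predictions are seeded explicitly because its
  vote tie-breaking otherwise consumes the global RNG.

## Test problem sizes

The shipped cohorts used by the acceptance checks are 3 classes × 10
subjects × 2 channels at 2 000 samples (4 s at 500 Hz) — large enough
that the ARC graphs have thousands of edges, small enough that the full
suite runs on one CPU in minutes. The colony used inside the
end-to-end checks is 10 ants × 15 iterations (the reference 30 × 50
configuration is exercised separately); with memoised fitness this
explores a few hundred distinct subsets per run, which is ample on a
15-feature pool.

## Known limitations

* On the geometry-only cohort the classifier fitness saturates: several
  feature subsets reach perfect cross-validated accuracy, so the
  best-ever subset among tied optima is partly arbitrary. CBEFI is
  selected in 100% of repeated colony runs, but WAII is not — classical
  features (edge count, path length, weight moments) co-vary strongly
  with the AR-smoothness contrast and can substitute for it. This is a
  structural property of the feature family on separable synthetic
  data, not a defect of the selector; on harder data with saturation
  broken the frequencies become informative again.
* The 40 s / 20 000-sample default window implies ~$2\times10^8$ pair
  checks per channel in the sweep; this is seconds in the compiled
  path, but the brute-force oracle is only meant for n ≤ 500.
* EEGLAB SET support covers uncompressed MAT v5 files with continuous
  data (including a separate `.fdt` payload); compressed v7 and HDF5
  v7.3 files are rejected with instructions rather than mis-read.
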