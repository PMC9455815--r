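---
title: "SimSpread: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SimSpread: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simspread)
```

## The prediction problem

Given a training network of known drug-target interactions (DTIs) and the
chemical structure of a query compound, SimSpread ranks the network's
targets by how likely the query is to interact with them. Because the query
connects to the network only through chemical similarity, the method makes
*de novo* predictions: the query need not be part of the training network
at all. The working assumption is the similarity-property principle --
structurally similar compounds tend to share bioactivities -- combined with
a network-diffusion formalism borrowed from recommender systems.

## Model

### Feature matrix

Let $S$ be a chemical similarity matrix between compounds (Tanimoto
coefficient over molecular fingerprints by default). The feature matrix
$S'$ thresholds and reweights it:

$$
S'_{ij} = \begin{cases} w(i,j) & S_{ij} \ge \alpha \\ 0 & \text{otherwise,}\end{cases}
$$

where $\alpha \in [0,1]$ is the similarity cutoff and the weighting scheme
$w$ is either *binary* ($w = 1$; `scheme = "binary"`) or *similarity*
($w = S_{ij}$; `scheme = "similarity"`). The threshold is inclusive
($\ge \alpha$), so at $\alpha = 1$ only structure duplicates link.
For bit-vector descriptors the Tanimoto coefficient is
$|A \cap B| / |A \cup B|$; for real-valued descriptors the continuous form
$\sum a_i b_i / (\sum a_i^2 + \sum b_i^2 - \sum a_i b_i)$ is applied after
column-wise min-max normalisation onto $[0,1]$. Two conventions keep the
similarity well defined on degenerate input: $0/0$ similarity (two empty
descriptor vectors) is 0, because an empty fingerprint should never link
compounds, and constant descriptor columns normalise to 0 rather than NaN.

### Network and diffusion

The prediction network has three layers: features F, drugs D and targets T.
In SimSpread the feature layer is a *copy of the training drugs*: the
drug-drug block of $S'$ links F to D, and query compounds attach to F
through their own $S'$ rows. The drug-drug block keeps its unit diagonal
(every drug is similar to itself), which guarantees that a drug dissimilar
to every other drug still reaches its own targets and that resources are
conserved. The D-T block is the binary interaction adjacency.

Scoring is two rounds of degree-normalised resource spreading
(`denovo_spread()`):

1. the query's feature values are placed on F; each F node splits its
   resource over its D neighbours;
2. each D node splits everything it received over *all* its neighbours --
   back to F and forward to T -- with the same division-and-summation rule.

The final T resources are the prediction scores. Under *binary* propagation
each edge gets an equal share (1/degree); under *weighted* propagation
shares are proportional to edge weight, normalised by the node's total
edge weight. Weighted propagation is the natural partner of similarity
weighting and the package default; the two rules coincide on binary
networks, and both conserve total resource exactly (asserted to 1e-12 in
the tests) whenever no resource sits on an isolated node. A query with no
above-threshold neighbour has an all-zero feature vector, receives all-zero
scores, and is flagged as *outside the application domain* -- the method
declines to predict rather than returning noise.

The two baselines reuse the same machinery: SDTNBI replaces the feature
layer with fingerprint substructure bits and uses binary propagation
(`sdtnbi_predict()` delegates to the identical code path, which a test
asserts bit for bit), while classical NBI (`nbi_predict()`) spreads on the
bipartite D-T network alone and therefore only scores drugs already in the
network. The k-NN reference (`knn_predict()`) scores a target by the
maximum (k = 1) or mean top-k similarity between the query and the
target's annotated ligands.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.2 | similarity cutoff for feature edges (unitless, [0,1]); 0.2 is the robust optimum reported for 4096-bit ECFP4 across benchmark datasets, re-derivable with `alpha_sweep()` (grid 0 to 1, step 0.05) |
| `scheme` | `"similarity"` | feature weighting; similarity weighting consistently edges out binary weighting in cross-validation |
| `propagation` | `"weighted"` | resource-splitting rule in the diffusion |
| `descriptor` | ECFP4, 4096 bits | fingerprint for similarity; MACCS/FP2/FP4 available through the same OpenBabel backend, arbitrary precomputed matrices importable |
| `k` (metrics) | 20 | rank cut for precision/recall at k |
| BEDROC `alpha` | 20 | early-recognition decay; distinct from the similarity cutoff of the same name |

A new descriptor family changes the similarity distribution, so the cutoff
should be re-optimised with `alpha_sweep()` before use; real-valued
descriptors typically need much higher cutoffs than bit fingerprints.

## Validation protocols

Four harnesses orchestrate any predictor configuration:

* **`loocv()`** -- drug-wise leave-one-out: all edges of one drug are
  removed, the network rebuilt, the drug scored de novo. Metrics are
  computed per drug.
* **`repeated_kfold()`** -- drug-wise 10-times 10-fold CV (defaults);
  per-fold values are the mean over the fold's evaluable drugs, and the
  per-drug granularity is kept alongside. Whether per-fold values should
  pool rankings or average per-drug metrics is an open convention; this
  package averages per-drug metrics and records both levels so either can
  be summarised.
* **`dti_holdout_kfold()`** -- partitions *interactions* instead of drugs,
  the only scheme NBI can participate in (it cannot score unseen drugs).
  A drug that loses all its edges in a fold is skipped for that fold, and
  a drug's retained training targets are masked during evaluation: they
  are neither novel positives nor fair negatives.
* **`time_split_validate()`** -- trains on an older snapshot and evaluates
  per test drug against strictly newer interactions prepared by
  `time_split()` (shared target panel, previously known edges removed).

Targets disconnected from the training network can never receive resources
and are masked from all metrics. Held-out drugs outside the application
domain are evaluated with their all-zero scores (worst case) *and*
flagged, so summaries can either include or exclude them. A drug whose
evaluable panel lacks a positive or a negative is reported but flagged
non-evaluable, never silently dropped. One integer seed drives every
shuffle (repeat $r$ uses seed $+ (r-1)$), making reports bitwise
reproducible; leakage tests assert that a held-out unit's predictions do
not depend on its own held-out edges.

## Metric conventions

Eight metrics are computed per evaluation unit (`evaluate_ranking()`):
AuROC and AuPRC for overall ranking, BEDROC (decay 20), P@20 and R@20 for
early recognition, and the maxima of MCC, F1 and balanced accuracy over
all decision thresholds for binary performance. Conventions that matter:

* AuROC uses the average-rank (Mann-Whitney) treatment of ties.
* AuPRC is average precision with step interpolation, not a trapezoid over
  PR points, which would be optimistic.
* BEDROC is the exponentially weighted robust initial enhancement
  normalised between its best- and worst-placement values; the test suite
  pins it to a direct-summation oracle.
* P@k keeps the denominator at k even when fewer predictions exist.
* Top-k cuts retrieve only targets with strictly positive scores: a zero
  score means the diffusion never reached the target, i.e. no prediction
  was made, and an unreached target must not be credited as a retrieval.
  Rankings break ties deterministically (score descending, then target ID).
* The threshold sweep for max-MCC/F1/bACC includes the reject-all
  classifier, so balanced accuracy is never reported below 0.5 merely
  because every cut point is bad.

## Synthetic fixtures: what they emulate and what they do not

`generate_clustered_library()` plants chemical series: each cluster is a
random prototype bit vector (density 0.1, a plausible on-bit fraction for
folded fingerprints of drug-like molecules) whose members flip each bit
with probability 0.05. At these defaults the within-cluster Tanimoto
similarity is about 0.47 while between-cluster similarity peaks below the
0.2 default cutoff, so clusters do not link through the feature layer --
the separability is the planted signal. `generate_planted_dti()` gives
every cluster a private block of targets annotated with probability 0.8,
realising an idealised similarity-property world.

The recovery analysis in the acceptance script runs drug-wise LOO on this
planted world (4 clusters x 15 compounds, 256 bits, 5 targets per cluster,
seed 1) and contrasts it against a permutation null in which the *same
trained predictions* are scored against label-shuffled edges -- the
standard way to break the chemistry-target association while leaving the
predictor untouched. Recovering median R@20 of 1.0 versus 0.25 under the
null shows the pipeline finds planted neighbourhood structure; it does
*not* show real-data performance. Real bioactivity data have correlated
fingerprint bits, promiscuous compounds and targets, activity cliffs and
noisy annotations, none of which the generator emulates; external
benchmark behaviour must be measured on external data
(`scripts/external_benchmarks.R`).

`generate_bioactivity_table()` plants per-rule compliance for the
bioactivity filter (activity type in Ki/Kd/IC50/EC50, value < 10 uM,
5 < heavy atoms < 80, phase >= 1, human target) so the expected survivor
count is exact by construction. The bounds are deliberately strict
inequalities -- "<" versus "<=" at 10 uM or 80 atoms silently changes
datasets, so the convention is pinned by tests.

## Numerical and degenerate-input choices

* All diffusion is double precision; conservation and oracle agreement are
  asserted at 1e-12, metric oracles at 1e-10.
* Zero-degree nodes retain nothing and distribute nothing; resource placed
  on them disappears (documented, exercised in tests).
* Empty queries, empty fingerprints and empty scaffolds are legal inputs
  with defined outputs (zero scores, zero similarity, `""`), never errors.
* Murcko scaffolds are computed as the 2-core of the heavy-atom graph
  (iterative terminal-atom pruning leaves exactly rings plus inter-ring
  linkers) plus atoms multiple-bonded to that framework, then
  canonicalised through OpenBabel. Acyclic molecules yield an empty
  scaffold and are excluded from scaffold counts.
* The optional 2-D embedding for space-coverage figures is classical
  multidimensional scaling of Jaccard distances -- deterministic,
  dependency-free, and quarantined to visualisation; no quantitative
  result depends on it.

## Problem sizes

The bundled analyses are desk-scale by design: oracle and conservation
checks use networks of up to ten nodes per layer (100+ random instances),
metric oracles use rankings of up to 40 targets (100 instances), and the
planted-recovery study uses 60 compounds x 20 targets under full LOO.
These sizes keep the whole suite in the tens of seconds while exercising
every code path; the implementation itself is vectorised matrix algebra
and scales to the thousands of compounds and targets of real
drug-repositioning datasets.

## Known limitations

* Only two diffusion rounds are implemented -- the published formalism --
  so signals never travel more than one drug-drug hop.
* The drug-target layer is binary; bioactivity values pass through the IO
  layer but do not weight edges.
* Whether the original weighted variant normalises by weighted or
  unweighted degree in round two is not documented anywhere we could
  verify; both propagation modes are exposed and the choice is recorded in
  every report label.
* Protein-side similarity is out of scope; the feature layer is purely
  chemical.
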