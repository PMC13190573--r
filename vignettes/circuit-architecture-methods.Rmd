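---
title: "Methods: detecting region-intrinsic neurons and classifying their circuit architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting region-intrinsic neurons and classifying their circuit architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitome)
```

## The problem

Synapse-level connectomes of the *Drosophila* central brain make it possible
to ask, for a chosen neuropil, which neurons are *intrinsic* to it — neurons
whose pre- and post-synaptic sites are essentially confined to the region —
and what wiring architecture those neurons realise with the rest of the
brain. Three candidate architectures frame the analysis:

* **labeled line** — each intrinsic neuron relays one dedicated input to one
  dedicated output, forming parallel channels;
* **mixed** — all-to-all connectivity between inputs, intrinsic neurons, and
  outputs;
* **convergence-divergence** — each intrinsic neuron pools many dedicated
  inputs (fan-in) and broadcasts to many outputs (fan-out), so the
  population forms a bottleneck reminiscent of an autoencoder's latent
  layer.

`circuitome` implements the full analysis chain — intrinsic-neuron
detection, connectivity atlas, entropy and motif architecture tests,
multi-layer input tracing, morphological similarity, and subcellular
synaptic topology — together with a seeded synthetic-connectome generator
that plants each architecture with known ground truth, so every stage is
testable without connectome downloads.

## Intrinsic-neuron detection

**Completeness threshold.** Reconstructions mix partially traced fragments
with well-traced neurons. Pooled per-fragment synapse counts are therefore
bimodal, and the package locates the valley of a Gaussian kernel density of
`log10(count + 1)` (Scott's bandwidth, `sd * n^(-1/5)`) between the two
largest modes. The log scale is used because counts span orders of
magnitude. Two guards prevent spurious thresholds: candidate modes must
reach 5% of the peak density, and the valley must dip below 90% of the
smaller mode — otherwise an explicit "no threshold found" result is
returned, never a silent default. A second operationalisation
(`method = "turning_point"`) fits a continuous two-segment linear model to
the log-log count-frequency relation and reports the breakpoint; it exists
because the fragment/neuron boundary is sometimes described as a turning
point of that relation rather than a density valley, and the choice is
recorded in the output.

**Region fractions and the 85% rule.** For each neuron the package computes
the fraction of pre-synaptic, post-synaptic, and pooled synaptic sites
inside the focal region (by default the superior protocerebrum, the union
of SMP, SIP, SLP, and CRE). A neuron is intrinsic when its fraction is
*strictly* greater than 0.85; the boundary case is excluded. Two rules are
provided because the pooled and per-polarity readings are both defensible:
`"both_polarity"` (default; the neuron must clear 85% on the pre side *and*
the post side, i.e. it sits in the high-pre x high-post corner of the
fraction scatter) and `"combined"` (the pooled fraction clears 85%). The
rule and threshold are recorded on the output.

**Type completion.** Because the completeness threshold truncates the
pre-synaptic count histogram near its mode, neurons sharing a cell type
with a selected neuron, passing the fraction rule, and falling below the
pre-synaptic count threshold are added back. Candidates are re-checked
against the fraction rule — the safer choice where re-checking is not
explicitly prescribed — and a user-supplied exclusion list of reported cell
types is removed last.

**Fraction curve.** The binned (5% bins, half-open intervals) mean
post-fraction versus pre-fraction relation is fit with a degree-2
polynomial by ordinary least squares; `R^2 = 1 - SS_res/SS_tot`, defined as
1 when the binned responses have zero variance (a constant is fit
perfectly; the case is flagged).

## Architecture tests

**Entropy.** For each hub the Shannon entropy
`H = -sum(p_i log2 p_i)` of its input (or output) synaptic weight
proportions is computed, with `0 log 0 = 0`; `H` ranges from 0 (one
dominant partner) to `log2 N` (uniform over `N` partners). Three null
models are tested:

1. *labeled line*: `H = 0` for every hub; one-sample t-test of observed
   entropies against 0.
2. *mixed*: uniform weight over each hub's partners, so the deficit
   `H - log2 N` is 0; one-sample t-test of deficits against 0.
3. *shuffled*: partner labels are globally permuted across all hub
   connections, preserving each hub's connection count and weight multiset.
   When a hub draws the same partner twice the weights merge, which is
   exactly how specific wiring differs from a degree-matched random
   assignment. The observed mean entropy is compared to 100 replicates via
   `Z = (H_obs - mu)/sigma` with a two-sided normal p-value.

Degenerate inputs follow explicit conventions rather than erroring:
all-zero entropies give `t = 0, p = 1` (null retained); zero-variance
nonzero values give an infinite statistic with `p = 0` and a flag; a
zero-sigma shuffle distribution gives an undefined, flagged Z that counts
as "not rejected".

**Classification.** The three architectures leave distinct signatures, and
two structural facts force the decision rule the package uses. First, a
labeled-line population has exactly one partner per hub, so `H = 0` *and*
`log2 N = 0`: both point nulls are exactly satisfied and no test can
reject the mixed null on such data — labeled-line circuits are identified
by *failing* to reject the labeled-line null. Second, an all-to-all
population with realistically dispersed (log-normal) weights has strictly
negative deficits, so the mixed t-test rejects even on mixed circuits; the
informative discriminator between mixed and convergence-divergence is the
shuffled null, which is rejected for all-to-all wiring (label collisions
merge weights and depress entropy) but degenerate for dedicated,
non-overlapping partner sets (every permutation of distinct labels leaves
every entropy unchanged). Hence:

* labeled-line null not rejected → `labeled_line`;
* rejected, and shuffled null rejected → `mixed`;
* rejected, and shuffled null not rejected → `convergence_divergence`.

On 100 synthetic brains per architecture (~300 neurons each) this rule
classifies at least 95% correctly at `alpha = 0.01` (the acceptance suite
recomputes this).

**Motif census and significance profile.** Directed triads are counted per
the standard 16-class taxonomy (all permutations of directed edges over 3
nodes, merged by isomorphism); the divergence motif is the one-source/
two-target class (`021D`) and the convergence motif the two-source/
one-target class (`021U`). All 16 classes, including the sparse ones, are
reported so counts always sum to `choose(n, 3)`. Class counts are compared
to a randomised ensemble via `z = (N_real - mean(N_rand))/sd(N_rand)` and
the network significance profile is the unit-norm z vector. The default
randomisation redraws the graph uniformly among simple digraphs with the
same node and edge counts (endpoint reshuffling). Degree-preserving
double-edge swaps are also provided, but they *cannot* serve as the null
for fan-in/fan-out enrichment on bipartite hub circuits: the convergence
and divergence counts there are functions of the degree sequence alone, so
every swap leaves them unchanged and all z-scores collapse to zero. The
scheme in use is always recorded in the output. Edge thresholds are
configuration, defaulting to >= 2 synapses (>= 5 is conventional for
higher-z-resolution reconstructions).

## Connectivity atlas

Hub feature vectors concatenate the upstream and downstream connectivity
blocks, each normalised to the hub's total input/output so blocks sum to 1
(or 0, flagged). Pairwise distances are Bray-Curtis
(`sum|u - v| / sum(u + v)`), a semimetric: the triangle inequality is not
guaranteed, which is documented rather than worked around. Ward
agglomeration on these distances follows the standard Lance-Williams
recurrence (applying Ward to a non-Euclidean dissimilarity is heterodox but
deliberate and recorded); the cut is a fixed `k` or the largest
merge-height gap. UMAP (36 neighbours, min_dist 0.1, 3 components by
default) embeds the Bray-Curtis distances; the optimiser runs
single-threaded so a fixed seed reproduces coordinates bitwise, and a
parameter sweep helper re-embeds over the `n_neighbors` in {24, 32, 40, 48}
x `min_dist` in {0.1, 0.15, 0.2, 0.25} grid and reports cross-run cluster
agreement. HDBSCAN (via scikit-learn; `min_samples = 15` by default)
clusters the embedding, with refused points labelled `-1`. Local density is
the inverse mean Bray-Curtis distance to the 15 nearest neighbours (self
excluded, ties by row order, mean floored at 1e-12 for duplicate rows), and
the 2-D density landscape is a Gaussian KDE with Scott's bandwidth whose
grid integrates to 1 within 2%. Regional preference per hub takes the
larger of the summed input and output percentages per region group, mapped
to CMY (or RGB) channels after clipping to [0, 1]; an all-zero preference
renders white under CMY and black under RGB.

## Multi-layer tracing

Relative connectivity through one intermediate layer row-normalises the
source-to-intermediate counts, column-normalises the intermediate-to-target
counts, and multiplies. The general tracer chains `l + 1` normalised hops
for `l = 0..5` intermediate layers: every hop but the last is the
presynaptic cell's output distribution, and the final hop divides by the
target's *total* input weight over the whole graph. That final-hop choice
makes strengths additive across disjoint source populations (the three
modality channels sum to the pooled strength), which is the property the
modality analysis depends on. "Disynaptic" means one intermediate layer and
"trisynaptic" two; intermediates exclude sources and targets but may repeat
across layers (matrix-product semantics), and the convention is stated in
the output. The measure is aggregate relative path strength, not causal
influence.

## Morphological similarity

Skeletons become dotprops: points plus unit tangents, each tangent the
principal axis of its 5 nearest points (including itself; coincident-point
neighbourhoods fall back to the parent-edge direction). The raw score
accumulates `f(d_i, |u_i . v_i|)` over query points matched to nearest
target points; tangent sign is meaningless, so the absolute dot product is
used. Because trained `log2(p_match/p_rand)` tables are dataset-specific,
the default score function is a smooth surrogate
`f(d, a) = a exp(-d/sigma) - lambda` (sigma 2000 nm, lambda 0.1),
maximised at zero distance and parallel tangents; tabulated score matrices
load from plain text. The similarity matrix is normalised by each query's
self-score and symmetrised by averaging the two directions (diagonal
exactly 1; non-positive self-scores are flagged and excluded). Connectivity
clusters whose intra-cluster similarities significantly exceed their
similarities to everything else (two-sample t-test, intra > inter required)
are accepted as ensembles; cross-dataset matching thresholds each reference
ensemble at the mean minus one standard deviation of its intra-pair
similarities, and a query joins when its mean similarity to the members
reaches that threshold. Hemisphere comparison uses a plane mirror
(an exact involutive isometry); template registration is out of scope.
Downsampling by an integer factor keeps every factor-th node plus the root
and all branch points; on smooth, densely sampled synthetic skeletons the
normalised self-similarity after factor-2 downsampling stays above 0.8 — a
heuristic bound tied to the node spacing being well inside the score
function's distance decay.

## Subcellular topology

Synaptic sites map to the nearest skeleton node (ties to the lower node
id; assignment distances recorded, outliers flagged). Geodesic distances
are cable lengths along the unique tree path. The putative axon initial
segment is a heuristic, flagged as such in every output: walking the
primary neurite (root-to-deepest path by cable length) from the root, the
first branch point whose off-primary subtree is >= 80% pre-synaptic and
holds >= 10% of the neuron's pre-synaptic sites is taken as the branch
point where the axon leaves the primary process. Distance distributions
are grouped by input class and polarity, measured from the detected AIS
for whole-cell analyses or from a branch root for local-branch analyses;
raw distances are always retained and units are configuration (nm
internally), never hard-coded. The proximal-bias comparison is a
median-difference permutation test (two-sided, ties counted as
exceedances, so the test is conservative and its type-I rate is controlled
— the published comparisons are visual overlays, so this statistic is this
package's quantitative stand-in and is declared as such).

Two dendrogram layouts support the figures. The force-directed layout uses
the spring-electrical model — repulsion inversely proportional to
distance between every vertex pair, attraction proportional to the squared
distance between neighbours — minimised by moving vertices along their net
force with an adaptive step that is accepted only when the system energy
(sum of squared net-force magnitudes) decreases, so the recorded energy
trace is non-increasing by construction. The ranked layout assigns each
node a vertical rank (topological depth, or geodesic distance quantised by
a step), splits edges spanning multiple ranks with virtual nodes, and
orders nodes within ranks by iterated barycenter sweeps, reporting the
crossing count.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions:

* **Architectures**: labeled-line assigns each hub one dedicated upstream
  and downstream partner (disjoint across hubs); mixed connects every
  input to every hub and every hub to every output; convergence-divergence
  gives each hub `fan_in` dedicated upstream and `fan_out` dedicated
  downstream partners, drawn without replacement from a shuffled pool with
  round-robin overflow, so exclusivity is exact rather than probabilistic.
  Edge weights are i.i.d. log-normal with median 5 and sigma_log 1, so the
  conventional >= 2 and >= 5 edge thresholds remove a realistic minority
  of edges. The acceptance-scale brains use 100/100/100 neurons
  (labeled-line, mixed) and 20 hubs x 8 fan-in x 7 fan-out (~320 neurons,
  convergence-divergence).
* **Fragments**: pre- and post-synaptic counts per neuron from two
  log-normals with modes near 300 (well-traced) and 8 (fragments); mode
  separation below a configurable factor flags the output.
* **Intrinsic populations**: per-neuron in-region fractions drawn
  uniformly from (0.88, 0.99) for intrinsic and (0.05, 0.75) for
  extrinsic neurons, with in-region site counts rounded up (intrinsic) or
  down (extrinsic) so realised fractions respect the strict 85% boundary
  exactly; fraction laws touching the boundary are rejected.
* **Skeletons**: binary trees grown segment by segment (uniform segment
  lengths 8-20 um, 1 um node spacing, direction persistence 0.9 for
  locally smooth neurites); `b` branch events give exactly `b + 1` leaves.
  Synapse placement weights each node by its incident cable share times
  `exp(-+ bias x normalised root distance)`; bias 0 is exactly uniform.
* **Whole brains**: architecture edges are expanded to one row per
  synaptic site; hub sites are labelled in-region per polarity so both
  fraction rules recover exactly the planted hubs, and non-hub neurons
  receive out-of-region background sites diluting them to <= 80%.
  Transmitter labels are drawn per role with an inhibitory/modulatory
  majority among hubs.

All generators are deterministic per seed. What passing tests on these
brains shows is that the pipeline recovers structure *of the kind the
analysis assumes* — exact fraction boundaries, exactly dedicated or
all-to-all wiring, unimodal placement biases. Real connectomes add
reconstruction noise, boundary-straddling synapses, partner overlap between
hubs, and non-stationary region geometry, none of which the generator
imitates; results on real data therefore need the dataset-specific
thresholds and curation the interfaces expose.

## Numerical choices and limitations

* Problem sizes in the tests and acceptance runs — 100 seeds per
  architecture at ~300 neurons, 50 clustering seeds, 5,000-count threshold
  estimation, 999-permutation bias tests — were chosen as the smallest
  scales at which the stochastic criteria are stable.
* Ties: nearest-node assignment breaks toward the lower node id; k-NN
  neighbour ties break by row order; HDBSCAN labels are canonicalised by
  first appearance, and borderline points may legitimately change
  assignment under reordering.
* Zero-variance t-tests, all-zero feature rows, duplicate rows in k-NN
  density, degenerate KDE inputs, and undefined shuffle Z-scores all
  return flagged results rather than raising.
* The AIS rule is one operationalisation of a verbal convention; outputs
  carry a `heuristic` flag.
* Ward-on-Bray-Curtis lacks the variance interpretation that justifies
  Ward on Euclidean distances; it is retained deliberately for
  comparability and documented.
* The pipeline consumes transmitter labels; predicting them, single-cell
  expression analyses, template-space registration, and mesh/EM rendering
  are out of scope.
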