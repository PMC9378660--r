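---
title: "Shape graphs and hub-mediated transition dynamics: methods"
author: "brainmapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape graphs and hub-mediated transition dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainmapper)
```

## The problem

Resting-state fMRI recordings sampled densely within individuals make it
possible to ask how the brain moves between whole-brain activity
configurations over time, at the resolution of single time frames (TRs),
without sliding windows and without presupposing a fixed number of mutually
exclusive states. `brainmapper` implements a topological data analysis view
of this question: each retained time frame of a parcellated recording
(frames x parcels matrix) is a point in parcel space, and the Mapper
algorithm summarises the point cloud as a *shape graph* whose nodes are
small clusters of frames and whose edges mark shared frames. Topologically
central, highly connected nodes ("hubs") are candidate transition states;
annotating nodes with resting-state network (RSN) activation and
propagating node labels back to frames yields a discrete state sequence
from which a Markov chain of transitions is estimated.

## The Mapper pipeline

Four steps, composed by `runMapper()`:

1. **Filter.** Pairwise Euclidean distances between z-scored frames are
   converted to geodesic distances over a k-nearest-neighbour graph
   (directed k-NN, symmetrised by union, edge weight = input distance,
   all-pairs shortest paths), then embedded into `d = 2` dimensions by
   classical multidimensional scaling. This is the Isomap construction: the
   k-NN geodesics capture the intrinsic, possibly nonlinear geometry of the
   cloud, and the MDS step embeds it while preserving those distances. The
   cited description of the filter — geodesic distances followed by a
   distance-preserving Euclidean embedding — does not pin down one specific
   algorithm; Isomap is the minimal method matching it, and `k` (default
   20) is exposed in `mapperConfig()`. If the k-NN graph is disconnected we
   bridge components with the single minimum-distance inter-component edge
   per merge (the standard Isomap repair), with a warning.
2. **Cover.** The 2-D embedding is covered by overlapping rectangular bins:
   per axis, the bounding box (expanded by `1e-9` so extreme points are
   interior) is split into `R` base intervals of width `w0`, and bin `j`
   spans `[min + j w0 - h, min + (j+1) w0 + h]` with
   `h = (G/100) w0 / 2`, so adjacent bins share an overlap region equal to
   `G` percent of the base width. Mapper implementations differ in how
   "percent overlap" is parameterised; this dialect is stated explicitly so
   the numbers are unambiguous. Defaults `R = 30`, `G = 70`.
3. **Partial clustering.** Within each bin, single-linkage clustering on
   the *original* high-dimensional distances, cut at the first empty bin of
   a 10-bin histogram of merge heights (the classic Mapper heuristic).
   If no empty bin exists the bin stays one cluster; singletons stay
   singletons. Ties and orderings are fixed deterministically (clusters
   ordered by smallest member, nodes by bin then cluster), so graphs are
   byte-reproducible.
4. **Graph.** One node per cluster; nodes are connected iff they share at
   least one frame. Clusters partition each bin, so edges only arise
   between bins.

### Preprocessing

`prepareForMapper()` applies the conventional order: per-session column
z-scoring (sample SD, `n - 1` denominator), session concatenation with
boundary bookkeeping, then removal of censored (artifact-flagged) frames.
Censoring and stitching make some consecutive retained frames
non-contiguous in real time; those positions are carried as `breaks` and
excluded later from transition counting, so the Markov chain never sees
phantom adjacency. Whether z-scoring should happen per session or after
concatenation is not fully determined by convention; per-session scoring is
used here (it is what "harmonising across sessions" requires) and the
choice is isolated in one function for sensitivity analysis.

## Topological characterisation and hubs

Degree is the row sum of the binary adjacency. Closeness centrality of node
$i$ is $C_C(i) = (N-1) / \sum_{j \ne i} l_{ij}$ with unit edge weights. On
disconnected graphs the formula is applied within each connected component
(component size as $N$), and by default the value is additionally scaled by
the component's node fraction $(n_c - 1)/(N - 1)$ (Wasserman–Faust). The
scaling is the identity on connected graphs; without it every two-node
component scores a perfect 1, and because desk-scale shape graphs contain
many small components, the top closeness quantile would consist entirely of
dyads and the hub definition below would be unsatisfiable. The raw
within-component variant is available via `scaled = FALSE`.

A **hub** is a node with degree above a cutoff *and* closeness in the top
1% over all nodes (ties at the quantile included). The cutoff is 20 by
default; 21 is a documented alternative for the same analysis, selectable
via `degreeCutoff` — both appear in the literature for this analysis and we
do not guess which was intended. The tail statistic compared against null
models is the proportion of nodes with degree > 20.

## Annotation, state labels, transitions

Network mean signals (mean over each network's parcels, column z-scored)
are thresholded at 0.5 SD to call a network "active" in a frame.
`annotateNodes()` stores, per node, the fraction of member frames with each
network active (pie-chart proportions), the mean activation, and the SD of
mean activation across networks. Uniformly engaged nodes — the hub
phenotype — have low SD; single-network nodes have high SD, producing the
topographic gradient from periphery to centre.

`assignDominant()` labels hub-flagged nodes `HUB` and every other node with
the argmax of mean activation ("dominance" is a visual notion in pie-chart
displays; argmax of the node mean is the operationalisation here, with a
proportion-based variant by flag; exact ties go to the lowest network
index, logged). `labelFrames()` propagates node labels to frames by
majority over the nodes containing the frame — the propagation rule for
frames in several nodes is underdetermined, so majority with a HUB-favouring
tie-break was chosen, logged, and kept deterministic. `estimateChain()`
counts transitions over valid consecutive pairs only and row-normalises;
observed states with no outgoing valid pair get a uniform row (with a
warning) so matrices remain comparable across subjects.

## Null models

Two linearity-preserving surrogates, 25 instances per recording by
convention (`generateEnsemble()`, instance `i` seeded `seed + i`):

- **Phase randomisation**: FFT per column, one common random phase vector
  added to all columns (the multivariate scheme that preserves lagged
  cross-covariance as well as each column's amplitude spectrum), conjugate
  symmetry enforced, DC and Nyquist left real. An independent-phase variant
  exists behind a flag but breaks cross-column structure.
- **VAR(p)**: ordinary least squares on the stacked lagged regression
  (default `p = 1`), simulation with Gaussian innovations drawn from the
  fitted residual covariance, burn-in of 500 frames, initial state drawn
  from data rows. Unstable fits and non-PSD covariances are warned about
  and repaired (nearest-PSD eigenvalue clipping).

## The synthetic generator

No generative model is prescribed for this analysis by its sources, so the
generator is the package's own design and its defaults define the study
conditions used by the tests. It plants exactly the structure the pipeline
claims to detect: a latent Markov chain over one hub state plus
`nNetworks` peripheral states. Peripheral state $s$ elevates the parcels of
network $s$ by `amplitude` (z-scale, baseline 0 elsewhere — matching the
0.5 SD activation convention); the hub elevates nothing. From every
peripheral state the hub receives `peripheralToHubProb`, the rest of the
off-diagonal mass spread uniformly; dwell times come only from the diagonal.
Observation noise is AR(1) (`smoothingRho`, default 0.3) as a proxy for
haemodynamic autocorrelation — no HRF convolution, no spatial smoothness,
no motion model. Censoring is i.i.d. Bernoulli per frame; bursts are left
to a config extension.

Defaults, chosen once to be desk-scale but realistic: 6 networks x 30
parcels (Gordon-atlas-like parcel counts per network), 2 sessions x 500
frames, `hubSelfProb = 0.5`, `peripheralSelfProb = 0.5`,
`peripheralToHubProb = 0.3`, `amplitude = 1.5`, `noiseSd = 1`,
`censorFraction = 0.1`. Two of these deserve comment. *Parcel count*: with
few parcels (low dimension), pairwise frame distances fluctuate so much
relative to their mean that planted state geometry is unrecoverable by any
clustering — distance concentration requires a realistic parcel count, and
~180 parcels gives between-state distance contrasts of 15–30%.
*Amplitude*: 1.5 SD puts single-network activation comfortably above the
0.5 SD threshold while leaving labelled-frame accuracy well below ceiling,
so the tests exercise a noisy but solvable regime. What passing tests show
is that the pipeline recovers planted hub-mediated structure under
autocorrelated Gaussian noise; real BOLD data differ (haemodynamics,
non-Gaussian artifacts, spatially structured noise, non-mutually-exclusive
network activity), so these are verification conditions, not a claim about
biology.

## Numerical choices and degenerate inputs

- z-scoring uses the sample SD; constant columns are rejected by index.
- MDS signs are fixed (largest-magnitude coordinate per axis positive);
  fewer than `d` positive eigenvalues pads with zeros and warns.
- Cover: `G = 0` uses half-open intervals so each point lies in exactly one
  bin; degenerate (zero-range) axes collapse to a single bin.
- Clustering histogram spans `[min(h), max(h)]` of the merge heights; equal
  heights mean no gap, hence one cluster.
- All-censored recordings, empty networks, ragged TSVs, unknown metrics and
  invalid probabilities are rejected with specific messages.
- Every stochastic step takes an explicit seed; equal seeds give
  bit-identical outputs.

## Problem sizes used by the checks

The packaged verification runs use 1000-frame recordings (the generator
default) for the parameter sweep (11 x 11 = 121 resolution/gain cells),
the real-versus-surrogate fat-tail comparison (10 runs x 25 phase
surrogates each) and the 4-subject cohort reliability analysis, and
5000-frame recordings for end-to-end hub detection and transition recovery
(transition-matrix recovery is asserted at >= 5000 valid transition pairs,
where the max-abs sampling error of a 7-state chain sits near the 0.05
bound; it is therefore checked as a median over three seeds). The
hub-as-top-destination property is asserted on the transition matrix
averaged over three independent recordings, matching the group-average
form in which that claim is naturally made; per-recording chains vary, and
in roughly half of single runs one peripheral state beats the hub from
some origin (see the limitation below).

## Known limitations

- The filter is Isomap-like by construction; other neighbourhood
  embeddings (LLE, UMAP, diffusion maps) would satisfy the same verbal
  description and may shape the landscape differently.
- Closeness-based hub detection depends on the component-fraction scaling
  discussed above whenever the graph fragments; on well-connected graphs
  the choice is immaterial.
- The co-localization similarity uses node-level mean activations
  (amplitude language); a proportion-based variant is provided because the
  node-level definition is not uniquely determined.
- `d` is fixed at 2 by default for interpretability; nothing in the code
  requires it.
- Six mutually equidistant peripheral clusters (the generator's orthogonal
  state templates) cannot be embedded isometrically in 2-D: classical MDS
  of the hub-and-spoke geodesic geometry tends to relieve strain by
  placing one peripheral cluster near the origin, where it absorbs part of
  the hub cluster's frames during labelling. This depresses hub-state
  occupancy relative to ground truth and is the main source of
  run-to-run variability in single-recording transition matrices; real
  resting-state networks are not equidistant, so the severity on real data
  will differ.

## A worked miniature

```{r example, eval = FALSE}
x <- simulateDataset(syntheticConfig(seed = 1))
res <- mapperPipeline(x)
pipelineReport(res)
```
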