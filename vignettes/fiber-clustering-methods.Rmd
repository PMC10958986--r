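---
title: "Self-supervised fiber clustering: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised fiber clustering: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-brain diffusion MRI tractography produces hundreds of thousands of
streamlines ("fibers"), each an ordered polyline of 3-D points in world
millimetre coordinates. To make this useful, tractography is *parcellated*:
fibers with similar trajectories are grouped into clusters that, across
subjects, correspond to the same anatomical pathways. Three properties of
tractography data shape the method implemented here:

* **orientation is arbitrary** — a streamline may be stored starting from
  either end, so any distance or representation must be insensitive to point
  order;
* **pairwise distances are expensive** — the classical minimum average
  direct-flip (MDF) distance is accurate but quadratic in the number of
  fibers;
* **outliers are endemic** — false-positive streamlines with implausible
  shapes contaminate every tractogram.

`fibercluster` embeds each fiber with a neural network so that Euclidean
distances between embeddings approximate MDF distances, clusters the
embeddings with a Student's-t soft assignment that can be modulated by
gray-matter anatomy, and removes outliers by a cluster-adaptive probability
threshold. The trained model (an "atlas") is reusable: new subjects are
parcellated by a single forward pass plus nearest-centroid assignment,
giving cluster correspondence across subjects for free.

## Fiber representation and the along-fiber graph

Fibers are arc-length resampled to `np = 14` points (`resample_fiber()`),
the resolution at which the network operates; the length filter
(`filter_by_length()`, 40 mm, strict `<`) runs before resampling on the
original geometry. Full-resolution anatomical point labels are preserved
alongside the downsampled geometry, so profile and Dice computations do not
lose regions touched between resampled points.

Each fiber is treated as a point cloud with a fixed graph: point *t* is
connected to its `k = 4` sequence-nearest indices (interior: *t±1, t±2*;
ends: the nearest valid indices). The graph is identical for every fiber —
only the node features (coordinates) differ. Note a symmetry that matters:
for **even k** the neighbourhood structure maps onto itself under point-order
reversal. Combined with max aggregation, this makes the encoder *exactly*
flip-invariant — `encode(flip_fiber(f)) == encode(f)` to the last bit — which
is the architectural counterpart of MDF's flip minimisation. Odd `k` breaks
the tie between *t−(k+1)/2* and *t+(k+1)/2* asymmetrically and loses the
exact identity, so the default stays even.

## The encoder and the pretext task

The encoder is a stack of five edge-convolution layers: for each directed
edge (t, u) the layer applies a shared linear map to
`[x_t ; x_u − x_t]` followed by a LeakyReLU (slope 0.2), and aggregates over
the neighbours of *t* by elementwise maximum. The per-layer outputs are
concatenated, passed through a pointwise global descriptor, max-pooled over
points, and mapped by a three-layer fully connected head to an `n_e = 10`
dimensional embedding.

Channel widths default to (16, 16, 24, 24, 32) with a 96-wide descriptor and
a (64, 32, 10) head. These are deliberately small: the package targets
single-CPU training, the desk-scale schedule below fits in minutes, and on
the reference synthetic scene the pretext regression still reaches a
held-out Pearson correlation of ~0.998 — the map from 14-point fiber
geometry to MDF is not a capacity-hungry problem. All widths are
configurable (`encoder_config()`). No normalisation layers are used: the
network is small, He initialisation plus Adam train it stably, and omitting
batch statistics makes every forward pass exactly deterministic.

Training is self-supervised (`pretrain()`): each iteration draws 256 random
fiber pairs (partner resampled every iteration, never the fiber itself),
computes their MDF distance as the pseudo-label, and minimises the mean
squared error between the embedding-space Euclidean distance of the pair
(the Siamese head — one shared parameter set, hence exact symmetry) and the
pseudo-label. The desk-scale schedule is 2000 iterations at learning rate
1e-4 plus 200 at 1e-5; a paper-scale schedule (50k + 1k, 1024-fiber batches)
is available behind `--paper-scale` / the schedule arguments. The backward
pass and Adam are implemented in C++ (RcppArmadillo) and verified against
finite differences in the test suite.

## Clustering stage

k-means (k-means++ seeding, Lloyd iterations) on the pretrained embeddings
initialises `nc` centroids. Soft assignments use the Student's-t kernel with
one degree of freedom,

  q_ij = (1 + ||z_i − mu_j||^2)^−1 / Σ_j' (1 + ||z_i − mu_j'||^2)^−1,

and the self-training target sharpens them: p_ij ∝ q_ij² / f_j with soft
frequencies f_j = Σ_i q_ij, rows renormalised. The clustering loss is
KL(P‖Q) averaged over fibers, and the total loss is L = Lp + λ·Lc with
λ = 0.1; the distance-prediction loss is retained so the embedding geometry
stays anchored to fiber space. Encoder parameters and centroids are trained
jointly by one Adam optimizer; the KL gradients with respect to embeddings
and centroids are the standard deep-embedded-clustering expressions
2·w_ij·(p_ij − q_ij)·(z_i − mu_j).

Every `profile_update_interval` (default 200) iterations the full-data Q and
P are recomputed. Two refresh-time updates deserve explanation:

* **Centroid re-anchoring.** The pretext loss constrains only *pairwise*
  distances, so the embedding cloud has a free global translation and drifts
  during fine-tuning, while Adam-limited centroid steps (≈ lr per iteration)
  cannot follow. Left alone, centroids end several millimetres off the
  cluster mass and the maximum assignment probability q_m loses its meaning
  as a membership score. At each refresh the centroids are therefore reset
  to the soft cluster means (a soft k-means M-step); between refreshes they
  remain ordinary trainable weights. The update is skipped when λ = 0 so
  that ablating the clustering loss leaves centroids untouched.
* **Profile refresh.** When anatomy is in use, hard labels are recomputed
  with the anatomically informed assignment and both profile tables are
  rebuilt from them.

### Anatomically informed assignment

When an anatomical region volume and a cortical parcel volume are supplied,
each fiber carries (a) the set of regions its full-resolution points
traverse and (b) the parcels nearest to its two endpoints. Per cluster, the
*tract anatomical profile* is the set of regions traversed by strictly more
than 40% of members, and the *tract surface profile* maps each parcel to the
fraction of member endpoints terminating there. The assignment then weighs
each cluster by

  q_ij ∝ [(1 + ||z_i − mu_j||²) · (1 − Da_ij) · (1 − Dc_ij)]^−1,

where Da is the Dice overlap between the fiber's region set and the
cluster's anatomical profile and Dc is the sum of the cluster's surface
profile fractions over the fiber's endpoint parcels. Fibers that share a
cluster's anatomy are pulled towards it; fibers that contradict it are
pushed away.

Each (1 − D) factor is floored at ε before inversion. The default is
**ε = 0.1**, i.e. a perfect anatomical agreement boosts a cluster's weight
by at most 10× per factor. A much smaller floor looks harmless but is not:
with ε = 1e-3 a fiber with perfect Dice receives a 1000-fold boost, the
quantised Dice values (sets are small, so Dice moves in steps) dominate the
assignment probability, and the *ranking* of q_m within a cluster — which
the outlier rule below depends on — no longer reflects geometry. On the
reference scene this costs planted-outlier recall (0.82 vs 0.96 at matched
removal fractions) while ARI is unaffected. With all-zero agreement scores
the expression reduces exactly to the geometric kernel, which is also the
inference fallback for unlabelled data. During training the KL loss is
computed on the geometric Q (it stays smooth; the set-valued Dice factors
are not differentiable and are treated as constants refreshed with the
profiles), while the anatomical assignment governs hard labels and
profiles; at inference the anatomical form is used whenever labels are
available.

## Outlier removal

After assignment, each fiber's maximum probability q_m is compared with a
cluster-specific threshold T_c = m_c − n·s_c, where m_c and s_c are the mean
and sample standard deviation (N−1 divisor; singletons get s_c = 0) of q_m
over the cluster's members, and n is a user hyperparameter (default 1).
Fibers strictly below T_c are flagged; they remain in the assignment record
but are excluded from metrics and written outputs. The flagged set shrinks
monotonically in n. `match_outlier_fraction()` scans n to hit a target
removal fraction, the natural way to set n when an expected contamination
level is known (as with the planted outliers of the synthetic scenes).

## Parcellation metrics

* **DB index** — (1/n) Σ_k max_{i≠j} (α_i + α_j)/d(c_i, c_j) with α the mean
  within-cluster pairwise MDF and d the MDF between *centroid fibers* (the
  member minimising mean MDF to the rest; ties to the lowest index). Lower
  is better. For large clusters α is estimated on a seeded subsample of at
  most 300 members (configurable; exact mode available); the test suite
  checks exact agreement with a brute-force oracle on small instances.
* **WMPG** — fraction of atlas clusters with strictly more than 20 assigned
  fibers (a cluster with exactly 20 does not count).
* **TAPC** — per cluster, the mean Dice between member region sets and the
  cluster profile; subject score is the unweighted mean over non-empty
  clusters.
* **TSPC** — per cluster, the mean surface-profile fraction over all parcels
  intersected by the cluster's endpoints (the literal all-intersected
  reading; no fraction cutoff), averaged over clusters with at least one
  labelled endpoint.

All metrics exclude outlier-flagged fibers and are invariant to fiber order
and to flipping any fiber.

## The synthetic scene generator

`generate_scene()` builds ground-truthed tractography at brain scale:
bundle centerlines are natural cubic curves through four randomized control
points in a 150 mm cube, rejected until all pairwise centerline MDF
distances exceed 20 mm and endpoint zones are disjoint; fibers are splines
through control points jittered by isotropic N(0, 1 mm²); half the fibers
are stored point-reversed (orientation is arbitrary in real tractography);
5% are planted outliers whose two interior control points are kicked 20 mm
in random directions (kinked fibers of distinctly different shape, ~5× the
within-bundle spread in MDF terms, with endpoints left near the bundle's
cortical zones — deliberately the hard case where only shape, not
termination, betrays the outlier). A slab label volume (five 30 mm z-slabs,
2 mm voxels) gives each bundle a known region set; a parcel volume labels a
6 mm sphere at each bundle endpoint with a unique parcel id, so a perfectly
parcellated cluster has a 50/50 surface profile and a TSPC optimum of 0.5.

What the generator does *not* emulate: crossing-fiber ambiguity, partial
voluming, scanner noise, subject variability, or the heavy-tailed cluster
size distribution of real tractograms. Passing the recovery tests therefore
shows that the machinery is correct and well-conditioned, not that the
defaults are tuned for clinical data.

Defaults of the reference scene (10 bundles × 200 fibers, jitter 1 mm,
separation ≥ 20 mm, 5% outliers at 20 mm) were chosen once as a
well-separated, realistically sized desk-scale stand-in for whole-brain
training sets; the problem sizes in the test suite (2000 fibers, nc = 10,
2000 + 200 iterations per stage) are the package's reference conditions for
CPU runs.

## Numerical choices and degenerate inputs

* MDF sums are accumulated in a reversal-symmetric pairing, so
  `mdf(a, flip(b)) == mdf(a, b)` holds *bit-exactly*, not just to tolerance.
* Resampling uses arc-length parameterisation of the piecewise-linear curve;
  endpoints are always retained; zero-length fibers are an error.
* Hard-assignment ties break to the lowest cluster index; nearest-parcel
  ties to the lowest parcel id; centroid-fiber ties to the lowest member
  index. All deterministic.
* KL evaluation clamps q at 1e-12; target-distribution columns with zero
  frequency are dropped for the batch and rows renormalised.
* TRK reading applies the voxel-to-RAS affine with the TrackVis half-voxel
  origin convention (world = A·(p/voxel_size − 0.5)); an all-zero stored
  affine is treated as identity. TRK/TCK store float32, hence the 1e-4 mm
  round-trip contract.
* Every stochastic step (weight init, pair sampling, k-means seeding, scene
  generation, DB subsampling) is seeded; two runs with the same
  configuration and seed produce bit-identical atlases.

## Known limitations

* The cortical "surface" is approximated by the nonzero voxels of the
  parcel volume; no mesh is consulted.
* With few, widely separated clusters the Student's-t probabilities
  saturate near 1, so *absolute* q_m values are uninformative — only the
  within-cluster ranking (which the outlier rule uses) carries signal.
* The desk-scale schedule is sized for thousands of fibers and tens of
  clusters; paper-scale data (10^6 fibers, 800 clusters) requires the
  paper-scale schedule and considerably more compute.
* Embedding dimensionality, widths, and the absence of normalisation layers
  are pragmatic defaults declared in `encoder_config()`, not values
  inherited from any reference implementation.
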