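---
title: "Soft parcellation of functional connectivity with fuzzy c-means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft parcellation of functional connectivity with fuzzy c-means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmparc)
```

## The model

`fcmparc` partitions resting-state BOLD data into functional networks by
soft clustering. Each in-mask voxel $k$ is represented by its Pearson
correlation with every other voxel — row $X_k$ of the $n \times n$
correlation map — so that clustering operates on whole-brain connectivity
profiles rather than raw time courses. Fuzzy c-means (FCM) assigns every
voxel a graded membership $u_{ik} \in [0,1]$ in each of $c$ clusters,
$\sum_i u_{ik} = 1$, by alternating

$$u_{ik} = \left[\sum_{j=1}^{c}
  \left(\frac{\lVert X_k - V_i\rVert}{\lVert X_k - V_j\rVert}\right)^{2/(M-1)}
  \right]^{-1},
\qquad
V_i = \frac{\sum_k u_{ik}^M X_k}{\sum_k u_{ik}^M},$$

with Euclidean distance throughout. Convergence is monitored with the
Xie–Beni index (compactness over separation),

$$XB = \frac{\sum_i \sum_k u_{ik}^M \lVert X_k - V_i\rVert^2}
            {n \cdot \min_{i \neq j} \lVert V_i - V_j\rVert^2},$$

and the iteration stops once the index changes by less than $10^{-4}$ on
five consecutive iterations. Graded membership is the point of the
method: cortical and subcortical territory genuinely shared between
networks is expressed as split weights rather than forced into one
label.

Soft partitions are compared with normalized inner products: *spatial
similarity* between two membership vectors (optionally after mean
centering, which is what allows negative values between nonnegative
weight maps) and *temporal similarity* between two centroid vectors.
With correlation-map features the centroids live in correlation space,
not literal time-course space; their inner product measures how
similarly two clusters relate to the rest of the brain, and is strongly
negative for the two anticorrelated systems. Both readings of the
centroid similarity are documented here because the clustering space
makes the time-course interpretation unavailable; correlation space is
the implemented default.

Cluster number selection uses the cluster dispersion

$$CD = \frac{\sum_i \sum_k u_{ik}^M \lVert X_k - V_i\rVert^2}
            {\sum_k \lVert X_k - \bar{x}\rVert^2},$$

whose denominator is the numerator of the single-cluster solution, so
$CD(c{=}1) = 1$ identically and lower is better. Interior strict local
minima of the curve over $c$ are reported, not adjudicated: several
scales of a hierarchy can be simultaneously meaningful.

Voxelwise classification uncertainty is the geometric mean of a voxel's
weights, $CU_k = (\prod_i u_{ik})^{1/c}$, computed through the mean of
logs with a zero-weight short circuit. By the AM–GM inequality
$CU_k \le 1/c$ with equality only at uniform memberships.

## Parameters and defaults

* **Fuzzifier `m = 1.2`** (unitless, $> 1$). Near-crisp clustering that
  still exposes shared-membership voxels; as $m \to 1^+$ the argmax
  memberships coincide with hard k-means (this limit is exercised in the
  test suite at $m = 1.05$).
* **Convergence `tol = 1e-4`, `patience = 5`** on the Xie–Beni index,
  plus a `max_iter = 1000` cap so a pathological plateau cannot loop
  forever; the cap is an addition beyond the stopping rule itself.
* **Initialization.** Random mode: each centroid is the mean feature row
  over a random axis-aligned cube of 3 voxels per dimension (duplicates
  redrawn). Seeded mode: the mean feature row over in-mask voxels within
  a 5 mm radius sphere around stereotaxic ROI coordinates;
  `rsn_seed_table()` ships one canonical seed per resting-state network
  for $c = 7$ (DMN precuneus, FPC right DLPFC, LAN left STG, VAN right
  MFG, SMN left parietal operculum, VIS superior occipital, DAN right
  FEF).
* **Consensus `n_runs = 20`.** Random-initialization results are averaged
  over matched runs. Alignment is an optimal one-to-one assignment on raw
  spatial similarity; the alignment reference is the converged run with
  the lowest objective $J_M$, so that a reference stuck in a poor local
  optimum cannot corrupt the average. Membership matrices are averaged
  entrywise (column sums stay 1) and centroids recomputed from the
  averaged memberships.
* **Preprocessing.** Fixed order: per-run linear detrending; zero-phase
  2nd-order Butterworth low-pass at 0.1 Hz (bidirectional pass, unit DC
  gain; the filter form itself is a design choice, since only the cutoff
  is standard); OLS regression of an intercept, any supplied nuisance
  regressors, and optionally the global (in-mask mean) signal; DVARS
  frame censoring; Pearson correlation over retained frames.
* **DVARS threshold 0.5 %** of the mode-1000 intensity scale, strict
  inequality: frames at exactly 0.5 % are kept. DVARS is the RMS over
  voxels of the frame-to-frame difference divided by 10. The default
  censors the frames whose backward difference exceeds the threshold —
  exactly two frames for an isolated spike; `censor_preceding = TRUE`
  additionally drops the frame before each corrupted transition. The
  global-signal regressor's temporal derivative is not included, and
  censoring follows filtering, matching the stage order above; neither
  choice is forced by the method and both are stated here because they
  are occasionally done differently.

## The synthetic generator

`simulate_bold()` draws from a linear factor model
$x_v(t) = \sum_i w_{vi}\, s_i(t) + \lambda_v\, g(t) + \sigma\,
\epsilon_v(t) + 1000$: iid standard-normal network signals $s_i$, one
shared system signal $g$ entering with opposite sign for the
task-negative and task-positive systems, white noise, and a constant
offset realising the mode-1000 convention. The factor model was chosen
because it has a closed-form expected correlation matrix
(`expected_correlation()`), which serves as an analytic oracle for every
downstream stage. Networks occupy contiguous cuboids on a 3-D grid so
cube-based initialization is meaningful.

Default condition: seven networks (three task-negative, four
task-positive), 100 voxels each, 300 frames at TR 2.16 s,
`loading_within = sqrt(0.5)` and `noise_sd = sqrt(0.5)` (within-network
correlation near 0.5), `loading_system = 0.35`, and `fuzzy_fraction =
0.1` of voxels per network with loadings split 50/50 with a partner
network. The system loading was calibrated so the within-system
between-network centroid similarities of a seven-cluster solution fall
in the high-positive range reported for real data while the two-system
centroids are strongly anticorrelated. The default `fuzzy_pairing =
"cross-system"` places shared voxels between the two systems — on real
data, uncertainty concentrates on networks weakly associated with
either system — and gives those voxels zero net system drive;
within-system pairing is available.

What the generator does **not** emulate: hemodynamic response shapes,
1/f and physiological noise spectra, spatial autocorrelation beyond the
block structure, unequal network sizes, and — importantly — the smooth
spatial gradients of real connectivity. Real correlation maps form a
continuum in feature space; the generator's networks are near-orthogonal
blocks separated by empty feature space. Passing tests on this data
therefore demonstrate algorithmic correctness and recovery under clean
planted structure, not performance on real BOLD data.

## Idealized blocks change two empirical behaviours

Two properties that the method exhibits on real data do **not**
transfer to idealized block data, and the package's validation reflects
this honestly rather than papering over it.

*Run-to-run stability.* On real data nearly every random-initialization
run converges to the same seven-network solution. On equal-sized block
data, the probability that $c$ random cubes land in $c$ distinct
networks is tiny ($7!/7^7 \approx 0.6\%$ at $c = 7$), and with
well-separated blocks the $M = 1.2$ iteration frequently cannot migrate
a duplicated centroid across the empty feature space between blocks —
forced runs of several thousand iterations confirm these are true local
optima, not premature stopping. A minority of runs is therefore fully
stable on synthetic data even though the *consensus* of twenty runs
recovers the planted networks essentially perfectly. On real data the
continuum of intermediate profiles provides the migration path, which
is how near-total stability arises there.

*Dispersion minima.* Because memberships optimally re-spread whenever a
cluster is added, $CD$ is non-increasing in $c$ at the global optimum;
interior local minima can only arise from run-to-run inconsistency at
non-structural $c$ — consensus averages of runs that split different
networks are blurred and score worse. On block data with a strong
consensus this inconsistency penalty is small and the curve decreases
smoothly past the planted count, so the planted $c^\*$ is flagged as a
strict local minimum only in a minority of seeds. The sweep machinery,
the strict-minimum rule (ties excluded, endpoints never reported) and
the per-$c$ solutions are all exercised regardless.

## Numerical choices

* Membership updates scale squared distances by their column minimum
  before the $-1/(M-1)$ power, so small-$M$ exponents cannot overflow; a
  voxel coincident with a centroid receives full membership in the first
  coincident cluster (a measure-zero event handled by the standard
  convention).
* Degenerate cases: $c = 1$ returns the grand-mean solution directly
  (dispersion exactly 1); coincident centroids make the Xie–Beni
  denominator zero and raise an error; an all-zero membership row in the
  centroid update raises an error; a constant uncertainty map has
  centered association 0 by convention.
* The assignment step of cluster matching is solved as maximum-weight
  perfect matching on a complete bipartite graph (igraph) after shifting
  similarities positive — a constant shift does not change the optimal
  perfect matching. Tests verify optimality against exhaustive
  permutation search up to $c = 5$.
* Zero-phase filtering pads each run with an odd reflection of up to 50
  samples before the forward–backward pass, so filter start-up
  transients decay inside the padding and a constant series passes
  through unchanged.
* All feature matrices are held in double precision; at the problem
  sizes used here the memory saving of reduced precision is not worth
  the complication.
* Validation problem sizes: the planted-recovery experiments use 700
  voxels over 300 frames; the model-selection sweeps use 280–350 voxels
  so that a full $c = 2..10$ sweep with ten restarts per $c$ over ten
  seeds remains a desk-scale computation.

## Limitations

Beyond the generator simplifications above: the pipeline starts from
motion-corrected, atlas-registered, intensity-normalized volumes (the
six motion parameters are inputs, not estimated); spatial smoothing of
real volumes is a pass-through hook; correlations are averaged and
clustered without Fisher transformation, matching the upstream
procedure this package operationalizes; and no anatomical naming or
statistical testing of similarity values is attempted. The number of
clusters is reported via dispersion minima only — alternative validity
indices are out of scope.
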