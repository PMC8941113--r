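---
title: "Voxel networks on the hyperbolic disc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel networks on the hyperbolic disc: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercore)
```

## What the package computes

hypercore analyses resting-state fMRI at the voxel level as a network problem.
Each subject contributes a BOLD matrix (voxels x time); the pipeline is

1. **Network construction** — pairwise sample Pearson correlations between
   voxel time series; edges are the correlations strictly above a positive
   threshold; the analysis proceeds on the largest connected component.
2. **Hyperbolic embedding** — the binary graph is fitted with the S1/H2
   geometric model, giving every voxel an angular (similarity) and a radial
   (popularity) coordinate on the hyperbolic disc.
3. **Angular coherence** — for labelled voxel groups (ICA subnetworks or
   anatomical lobes), the mean resultant length of their angles measures how
   tightly the group clusters on the disc.
4. **k-core percolation** — iterative pruning assigns every voxel a coreness;
   the k_max-core is the innermost non-empty core.
5. **Core composition** — the k_max-core voxels are counted per subnetwork,
   subjects are classified as DMN-dominant, VN-dominant or distributed, and
   voxels recurring across subjects form the common core.

## The S1/H2 model

In the S1 formulation each node has an angle $\theta_i$ on a circle of radius
$R = n/2\pi$ and a hidden degree $\kappa_i > 0$. A pair connects independently
with probability

$$p_{ij} = \frac{1}{1 + \chi_{ij}^{\beta}}, \qquad
  \chi_{ij} = \frac{R\,\Delta\theta_{ij}}{\mu\,\kappa_i\,\kappa_j},$$

where $\beta > 1$ sharpens the distance dependence (and with it the
clustering) and $\mu = \beta \sin(\pi/\beta) / (2\pi\langle k\rangle)$ ties
hidden degrees to expected degrees: with uniformly random angles the expected
degree of node $i$ is $\kappa_i$. Mapping
$r_i = \hat R - 2\ln(\kappa_i/\kappa_0)$ with
$\hat R = 2\ln\!\big(2R/(\mu\kappa_0^2)\big)$, $\kappa_0 = \min_i \kappa_i$,
places the nodes on a hyperbolic disc (curvature parameter fixed to 1, the
usual H2 convention) where the same connection law becomes a Fermi function
$p = 1/(1+e^{(\beta/2)(d - \hat R)})$ of hyperbolic distance $d$, with
$p = 1/2$ exactly at $d = \hat R$ and the best-connected voxel innermost.

Distances come from the hyperbolic law of cosines
(`hyperbolic_distance_exact`); the familiar logarithmic shortcut
$d \approx r_1 + r_2 + 2\ln(\Delta\theta/2)$
(`hyperbolic_distance_approx`) is also provided. Its validity premise is
$\Delta\theta > \sqrt{e^{-2r_1} + e^{-2r_2}}$ *and* a small-to-moderate angle:
the shortcut deviates from the exact distance by
$2\ln\big((\Delta\theta/2)/\sin(\Delta\theta/2)\big)$, which is under 1% of
the distance for $\Delta\theta \lesssim 1$ rad at disc radii 5–15 but grows
to ~9% at antipodal separations. The package therefore uses the exact form
everywhere internally (the S1 form of the likelihood needs no approximation);
the shortcut exists for interpretation and cross-checks.

### Fitting

`hyper_embed()` is the model-fitting entry point and returns a classed object
with `print`, `summary`, `coef`, `predict`, `simulate`, `residuals`, `logLik`
and `plot` methods. Internally:

* **`estimate_beta`** — $\beta$ controls clustering, so it is estimated by
  bisection on $(1, 10]$: for each candidate, hidden degrees are re-fitted,
  synthetic S1 graphs with those hidden degrees are sampled, and their mean
  local clustering is compared with the observed one (tolerance 0.01).
  Expected clustering is monotone increasing in $\beta$, so bisection is
  valid; sampling noise at the default two replicates is well below the
  tolerance at a few hundred nodes.
* **`infer_hidden_degrees`** — fixed-point iteration
  $\kappa_i \leftarrow \kappa_i (k_i / \bar k_i(\kappa))^{1/2}$ until the
  model-expected degrees $\bar k_i$ match the observed ones to 0.1 in
  sup-norm. The expected degree integrates the connection probability over a
  uniform angle, $\mathbb{E}[p_{ij}] = (c_{ij}/\pi) I(\pi/c_{ij})$ with
  $I(L) = \int_0^L (1+u^\beta)^{-1} du$; $I$ is precomputed on a log grid and
  interpolated, so each iteration is one dense outer product.
* **`initialize_angles_le`** — Laplacian eigenmaps: angles are read off the
  two leading nontrivial eigenvectors of the symmetric normalized Laplacian.
  On ring-like graphs this already recovers the circular order.
* **`refine_angles_ml`** — coordinate-wise hill climbing of the Bernoulli
  log-likelihood (compiled kernel): each sweep visits nodes in random order
  and offers each node 20 candidate angles — its current one plus von Mises
  draws around the degree-weighted circular mean of its neighbours' angles,
  with the proposal spread tightening from $\pi/2$ by a factor 0.8 per sweep
  down to 0.05 rad. Because the current angle is always a candidate the
  likelihood trace is non-decreasing; sweeps stop after 30 or when a sweep
  improves the log-likelihood by less than $10^{-4}$. Probabilities are
  clamped to $[10^{-12}, 1-10^{-12}]$ inside the likelihood so saturated
  pairs cannot produce infinities.

The disc is identified only up to rotation and reflection, so embeddings are
compared after `align_embeddings()`, which maximises the modulus of the mean
phasor of angle differences over both symmetries (closed form) and reports it
as the similarity in $[0, 1]$; for independent angle sets it concentrates
near $1/\sqrt{n}$.

On S1 benchmark graphs (n = 500, $\gamma = 2.5$, $\beta = 2.5$,
$\langle k\rangle = 10$) the full fit recovers planted angles with aligned
similarity around 0.95–0.98 and reproduces the Fermi connection curve with a
mean absolute deviation well under 0.05 — the acceptance script recomputes
both.

## Network construction choices

* **Estimators** — unbiased sample variance and the ordinary sample Pearson
  correlation; constant voxels are reported by id rather than silently
  yielding NA.
* **Thresholding** — strict `> t`, positive correlations only (negative
  correlations are a separate, deferred analysis). The operating threshold is
  0.4 with the candidate grid {0.30, 0.35, 0.40, 0.45, 0.50};
  `select_threshold` returns the smallest candidate whose graph passes both
  criteria below, keeping as many voxels as possible.
* **Largest-component criterion** — the component must hold at least 80% of
  the voxels; ties between equal-sized components break towards the one
  containing the smallest voxel id, for determinism.
* **Scale-freeness criterion** — "straight line on the log-log degree plot"
  is operationalized as: log-binned degree PDF (bin ratio 2), OLS line over
  the decaying tail — bins from the modal bin onward holding at least 5
  observations — requiring at least 3 such bins, a degree span of at least
  one decade, $R^2 \ge 0.90$ and slope $< -1$. Fitting the tail rather than
  every occupied bin matters: scale-free graphs with a bounded minimum
  hidden degree rise below the mode, and 1-count tail bins curve the fit;
  both would reject genuinely scale-free graphs. Poisson-like (ER) degree
  piles still fail — they span less than a decade and leave fewer than three
  tail bins. All cutoffs are arguments.

## k-core percolation

Coreness is computed with the linear-time bucket algorithm and is
order-independent; the tests verify it against a naive "delete any
minimum-degree vertex" oracle and against an independent library
implementation on hundreds of random graphs. $k_{max}$ is the largest k with
a non-empty k-core (the $(k_{max}+1)$-core is empty); because the innermost
core can fragment, the decomposition also records how many components the
k_max-core splits into. "Abrupt drops" in the core-size curve S(k) are steps
$S(k-1) - S(k)$ of at least 5% of S(1) by default (`min_drop` exposed).

## Composition, dominance, common core

Multi-membership is preserved throughout: a voxel carrying several labels
counts once per label (so composition fractions may sum above 1), and
merging the fifteen functional components into seven categories
(DMN+aDMN+PCN → DMN, L/R CEN → CEN, SMN1/2 → SMN, VN1–4+VAN → VN)
deduplicates within a category. A subject is DMN- or VN-dominant when that
category exceeds 40% of k_max-core voxels (strict); if both exceed it the
larger wins and an exact tie falls back to distributed — the rule is only
defined on the seven-category scheme, and anatomical profiles carry no
pattern. The cross-subject common core uses an inclusive share threshold
(at 60% of 30 subjects, 18 hits qualify). Core degrees for the stacked
histogram are read off the full original graph, not the core-induced
subgraph.

## Synthetic data: what it emulates, what it does not

`sample_s1_network` draws angles uniformly and hidden degrees from a
Pareto($\gamma$) law truncated at the natural cutoff
$\kappa_0 n^{1/(\gamma-1)}$, with $\kappa_0$ solved so the truncated mean
equals the target mean degree; the generator's binned connection frequencies
match the model curve, which the tests assert. With $\gamma = 2.5$ the hidden
degrees have infinite variance, so the realized mean degree of a single
500-node sample scatters around the target; the 15% degree-target check is
therefore made on the 10-seed average.

`simulate_bold` draws block-correlated Gaussian series through shared
factors (one global, one per block, plus voxel noise), which realises the
requested correlation matrix exactly and guarantees positive
semi-definiteness whenever $0 \le r_{between} \le r_{within} < 1$. Defaults
follow the resting-state regime the pipeline targets: TR = 0.72 s and
T = 1200 time points (both configurable; the number of time points per
subject is a free choice of the cohort generator).

`make_cohort` (default 140 voxels over the seven categories) encodes
dominance in the covariance: distributed subjects get symmetric blocks at
within-correlation 0.55; dominant-pattern subjects get their dominant block
at 0.70 with a double share of voxels, and the remaining blocks at 0.42,
just above the 0.4 operating threshold. At T = 1200 the correlation
estimator's noise (~0.026 SD) then makes the dominant block a clique whose
coreness roughly doubles any other structure, so the k_max-core is the
dominant block essentially surely — including when the realized between-block
edges (between-correlation 0.36, knife-edge at the threshold and strongly
dependent through the shared factors) are few enough to disconnect the
graph, because the dominant block is then itself the largest component. The
double-share design was chosen over equal blocks precisely because the
dependent between-block edge counts otherwise flip roughly one subject in
ten.

What the generators deliberately do **not** emulate: hemodynamic response
shapes, spatial autocorrelation of fMRI noise, head motion, negative
correlations, and non-stationarity. Passing tests on this synthetic family
therefore validate the pipeline's statistical machinery — thresholding
behaviour, embedding recovery, core detection, classification logic — not
its robustness to acquisition artifacts in real data.

## Numerical choices and degenerate inputs

* Band-pass filtering is a zero-phase order-4 Butterworth; each series is
  demeaned and odd-extension padded before the forward–backward pass, since
  an unpadded pass leaks edge transients. Constant series filter to exactly
  zero; linearity holds to the float64 noise floor (~$10^{-8}$ on unit-scale
  signals).
* Down-sampling is block-mean over factor³ grid cells with ceiling division
  per axis (2 mm → 6 mm uses factor 3); empty blocks are dropped, and full
  occupancy conserves the global mean exactly.
* Voxel ids are 0-based C-order flat grid indices, fixing a deterministic
  ordering for every reader and writer.
* IC-map binarization is strictly `Z > 6`; a voxel at exactly 6 is excluded.
* All stochastic steps (generators, beta estimation, proposal draws, sweep
  order) are pure functions of an integer seed.
* Degenerate inputs error loudly: empty masks and graphs, constant series,
  triangle-free graphs for $\beta$, disconnected graphs for the embedding,
  bands outside Nyquist.

## Problem sizes used by the tests and acceptance script

Embedding checks run at n = 500 with 5 seeds (recovery, calibration) and 10
seeds ($\beta$), planted-core recovery at n = 1000 with 10 seeds, the k-core
oracle on 200 random graphs up to n = 50, and the cohort at 9 subjects x 140
voxels x 1200 time points. These sizes make every stage's statistical target
measurable while the whole suite completes in a few minutes; the pipeline
itself handles the ~5000-voxel regime (the embedding's dense likelihood is
the O(n²) bottleneck, practical to about n = 6000).

## Known limitations

* The embedding likelihood is dense; very large graphs need subsampling or a
  sparsified objective.
* $\beta$ estimation assumes the S1 clustering-$\beta$ relation is monotone
  in the relevant range and caps the search at 10; graphs more clustered
  than the model can express are reported at the cap.
* The logarithmic distance approximation is exposed but not used in fitting;
  its error is documented above.
* Laterality comparisons use the paired two-sided Wilcoxon signed-rank test
  at $\alpha = 0.05$ per region without multiplicity correction, matching
  per-region reporting practice; callers needing family-wise control should
  adjust the returned p-values.
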