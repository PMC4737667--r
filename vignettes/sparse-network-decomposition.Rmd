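---
title: "Sparse dictionary decomposition of whole-brain fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse dictionary decomposition of whole-brain fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A single subject's 4D fMRI recording is flattened into a signal matrix
$S \in \mathbb{R}^{m \times n}$: $m$ time points in the rows, $n$ in-mask
voxel time series in the columns. `fmridict` represents $S$ as the product
of a temporal dictionary $D \in \mathbb{R}^{m \times k}$ and a sparse
spatial coefficient matrix $\alpha \in \mathbb{R}^{k \times n}$ by solving

$$
\min_{D \in \mathcal{C},\ \alpha}\ \tfrac{1}{2}\lVert S - D\alpha\rVert_F^2
  + \lambda \lVert\alpha\rVert_1,
\qquad
\mathcal{C} = \{ D : d_j^\top d_j \le 1 \ \forall j \},
$$

which decouples over voxels into $n$ lasso problems
$\min_a \tfrac12\lVert s_i - D a\rVert_2^2 + \lambda\lVert a\rVert_1$.
Each column of $D$ (an *atom*) is the temporal activity pattern of one
functional network; the matching row of $\alpha$ is that network's spatial
loading over voxels. The decomposition is intended to be over-complete
($k > m$) while remaining small relative to the voxel count ($k \ll n$);
the unit-ball constraint on atoms prevents the usual scale
indeterminacy from inflating $D$ while $\alpha$ shrinks to defeat the
$\ell_1$ penalty. Both the sign and the order of atoms are arbitrary:
all downstream consumers treat maps two-sidedly and compare sets of
networks, never atom indices.

Coefficient rows are mapped back to the 3D grid, z-scored over the
in-mask voxels and thresholded two-sidedly ($|z| > z_{\text{thresh}}$,
default 2.0) into candidate binary network maps. Candidates are
identified against labeled binary resting-state-network (RSN) templates
by spatial overlap, greedily and one-to-one; per-subject matches are
aggregated into group consensus maps by voxelwise majority.

## Solvers and numerical choices

**Sparse coding.** Cyclic coordinate descent on the Gram ("covariance")
formulation, deterministic by construction: coordinates are visited in
index order and iteration stops when no coefficient moves more than
1e-10 in a full sweep (cap 10,000 sweeps). All columns are swept
simultaneously — coordinate $j$ is updated for every column in one BLAS
call — and a column whose update falls below tolerance is frozen out of
the working set. Because columns never interact, each column's iterate
sequence is exactly what it would be if solved alone; freezing changes
cost, not results. Solutions are verified in the test suite against the
lasso subgradient conditions and, for $k \le 8$, against exhaustive
enumeration of every support and sign pattern. $\lambda = 0$ is accepted
only for full-column-rank, non-over-complete dictionaries, where the
problem is ordinary least squares.

**Dictionary updates.** Mini-batch online learning with accumulated
sufficient statistics $A_t = \sum \alpha\alpha^\top$,
$B_t = \sum s\alpha^\top$. After each batch one block coordinate-descent
pass updates atoms as
$u_j = d_j + (b_j - D a_j)/\max(A_{jj}, 10^{-12})$,
$d_j \leftarrow u_j / \max(1, \lVert u_j\rVert_2)$ — a surrogate descent
step followed by projection onto the unit ball, which never increases
the quadratic surrogate. Atoms with $A_{jj} \approx 0$ are left alone.

**Atom housekeeping.** At each epoch end, *dead* atoms (never used so
far) and *duplicate* atoms (|cosine| > 0.99 with an earlier atom) are
replaced by the worst-reconstructed signals of the most recent batch,
renormalized. Duplicate recycling matters when $k$ is close to the true
number of sources: without it, two atoms can lock onto one network
while another goes unrepresented.

**Initialization.** Atoms start as data columns projected to the unit
ball. A pool of $\min(n, 5k)$ columns is drawn under the seed and atoms
are chosen from it by greedy maximin |correlation| (in the spirit of
k-means++ seeding), which makes initial collisions — two atoms starting
inside the same network — rare.

**Defaults.** $\lambda = \mathrm{median}(\lVert s_i\rVert_2)/\sqrt{m}$
(about 1 for unit-variance columns), batch size 256, 5 epochs, $k$ = 400
for whole-brain recordings (fully configurable; the synthetic studies
below use $k = 50$). The per-epoch column order is a seeded shuffle, and
every random draw in the package flows through one seed, so a full run
is bitwise reproducible.

**Normalization.** Each voxel time series is linearly detrended (the
in-package analog of scanner drift removal; heavier preprocessing such
as motion or slice-time correction is assumed to have happened
upstream) and standardized to zero mean, unit variance. Zero-variance
columns — constant or purely linear series — are dropped rather than
imputed, because unit-variance scaling is undefined for them; the drop
is recorded and the voxel keeps an implicit zero loading in every map.
Standardizing (not merely detrending) is a deliberate choice: it puts
all voxels on one amplitude scale so that a single global $\lambda$ is
meaningful.

**z-scoring of maps.** Component z-maps are computed over all in-mask
voxels of the mapped volume, including voxels dropped at normalization
(their loading is zero). This keeps the reference population fixed to
the mask regardless of how many columns survive normalization — in a
noise-free limit most columns outside networks are dropped, and
z-scoring over survivors alone would make thresholds meaningless.

## Template matching

The overlap between a candidate map $A$ and a template $T$ defaults to
the Jaccard coefficient $|A \cap T| / |A \cup T|$; Dice and
fraction-of-template ($|A \cap T|/|T|$) are available because the
"percentage of overlapping area" convention differs between studies and
reported tables rarely pin it down. Matching is greedy one-to-one:
repeatedly take the best remaining (template, component) pair until the
best remaining overlap falls below `min_overlap` (default 0.05), ties
broken toward lower indices. Greedy matching is deterministic, and
adequate whenever overlaps are well separated, which planted-network
data and thresholded RSN maps are; a globally optimal assignment would
differ only in near-tie regimes.

Group maps are voxelwise consensus: stack the matched subject maps per
template, keep voxels present in at least `consensus_thresh` (default
0.5) of the matched subjects, and score the result against the template.
The group and individual overlap tables report, per dataset and
template, the group score and the mean ± population (n-denominator)
standard deviation of per-subject scores.

## The synthetic generator

The generator plants $K$ compact networks inside an ellipsoidal "brain"
and is the package's study-condition fixture: defaults are a $24^3$
grid (mask ≈ 5,200 voxels), $K = 10$ networks, $m = 120$ time points,
5 subjects, SNR 5, jitter 1.

* **Geometry.** Networks are connected blobs grown by stochastic region
  growth; frontier voxels are sampled with probability proportional to
  (in-region neighbors)^4, filling concavities first. The result is
  compact but irregular — a perfect sphere would make matching
  trivially easy, while unweighted growth yields dendritic shapes so
  fragile that a one-voxel displacement destroys half their overlap.
  Mean extent is `blob_size` = 200 voxels (≈ 4% of the mask, the order
  of real RSN extents relative to brain volume), varied ±20% per
  network; placement retries until all pairwise Jaccard overlaps are
  below 0.1.
* **Dynamics.** Each network has its own time course: white noise
  smoothed by a circular moving average (window 3 TRs) and standardized
  to unit variance — resting-state-like slow fluctuations with no task
  structure and no hemodynamic model, which this purpose does not need.
* **Mixing and noise.** A voxel's series is the sum of the time courses
  of the networks containing it (binary membership) plus i.i.d.
  Gaussian noise of sd $1/\text{SNR}$.
* **Subject variability.** Each subject perturbs each network's border:
  every voxel within `jitter` voxels of the boundary may independently
  flip membership (probability 0.25 per layer), so no voxel moves
  farther than `jitter`. Border jitter was chosen over rigid
  whole-network translation deliberately: independent local
  perturbations are what make the group consensus sharper than a
  typical individual — the pattern group-level analyses exist to show —
  whereas a rigid shift is a degenerate perturbation whose majority
  vote is no better than a single subject, and with few subjects the
  small set of possible integer shifts collides across subjects.

What the generator does **not** emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, spatial autocorrelation of
noise, scanner drift beyond what detrending removes, multi-site
heterogeneity, or weighted network membership. Passing the synthetic
studies therefore demonstrates the correctness of the factorization,
mapping and matching machinery under known ground truth — not
robustness to every artifact of real recordings.

## Study problem sizes

The bundled validation runs the full pipeline on the default synthetic
dataset (5 subjects, $24^3$ grid, $K = 10$, $m = 120$, SNR 5, $k = 50$
atoms) — a desk-scale analog of multi-site resting-state analyses, small
enough that a complete multi-subject decomposition plus its
quarter-sampled counterpart runs in minutes on one CPU. The voxel
sampling module is validated on the same data: training on 25% of
columns must still recover every planted network and agree with the
full-rate maps, and full-rate "sampling" must be bitwise identical to
the unsampled path.

## Known limitations

* Greedy matching can be suboptimal when two components overlap one
  template almost equally; `min_overlap` and the overlap method are the
  only levers exposed.
* Templates must already live on the analysis grid; there is no
  resampling or registration in the package.
* The dictionary path assumes the signal matrix fits in memory
  (desk-scale or masked whole-brain data); no out-of-core training.
* Atom count `k`, like the threshold `z_thresh`, is a modeling choice
  the package checks only for plausibility; it cannot be inferred from
  data here.
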