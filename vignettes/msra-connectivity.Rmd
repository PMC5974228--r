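---
title: "Multi-seed region analysis and the paired network-based statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-seed region analysis and the paired network-based statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI estimates functional connectivity from spontaneous BOLD
fluctuations: two brain regions are "connected" when their time-courses
correlate. How the regional time-courses are extracted strongly shapes the
resulting connectivity graph. msranet implements three extraction schemes
over one shared parcellation (an integer label atlas) and a paired
permutation statistic for detecting small between-session changes in the
resulting graphs:

* **MSRA** (multi-seed region analysis). A small, fixed-size seed (5 voxels)
  is placed automatically at each region's centre of mass. The seed's mean
  time-course is correlated with *every* brain voxel; significant voxels are
  selected by Benjamini–Hochberg FDR (q = 0.05) over the whole brain, and
  the significant **positive** correlations are averaged per target region.
  Row s of the matrix holds seed region s against all data-driven target
  regions, so the matrix is asymmetric — "pseudo-directed": the asymmetry
  comes from fixed seeds versus data-driven targets, not from any causal
  model.
* **SRCC** (seed-region cross-correlation). Pairwise Pearson correlation of
  the same seed time-courses; FDR is applied across the R(R−1)/2 matrix
  entries. Symmetric.
* **RCCA** (regional cross-correlation). As SRCC but each region is
  summarized by the score series of the first principal component of its
  voxel time-courses (sign-fixed to correlate non-negatively with the
  region mean), which is less biased than the plain mean in large,
  inhomogeneous regions. The per-region explained-variance fraction of PC1
  is reported as a diagnostic.

All three matrices store Pearson r with zeros meaning "not significant",
and are Fisher-z transformed (`atanh`) before averaging or t-statistics, as
z is approximately variance-stabilizing.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `q` | 0.05 | — | FDR level for declaring a correlation significant. MSRA applies it per seed map over all brain voxels; SRCC/RCCA over the matrix entries. |
| `seed_size` | 5 | voxels | Seed voxel count: the anchor nearest the centre of mass plus its 4 nearest in-plane neighbours. |
| `fwhm_mm` | 1.17 | mm | Gaussian smoothing kernel width, isotropic in mm (the per-axis sigma adapts to anisotropic voxels). |
| `lowpass_hz` | 0.1 | Hz | Low-pass cutoff; BOLD connectivity lives below ~0.1 Hz. |
| avg. degree | 20 directed / 10 undirected | edges per node | Graph threshold: N·d/2 strongest entries are kept (degree counts both endpoints, so 179 nodes at degree 20 give 1,790 edges). |
| `fraction` | 0.01 | — | pNBS first-level threshold: the p-value at or below which exactly ⌊0.01·m⌋ control connections fall. |
| `M` | 5000 | — | Permutations for the FWE-corrected p-value. |

## The paired network-based statistic

Classical network-based statistics permute group labels of independent
subjects; in a paired pre/post design the sessions are not exchangeable.
pNBS instead uses a second, unstimulated control group measured with the
identical pre/post protocol:

1. Per connection, a one-sample t-test of the subjects' Fisher-z session
   differences (post − pre) against zero, in both groups.
2. The first-level p cutoff is chosen so that exactly 1% of the control
   group's connections are supra-threshold — the control session carries no
   intervention, so these are "hypothetical false positives" that calibrate
   ordinary between-session variability.
3. The same cutoff is applied to the experimental group's p-values. Every
   connected component (weak skeleton, size measured in edges) no larger
   than the largest control component is eliminated; the statistic k is the
   number of surviving edges, which may span several components.
4. In each of M permutations, the subjects' difference matrices are
   reassigned to pseudo-groups of the original sizes and steps 1–3 are
   recomputed in full, including re-deriving the threshold — the wording of
   the procedure implies complete recalculation, and reusing the observed
   threshold would distort the null. `p_FWE = #(k' > k) / M`.

Two deliberate reading choices are exposed as options. The strict
inequality `k' > k` means ties favour significance; `tie = "ge"` gives the
conservative variant. And the procedure is sometimes described via a "99%
quantile" of control p-values — we implement the only reading consistent
with "1% supra-threshold false positives": the cutoff under which exactly
⌊fraction·m⌋ control connections fall.

When the number of distinct labelings is at most M (tiny designs), all of
them are enumerated instead of sampled, so the p-value is exact.

The analyzed connection set defaults to the union of the four group-average
session graphs at the average-degree threshold; `edge_rule = "all"` analyzes
every off-diagonal cell. The choice matters because the first-level quantile
is taken over this set.

## What the synthetic generator emulates — and what it does not

Real small-animal resting-state data are not redistributable here, so every
stage is exercised on synthetic studies with known ground truth:

* **Atlas**: an ellipsoidal foreground parcellated into contiguous regions
  by seeded round-robin region growing. Any contiguous parcellation serves;
  no anatomy is implied.
* **Signal model**: community c has a latent standard-normal signal
  s_c(t); region i in community c emits a·s_c(t) + σ·ε_i(t); each voxel
  adds independent noise. Two same-community region means then correlate at
  a²/(a²+σ²) in expectation (0.5 at the defaults a = σ = 1) and
  cross-community pairs at 0 — verified by Monte-Carlo against the closed
  form in the tests.
* **Paired modulation**: the experimental post session adds one shared
  latent component per planted edge, with its gain solved (including the
  voxel-noise attenuation term) so the pair's expected correlation rises by
  `delta_r`. Adding a latent keeps the series stationary with a valid
  positive-definite covariance; control pre/post and experimental pre remain
  exchangeable draws, which is exactly the null the permutation test needs.
* **Default scale**: 24×24×12 grids, 20–40 regions, 300 volumes at TR = 2 s
  — the acquisition cadence of a typical 10-minute resting-state run, at
  desk scale.

The generator deliberately omits hemodynamic response shapes, scanner drift
and spikes, motion, and physiological (cardiac/respiratory) structure.
Passing tests therefore demonstrate the *statistical machinery* — seed
placement, FDR thresholding, graph construction, permutation calibration —
not robustness to real-world artefacts, which upstream motion correction
and quality control must handle.

## Numerical choices

* **Low-pass filter**: the cutoff alone does not fix a filter; we use a
  4th-order Butterworth applied forward-backward (zero phase), since phase
  lags would bias correlations. Each voxel is demeaned before filtering and
  its mean restored, so DC passes exactly and the zero-padded edge
  transients act only on the fluctuation part.
* **Smoothing**: separable Gaussian with edge-inclusive reflect padding;
  the resulting convolution matrix is symmetric, so constants and the
  volume mean are preserved exactly. Background voxels are restored after
  the convolution: preprocessing never touches voxels outside the mask.
* **Seed placement**: the "central plane" is the z-slice nearest (in mm)
  to the region's centre-of-mass z that contains region voxels, ties to the
  lower slice. Distances are mm-scaled so anisotropic slices behave; exact
  geometric ties are broken lexicographically, and distances are rounded at
  1e-9 so floating-point noise cannot reorder true ties (this keeps
  placement translation-equivariant). Regions with fewer than 5 voxels on
  the plane keep all of them, with a warning, rather than being dropped.
* **r → p**: two-sided p from t = r·√((n−2)/(1−r²)) on n−2 df; the FDR
  step needs p-values and this is the standard exact mapping for Pearson r.
* **MSRA averaging** uses significant *positive* voxels only; anti-correlated
  networks can be studied by sign inversion (`anti = TRUE`).
* **Degenerate inputs**: zero-variance voxels get r = 0 and are flagged;
  constant seed time-courses zero their matrix row with a warning;
  zero-variance connections get p = 1 in the paired t step; |r| ≥ 1 is
  clipped to ±(1−1e−7) only at the Fisher-z stage.
* **Community detection**: Louvain modularity maximization (igraph) on the
  symmetrized graph (directed edges sum with their reciprocals). A target
  community count is reached by bisection on the resolution parameter; the
  reported Q is always the standard resolution-1 modularity. If the graph
  has more components than the target, the closest achievable count is
  returned with a warning.

## Problem sizes used in the tests

Oracle-equivalence checks run on 5-region, 50-volume toys against explicit
loop-based reimplementations. Calibration of the generator uses 3,000-volume
runs over 20 seeds. The permutation-test calibration uses 16-region atlases:
200 null studies (12 vs 13 subjects, 100 volumes, M = 200) for the type-I
rate and 50 replicate studies (300 volumes, Δr = 0.4 on a 6-edge star) for
power. These sizes were chosen so the full suite runs on a laptop in a few
minutes while keeping Monte-Carlo error well inside the asserted bounds.

## Known limitations

* Slice-time correction, motion correction, skull stripping and template
  registration are out of scope; inputs are assumed motion-corrected and
  atlas-aligned.
* Group ICA is not computed; component z-maps are accepted as input for the
  co-activation and Jaccard comparisons. The co-activation product is
  implemented as Σ_c (z̄_ci·z̄_cj)^k with region means clipped at 0; the
  pooled alternative (Σ then power) is available via `formula = "pooled"`
  because the literature is ambiguous about the order of operations.
* The "normalized variance" reproducibility matrix is normalized by the
  per-method maximum variance — a choice, made so methods share a [0, 1]
  scale; medians are compared across methods by Kruskal–Wallis.
* `run_pipeline()` logs stage parameters and input hashes but recomputes
  every stage on rerun; there is no artifact cache.
* Connected components of the pseudo-directed MSRA graph are measured on
  the weak (undirected) skeleton, and component size is counted in edges.
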