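---
title: "Detecting spatially variable features with big-small patch variance ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatially variable features with big-small patch variance ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchsvf)
library(Matrix)
```

## The problem

Spatially resolved omics assays measure thousands of features (genes, or
chromatin accessibility peaks) at known tissue coordinates. A first-line
analysis asks which features are *spatially variable* (SVFs): expressed in a
pattern tied to tissue geometry rather than scattered at random. As
platforms move toward single-cell and sub-cellular resolution the matrices
become very large (10^5 or more spots) and very sparse (non-zero fractions
below 0.1%), which breaks methods that densify the matrix or model each
feature's spatial covariance explicitly.

`patchsvf` implements a granularity-based statistic that needs only sparse
matrix products and a fixed-radius neighbor search, works in 2D and 3D
without modification, and makes no distributional assumption about the
counts themselves.

## The statistic

For a sample with $M$ spots and $N$ features, let $X$ be the $N \times M$
count matrix and $s_i$ the coordinates of spot $i$.

1. **Density rescaling.** All coordinates are multiplied by the single
   scalar $(M / \prod_d \Delta s^{(d)})^{1/D}$, where $\Delta s^{(d)}$ is
   the coordinate range along axis $d$. Afterwards the product of the
   ranges equals $M$, so the typical spot-to-spot spacing is about one
   unit regardless of the platform's physical pitch. Because the factor is
   isotropic, anisotropic geometry (e.g. widely spaced serial sections) is
   preserved, not hidden.
2. **Max-abs expression scaling.** Each feature row is divided by its
   maximum, mapping it into $[0, 1]$ without destroying sparsity.
3. **Patches at two radii.** For each spot $i$ and radius $R_k$ the patch
   is the set of spots at distance $< R_k$, excluding $i$ itself; a spot
   with no neighbors inside the radius falls back to a patch containing
   only itself. Patches are held as sparse binary $M \times M$ matrices
   $B^{(k)}$, with column $i$ marking the patch of spot $i$. Defaults are
   $R_1 = 1$ and $R_2 = 3$ rescaled units, i.e. roughly "immediate
   neighbors" and "a neighborhood three spacings wide".
4. **Local means and their variances.** $\bar X^{(k)} = \tilde X B^{(k)}
   D^{(k)}$, with $D^{(k)}$ the diagonal matrix of inverse patch sizes,
   gives the patch-averaged expression at every spot. Let
   $\sigma^2_{j,k}$ be the variance of feature $j$'s local means across
   spots.
5. **The ratio.** With $w_j = \sigma^2_j / \max_n \sigma^2_n$ (the
   feature's overall variance relative to the most variable feature),
   $$ r_j = w_j \, \frac{\sigma^2_{j,2}}{\sigma^2_{j,1}}. $$
   Smoothing at a coarser granularity wipes out unstructured variation
   quickly but retains variation organized over length scales larger than
   $R_1$; a large $r_j$ therefore indicates spatial structure.
6. **Null and p-values.** The bulk of $\{r_j\}$ is well approximated by a
   lognormal law when most features are not spatially variable. We fit
   $\hat\mu, \hat s$ by Gaussian maximum likelihood on $\ln r_j$ and assign
   one-sided upper-tail p-values $1 - \Phi((\ln r_j - \hat\mu)/\hat s)$.
   For low-throughput panels (hundreds of features, many of them real
   signals) the lognormal fitting set is contaminated; `permutation_null()`
   instead pushes spot-permuted copies of the observed features through the
   identical statistic and uses an add-one empirical tail.

## A worked run

```{r example}
sim <- simulate_2d("hotspot", n_svf = 50, n_null = 450,
                   fc = 5, tau2 = 0.2, seed = 1)
res <- run_bsp(sim$expression, sim$coords, seed = 1)
head(res[order(res$p_value), ], 3)
power_at_fdr(res$p_value, sim$labels, fdr_grid = c(0.01, 0.05))
```

## Parameters that matter

* `r1`, `r2` (defaults 1 and 3 rescaled units): the two granularity
  levels. They are meaningful only after density rescaling, which is why
  `build_spatial_index()` refuses raw coordinates unless overridden.
  Patterns much smaller than `r1` or much larger than the tissue will not
  produce a variance drop between the two levels.
* `null_kind`: `"lognormal"` for feature-rich data (thousands of features,
  minority of SVFs); `"permutation"` with `n_perm` (default 1000,
  minimum 100) otherwise.
* `alpha` (default 0.05): used only for the reported `significant` call;
  p-values are always reported for all features, and ranking by p-value is
  the primary output. No multiple-testing correction is applied by
  default; `adjust = "bh"` appends a Benjamini-Hochberg `q_value` column.
* `mode`: `"exact"` (cell-list search, the default and the mode used for
  all statistical guarantees) or `"approximate"` (randomly shifted grids
  whose repetition count is derived from `recall_target`; candidates are
  distance-verified, so only misses are possible, never false members).
* `variance_denominator`: population (divide by $M$; default) or sample
  variances, applied consistently to $\sigma^2_{j,k}$, $\sigma^2_j$ and the
  log-sd of the fit. The ratio $\sigma^2_{j,2}/\sigma^2_{j,1}$ and the
  weight are invariant to this choice; only $\hat s$ shifts slightly.
* `weight_on_scaled`: the weight $w_j$ uses raw-count variances by
  default, on the view that the intrinsic expression variance of a feature
  is a property of its counts; a switch computes it from the max-abs
  scaled matrix instead, which de-emphasizes high-count features.

## Numerical and degenerate-input choices

* Patch membership uses the strict inequality $\mathrm{dist} < R_k$. On
  lattice-like data, distances exactly equal to a radius are common, so
  strictness is part of the definition, and exact mode honours it to the
  last bit.
* Constant features (zero variance) are excluded up front with
  $p = 1$; so are features whose small-patch local means are constant
  ($\sigma^2_{j,1} = 0$, which would give an infinite ratio) and features
  with $r_j = 0$. Exclusions are flagged in the output rather than
  silently dropped, and every input feature gets a row.
* A coordinate dimension with zero range is a hard error: a 2D slice
  passed as 3D should be caught, not guessed around.
* p-values are floored at the smallest positive double so that downstream
  $\Phi^{-1}$ transforms (Stouffer) stay finite; inputs exactly 0 or 1 to
  `stouffer_combine()` are clipped with a warning.
* One seeded generator per run: the permutation null and the approximate
  index consume the seed in a fixed documented order, so results are
  bit-reproducible for a given configuration.

## What the simulators emulate

The package ships generators for the benchmark families used to validate
detectors of this kind; all emit ground-truth labels and a parameter
record sufficient to regenerate the dataset.

* `simulate_2d()`: 260 spots (configurable) on a jittered lattice with a
  disk, streak, or annulus mask, log-normal-Poisson counts with fold
  change `fc` between marked and unmarked regions and dispersion `tau2`.
  The geometry is a parameterized stand-in with marked fractions
  comparable to the classic olfactory-bulb benchmark patterns; it
  preserves the statistical structure (patterned versus permuted features
  under overdispersed counts) without shipping external data.
* `simulate_3d_continuous()`: 10 serial sections of a 15 x 15 grid
  (2,250 spots); the pattern is a union of spheres whose centers follow a
  step-2 random walk, monotone in two axes (curved strand), one axis
  (tissue layer) or none (irregular aggregate). At the domain boundary a
  monotone axis is clamped rather than reflected, because reflection would
  reverse the walk's direction.
* `simulate_3d_discrete()`: 10 sections of a 30 x 30 grid (9,000 spots)
  with 16 spheres centered on the $\{3, 11, 19, 27\}^2$ grid at
  $z = 5.5$, jittered by $U(-2, 2)$ per coordinate.
* Marked spots draw counts from the upper quartile of a right-skewed
  reference distribution, unmarked spots from the full distribution, with
  marked values scaled so the realized mean fold change equals `fc`. The
  reference is negative binomial (mean 2, size 2, configurable): the
  sampling scheme is distribution-agnostic, and any right-skewed count
  distribution preserves the design. Additive Gaussian noise with sd
  `noise_sigma` times the average feature sd is truncated at zero so
  counts stay non-negative.
* `apply_dropout()` zeroes whole spots (capture failure), and
  `stretch_interplane()` multiplies $z$ by 10 (coarse inter-plane
  resolution) — the two robustness perturbations.
* `simulate_sparse_random()` generates throughput-scale matrices with
  i.i.d. sparse entries, $\lfloor 1 + 10\,\mathrm{Beta}(1,5)\rfloor$
  valued, for calibration and performance work; it contains no spatial
  signal at all.

None of these reproduce platform-specific artifacts (segmentation errors,
spatial depth gradients, doublets), so passing benchmarks here demonstrates
correctness of the statistic and calibration of its null, not end-to-end
performance on any particular real tissue.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the generators at reduced
feature counts chosen to exercise every code path while keeping a full run
in the low minutes: oracle-agreement instances up to 200 spots x 50
features; calibration at 5,000 features x 2,000 spots over ten seeds; the
2D benchmark at 200 SVF + 1,800 null features over ten replicates; the 3D
discrete benchmark at 100 SVF + 900 null features over 9,000 spots; and a
20,000 x 50,000 sparse run at density 5e-4. The generators default to the
full-scale settings (1,000 SVF + 9,000 null) for users who want the
complete benchmark.

## Known limitations

* The lognormal null assumes SVFs are a minority; on panels where most
  features are patterned the fit shifts right and power drops — use the
  permutation null there.
* The variance ratio detects structure at scales bracketed by the two
  radii; a single fixed pair cannot be optimal for every pattern size,
  and patterns far smaller than the spot spacing are invisible by
  construction.
* Euclidean distances only: no geodesic or graph distances, no periodic
  boundaries.
* The method ranks features; it does not segment the tissue or say where
  the pattern is.
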