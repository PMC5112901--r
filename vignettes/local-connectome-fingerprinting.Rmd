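---
title: "Local connectome fingerprinting: model, statistics, and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local connectome fingerprinting: model, statistics, and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Diffusion MRI measures, per voxel and per gradient direction, how water
displaces in tissue. The spin distribution function (SDF) summarizes this
as a function on the sphere: the density of diffusing spins displaced
along each direction $\hat u$. `lcfp` reconstructs SDFs directly in a
common stereotaxic space (q-space diffeomorphic reconstruction):

$$
\psi(\hat u) \;=\; |J_\phi(r)|\; Z_0^{-1} \sum_i W_i(\phi(r))\,
\mathrm{sinc}\!\Big(\sigma \sqrt{6 D b_i}\,
\big\langle \hat g_i,\; J_\phi(r)\hat u / \lVert J_\phi(r)\hat u\rVert
\big\rangle\Big)
$$

where $W_i$ is the signal of volume $i$ (b-value $b_i$, gradient
direction $\hat g_i$), $\phi$ maps a standard-space coordinate $r$ into
the subject's native space, $J_\phi$ is its Jacobian (which transports
the sampling direction and, through its determinant, rescales density),
$\sigma$ is the diffusion sampling ratio, $D$ the free-water diffusivity
and $Z_0$ a free-water normalization constant. `sinc` is the unnormalized
$\sin(x)/x$; the kernel argument uses the q-space sampling length
$\sigma\sqrt{6 D b_i}$, the standard form in this reconstruction family.
With an identity warp the equation reduces to generalized q-sampling in
native space, which is how the package reconstructs its own synthetic
data.

The *local connectome fingerprint* samples $\psi$ at the fiber directions
of a per-voxel direction atlas across cerebral white matter, serializes
the samples in a canonical left-posterior-superior voxel order (fiber
rank innermost), and scales the compiled vector to unit sample variance.
Distances between fingerprints (root-mean-squared error) then drive all
downstream statistics:

* **identification** — within/between-subject partition of all scan
  pairs, d-prime separation, leave-one-out 1-D linear discriminant
  classification, and a modeled classification error
  $P(X_w > X_b)$ with both distance distributions fitted by a
  generalized extreme value (GEV) law;
* **similarity** — the similarity index $100(1 - d_1/d_0)$ against the
  expected unrelated-subject distance $d_0$, longitudinal trend tests
  (Mann-Kendall, least-squares slope per 100 days), and kinship group
  comparisons (Kruskal-Wallis, Scheffé post-hoc, permutation tests).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 1.25 | — | diffusion sampling ratio; lower values emphasize restricted diffusion |
| `D_free` | 2.51e-3 | mm²/s | free-water diffusivity at body temperature; enters only through the product $\sigma\sqrt{6Db_i}$ |
| `z0_estimator` | `"max"` | — | $Z_0$ = max (default) or mean of per-voxel peak unnormalized SDF over the ventricle mask |
| `out_spacing` | 1 | mm | standard-space output grid spacing |
| reconstruction directions | 321 axes | — | antipodally reduced 3-fold tessellated icosahedron |
| `angle_tol` | 4 | degrees | atlas direction sampled from the nearest reconstruction direction within this gap, else inverse-angular-distance interpolation over the 3 nearest |
| LDA priors | empirical | — | class-frequency priors, the default of standard LDA implementations; `"equal"` available |
| GEV shape bound | 1e-6 | — | the shape is constrained positive ($k > 0$), respecting the lower-bounded support of distance distributions |
| `n_perm` | 10000 | — | permutation count; p-values use the add-one estimator and can never be exactly zero |

$Z_0$ makes free water's peak density equal 1, so SDF magnitudes are
expressed relative to free diffusion. The "max" estimator is the
default; "mean" (mean over ventricle voxels of the per-voxel peak) is
available behind the config switch because either reading is defensible
and the difference is a global scale that cancels after variance
normalization.

## What the phantom emulates

`population_spec()` + `simulate_signals()` generate a full multi-subject,
multi-session study from a stick-and-ball signal model:
$S = S_0[\sum_f v_f e^{-b d_a \langle \hat g, e_f\rangle^2} + v_{iso}
e^{-b D}]$. The design encodes the central physical contrast of the
method: between-subject individuality lives in *how much* water diffuses
along fibers (the volume fractions $v_f$, log-normally perturbed per
subject), not in *how fast* (the diffusivities $d_a$, $D$ are fixed
across subjects). Fingerprints built from SDF magnitudes therefore carry
subject identity, which is exactly the property being tested.

Key generator choices:

* **Geometry.** Deterministic templates ("crossing-slab" with a
  two-fiber 90° crossing region, "callosum-arc", "uniform-z") on a
  12×12×8 voxel grid by default, with a free-water ventricle block used
  as the $Z_0$ reference. The matching direction atlas ranks fibers by
  descending base volume fraction.
* **Scheme.** One b0 plus 64 quasi-uniform (Fibonacci) directions at
  b = 2000 s/mm², a desk-scale analogue of single-shell protocols.
* **Subject effects and kinship.** Each (voxel, fiber) density
  multiplier is $e^{\varepsilon}$ with
  $\varepsilon = \sqrt\rho\,\varepsilon_{family} +
  \sqrt{1-\rho}\,\varepsilon_{unique}$, so kin pairs correlate at
  $\rho$ ($\rho_{MZ} = 0.25$, $\rho_{DZ} = \rho_{sib} = 0.10$ by
  default, satisfying $\rho_{MZ} > \rho_{DZ} = \rho_{sib} > 0$).
* **Noise.** Rician (magnitude MRI) at SNR 10 on the white-matter b0
  signal by default; Gaussian available for debugging.
* **Drift.** Session signals scale by $1 - \text{rate}\cdot
  \text{days}/100$ across the whole white-matter voxel.

**Calibration.** The defaults `subject_sd = 0.15`, `snr = 10` were fixed
once, by choosing the noise level at which repeat-scan similarity falls
in the 70–80% band reported for real repeat scans. At that operating
point the phantom reproduces the method's central claim pattern: repeat
scans are visibly imperfect copies (similarity far from 100%), kin-pair
similarity lands near observed twin-study levels (about 12.5% for MZ
pairs and 5% for DZ/sibling pairs, via the closed-form relation
$\text{sim} \approx 100(1-\sqrt{1-\rho u})$ with $u$ the fraction of
between-subject distance variance attributable to subject effects), yet
identification over 10 subjects × 2 sessions is still error-free with
d-prime far above 4.

**Homogeneous drift and normalization.** The default drift multiplies
every white-matter entry by the same factor, which makes the raw
fingerprint scale exactly by $1 - \text{rate}\cdot\text{days}/100$ — a
sharp, testable prediction through the whole pipeline. The flip side is
that a *uniform* scale cancels under global variance normalization, so
homogeneous drift alone does not move normalized similarity. Spatially
heterogeneous drift (`drift_sd > 0`) produces genuine similarity decline;
the longitudinal trend statistics (slope recovery, Mann-Kendall) are
validated on similarity series with a known imposed slope, which is the
level at which the trend layer operates.

**What the phantom does not emulate.** No scanner artifacts (eddy
currents, motion, susceptibility), no gyral/sulcal geometry, no real
registration error (warps are identity or user-supplied), and grids are
orders of magnitude smaller than brain volumes. Passing tests therefore
demonstrate the correctness and calibration of the algorithms, not
real-data effect sizes: headline real-data numbers (specific d-prime
values per cohort, error magnitudes near $10^{-6}$) depend on the
original scans and are out of reach by construction.

## Numerical choices

* `sinc` evaluates $\sin(x)/x$ with a series branch below $10^{-4}$, so
  the removable singularity at b = 0 is exact.
* Negative reconstruction sums (possible because sinc takes negative
  values) are clamped to zero and counted (`n_clamped`); the SDF field
  is nonnegative by contract.
* Signals at warped coordinates are trilinearly interpolated in voxel
  space; positions outside the subject volume mark the standard-space
  voxel as background (zeros) and flag it in `valid`.
* Warps supplied without a Jacobian get one by central finite
  differences (one-sided at borders); determinants must be positive
  inside the mask.
* The GEV likelihood is maximized by Nelder-Mead on
  $(\log(k - k_{min}), \log\sigma, \mu)$ from three shape starts with a
  support penalty; the positive-shape constraint is a box bound
  $k \ge 10^{-6}$. Fits with fewer than 10 samples warn.
* $P(X_w > X_b)$ integrates $F_b(Q_w(u))$ over $u \in (0,1)$ (the
  probability integral transform maps the lower-bounded, heavy-tailed
  supports onto a finite interval) by adaptive quadrature at absolute
  tolerance $10^{-10}$, with a seeded Monte-Carlo fallback.
* Mann-Kendall uses the exact permutation distribution of S (Mahonian
  convolution) for n ≤ 10 without ties, otherwise the normal
  approximation with tie-corrected variance and continuity correction.
* Scheffé's post-hoc is applied to rank-transformed values by default so
  the family stays coherent with the Kruskal-Wallis omnibus; a
  raw-value variant is available (`on = "raw"`). Which variant the
  original analyses used is not documented, so both are exposed.
* LPS entry order is defined as lexicographic (i, j, k) with i the
  slowest key and fiber rank innermost, on volumes reoriented to LPS at
  load; the atlas content hash is recorded in fingerprint metadata so
  order/atlas mismatches are detectable rather than silent.
* Ties in 1-D LDA are broken by the larger prior; LOOCV refits the
  discriminant for every held-out pair.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen so the full suite completes in minutes on one
CPU: oracle equivalence on a 5×5×5 grid with 21 sampling axes;
identification on 10 subjects × 2 sessions (12×12×8 grid, 65 volumes,
321 axes); kinship on 90 pair-families (180 subjects) with 10,000
permutations; GEV recovery at n = 10⁴ and Monte-Carlo cross-checks at
10⁶–10⁷ draws; Mann-Kendall calibration over 10⁴ null series.

## Known limitations

* Oblique (non axis-aligned) NIfTI affines are rejected rather than
  resampled; inputs must be on axis-aligned grids.
* The warp is consumed, never estimated: registration quality is the
  user's responsibility, exactly as in the underlying method.
* `fit_gev` assumes the positive-shape regime; data genuinely favoring
  $k < 0$ are pushed to the boundary $k \approx 0$ (Gumbel-like), which
  is the intended behavior for non-negative distance data but wrong for
  arbitrary samples.
* Atlas fiber ranks are taken as given; the package does not re-derive
  them from SDF peaks.
* The LOOCV error of the 1-D LDA at chance-level problems exhibits the
  classic leave-one-out pessimism (rate near 1 when both classes are
  identical and equally sized); this is a property of the estimator, not
  a defect of the implementation.
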