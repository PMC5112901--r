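# lcfp — local connectome fingerprinting for diffusion MRI

`lcfp` quantifies differences and similarities between whole-brain white
matter architectures. It reconstructs spin distribution functions (SDFs)
from diffusion-weighted MRI in a common stereotaxic space, samples their
magnitudes along a per-voxel fiber-direction atlas, and compiles the
samples into a single high-dimensional **local connectome fingerprint**
per scan. Fingerprint distances then power two analyses:

* **Subject identification.** The root-mean-squared-error distance
  between two fingerprints classifies scan pairs as same-subject or
  different-subject: within/between partition, d-prime separation,
  leave-one-out linear-discriminant classification, and a modeled
  classification error from generalized extreme value (GEV) fits of the
  two distance distributions.
* **Similarity quantification.** The similarity index
  `100 × (1 − d1/d0)` — a pair's distance relative to the expected
  unrelated-subject distance — feeds longitudinal trend analysis
  (Mann-Kendall test, slope per 100 days) and kinship group comparisons
  (Kruskal-Wallis, Scheffé post-hoc, permutation tests).

The reconstruction implements

```
psi(u) = |J(r)| / Z0 * sum_i W_i(phi(r)) * sinc(sigma * sqrt(6 D b_i) * <g_i, J u/||J u||>)
```

with signals `W_i` interpolated at the warped coordinate `phi(r)`,
sampling directions transported through the Jacobian `J`, density scaled
by `|J|`, and `Z0` estimated from free-water diffusion in the ventricle.
With an identity warp this is generalized q-sampling in native space.

A built-in synthetic phantom (`population_spec()`, `simulate_signals()`,
`emit_dataset()`) generates multi-subject, multi-session diffusion data
with controllable between-subject variability, temporal drift, kinship
sharing (MZ/DZ/sibling) and Rician noise, so the entire pipeline runs and
is tested without any external imaging data. It is intended for method
developers and for validating the statistical layer; real studies plug in
their own NIfTI volumes, b-tables and atlases through the same readers.

## Worked example

Simulate a 10-subject repeat-scan study, build fingerprints, and run the
identification analysis:

```r
library(lcfp)

spec <- population_spec(n_subjects = 10, sessions_days = list(c(0, 30)),
                        seed = 7)
pop <- simulate_signals(spec)
fps <- lapply(pop$sessions, function(ss)
  normalize_fingerprint(extract_fingerprint(
    reconstruct_sdf(ss$dwi), pop$atlas, ss$subject, ss$session, ss$days)))
dm <- distance_matrix(fps)
identification_report(dm)
```

```
Identification report
  pairs: 10 within, 180 between
  d-prime: 27.541
  LOOCV: 0 / 190 misclassified (rate 0)
  GEV within:  k=0.0000 sigma=0.008523 mu=0.2043
  GEV between: k=0.0000 sigma=0.03048 mu=0.846
  modeled classification error: 0
```

All 190 scan pairs are classified correctly: within-subject distances
(mean GEV location 0.20) sit far below between-subject distances (0.85),
a separation of d′ ≈ 28, and the modeled probability of a within-subject
distance exceeding a between-subject one is numerically zero. At the
same time the repeat scans are not perfect copies:

```r
pd <- partition_differences(dm)
mean(similarity_index(pd$within, mean(pd$between)))
#> [1] 75.7
```

i.e. repeat-scan similarity sits in the 70–80% band — identification
stays perfect even though a quarter of the fingerprint distance budget is
noise. `similarity_trend()` and `kinship_groups()` run the longitudinal
and kinship analyses on the same distance matrices, and `lcfp_cli()`
(also available as `inst/cli/lcfp.R`) exposes the pipeline as
`simulate / reconstruct / fingerprint / compare / identify / similarity /
groups` subcommands.

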