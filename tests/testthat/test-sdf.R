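test_that("sinc kernel handles the removable singularity and matches sin(x)/x", {
  expect_identical(sinc_kernel(0), 1)
  expect_lt(abs(sinc_kernel(pi)), 1e-12)
  expect_equal(sinc_kernel(pi / 2), 2 / pi, tolerance = 1e-12)
  x <- seq(-20, 20, length.out = 1001)
  x <- x[x != 0]
  expect_equal(sinc_kernel(x), sin(x) / x, tolerance = 1e-12)
  # series branch agrees with the ratio just outside it
  expect_equal(sinc_kernel(9e-5), sin(9e-5) / 9e-5, tolerance = 1e-15)
  expect_true(all(sinc_kernel(x) >= -0.2173 & sinc_kernel(x) <= 1))
})

test_that("Z0 is homogeneous in signal scale and equals the ventricle SDF peak", {
  sch <- lcfp:::phantom_scheme(32, 2000)
  dwi <- free_water_dwi(sch)
  cfg <- recon_config()
  dirs <- icosphere_directions(2)
  z0 <- estimate_z0(dwi, cfg, dirs)
  expect_gt(z0, 0)
  dwi10 <- dwi_dataset(dwi$signals * 10, sch, dwi$grid,
                       ventricle_mask = dwi$ventricle_mask)
  expect_equal(estimate_z0(dwi10, cfg, dirs), 10 * z0, tolerance = 1e-12)
  # brute-force maximum of the unnormalized sum over the ventricle
  brute <- -Inf
  vent <- which(dwi$ventricle_mask, arr.ind = TRUE)
  for (v in seq_len(nrow(vent))) for (u in seq_len(nrow(dirs))) {
    acc <- 0
    for (i in seq_along(sch$b_values)) {
      arg <- cfg$sigma * sqrt(6 * cfg$D_free * sch$b_values[i]) *
        sum(sch$directions[i, ] * dirs[u, ])
      acc <- acc + dwi$signals[vent[v, 1], vent[v, 2], vent[v, 3], i] *
        (if (abs(arg) < 1e-12) 1 else sin(arg) / arg)
    }
    brute <- max(brute, acc)
  }
  expect_equal(z0, brute, tolerance = 1e-10)
  # mean estimator lies at or below the max
  cfg_m <- recon_config(z0_estimator = "mean")
  expect_lte(estimate_z0(dwi, cfg_m, dirs), z0 + 1e-12)
  dwi_nov <- dwi_dataset(dwi$signals, sch, dwi$grid)
  expect_error(estimate_z0(dwi_nov, cfg, dirs), "free-water")
})

test_that("vectorized reconstruction matches the triple-loop oracle on a 5x5x5 phantom", {
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(5, 5, 5), layout = "crossing-slab",
                          subject_sd = 0.2, snr = 20, seed = 77)
  pop <- simulate_signals(spec)
  dwi <- pop$sessions[[1]]$dwi
  dirs <- icosphere_directions(1)
  cfg <- recon_config()
  z0 <- estimate_z0(dwi, cfg, dirs)
  cfg$z0 <- z0
  warp <- identity_warp(dwi$grid)
  sdf <- reconstruct_sdf(dwi, warp, cfg, dirs)
  oracle <- oracle_sdf(dwi, warp, z0, cfg$sigma, cfg$D_free, dirs)
  expect_lt(max(abs(sdf$values - oracle)) / max(oracle), 1e-10)
})

test_that("reconstruction is invariant to supplying an explicit identity warp", {
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(6, 6, 5), subject_sd = 0.2,
                          snr = 20, seed = 5)
  pop <- simulate_signals(spec)
  dwi <- pop$sessions[[1]]$dwi
  dirs <- icosphere_directions(2)
  a <- reconstruct_sdf(dwi, NULL, recon_config(), dirs)
  b <- reconstruct_sdf(dwi, identity_warp(dwi$grid), recon_config(), dirs)
  expect_lt(max(abs(a$values - b$values)), 1e-10)
})

test_that("Jacobian scaling multiplies density by c^3 and keeps argmax directions", {
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(5, 5, 5), layout = "uniform-z",
                          subject_sd = 0, snr = Inf, seed = 2)
  pop <- simulate_signals(spec)
  dwi <- pop$sessions[[1]]$dwi
  dirs <- icosphere_directions(2)
  cfg <- recon_config()
  cfg$z0 <- estimate_z0(dwi, cfg, dirs)
  iw <- identity_warp(dwi$grid)
  cc <- 1.3
  scaled <- diffeo_map(iw$phi, iw$grid, jacobian = iw$jacobian * cc)
  a <- reconstruct_sdf(dwi, iw, cfg, dirs)
  b <- reconstruct_sdf(dwi, scaled, cfg, dirs)
  expect_equal(b$values, cc^3 * a$values, tolerance = 1e-10)
  wm <- which(as.vector(pop$template$wm_mask))
  expect_equal(apply(b$values[wm, ], 1, which.max),
               apply(a$values[wm, ], 1, which.max))
})

test_that("signal-scale equivariance: rescaling signals and re-estimating Z0 leaves psi fixed", {
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(5, 5, 5), subject_sd = 0.2,
                          snr = 30, seed = 9)
  pop <- simulate_signals(spec)
  dwi <- pop$sessions[[1]]$dwi
  dirs <- icosphere_directions(2)
  a <- reconstruct_sdf(dwi, NULL, recon_config(), dirs)
  dwi2 <- dwi_dataset(dwi$signals * 7.5, dwi$scheme, dwi$grid,
                      brain_mask = dwi$brain_mask,
                      ventricle_mask = dwi$ventricle_mask)
  b <- reconstruct_sdf(dwi2, NULL, recon_config(), dirs)
  expect_lt(max(abs(a$values - b$values)), 1e-10)
})

test_that("isotropic free water yields a direction-independent SDF on a symmetric scheme", {
  # smooth kernel (low b) + icosahedral full-sphere scheme: quadrature is
  # essentially exact, so psi must be rotationally flat
  sch <- symmetric_scheme(100, subdiv = 2)
  dwi <- free_water_dwi(sch)
  sdf <- reconstruct_sdf(dwi, NULL, recon_config(), icosphere_directions(3))
  psi <- sdf$values[14, ]
  expect_lt(stats::sd(psi) / mean(psi), 1e-6)
  # at the phantom's own sharper scheme the flatness is approximate
  sch2 <- lcfp:::phantom_scheme(64, 2000)
  dwi2 <- free_water_dwi(sch2)
  sdf2 <- reconstruct_sdf(dwi2, NULL, recon_config(), icosphere_directions(3))
  psi2 <- sdf2$values[14, ]
  expect_lt(stats::sd(psi2) / mean(psi2), 5e-3)
})

test_that("antipodal symmetry holds for schemes containing +/- gradient pairs", {
  sch <- symmetric_scheme(2000, subdiv = 2)   # icosahedral: contains -g for every g
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(5, 5, 5), layout = "uniform-z",
                          subject_sd = 0, snr = Inf, seed = 3)
  pop <- simulate_signals(spec)
  dwi0 <- pop$sessions[[1]]$dwi
  # resynthesize the phantom signal on the symmetric scheme
  dirs_full <- icosphere_directions(2, antipodal = FALSE)
  n <- nrow(dirs_full)
  dwi <- dwi_dataset(
    synthesize_on_scheme(pop$template, sch),
    sch, dwi0$grid, brain_mask = dwi0$brain_mask,
    ventricle_mask = dwi0$ventricle_mask)
  pm <- rbind(unclass(dirs_full), -unclass(dirs_full))
  sdf <- reconstruct_sdf(dwi, NULL, recon_config(),
                         direction_set(pm, antipodal = FALSE))
  psi_plus <- sdf$values[, seq_len(n)]
  psi_minus <- sdf$values[, n + seq_len(n)]
  expect_lt(max(abs(psi_plus - psi_minus)), 1e-10)
})

test_that("only b0 terms survive when diffusion-weighted signals vanish", {
  sch <- lcfp:::phantom_scheme(16, 2000)
  grid <- make_grid(c(3, 3, 3), c(2, 2, 2))
  sig <- array(0, c(3, 3, 3, 17))
  sig[, , , 1] <- 50                      # b0 only
  dwi <- dwi_dataset(sig, sch, grid)
  cfg <- recon_config(z0 = 1)
  sdf <- reconstruct_sdf(dwi, NULL, cfg, icosphere_directions(2))
  expect_equal(max(sdf$values) - min(sdf$values), 0)
  expect_equal(sdf$values[1, 1], 50)      # |J| Z0^-1 sum = 1 * 1 * 50
})

test_that("voxels warped outside the subject volume become background", {
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(4, 4, 4), layout = "uniform-z",
                          subject_sd = 0, snr = Inf, seed = 1)
  pop <- simulate_signals(spec)
  dwi <- pop$sessions[[1]]$dwi
  iw <- identity_warp(dwi$grid)
  phi <- iw$phi
  phi[1, 1, 1, ] <- c(1e3, 1e3, 1e3)      # push one voxel far outside
  warp <- diffeo_map(phi, dwi$grid, jacobian = iw$jacobian)
  sdf <- reconstruct_sdf(dwi, warp, recon_config(), icosphere_directions(1))
  expect_false(sdf$valid[1, 1, 1])
  expect_true(all(sdf$values[1, ] == 0))
  expect_true(sdf$valid[2, 2, 2])
})

test_that("SDF fields round-trip through NIfTI + direction sidecar", {
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(4, 4, 4), subject_sd = 0.1,
                          snr = 30, seed = 6)
  pop <- simulate_signals(spec)
  sdf <- reconstruct_sdf(pop$sessions[[1]]$dwi, NULL, recon_config(),
                         icosphere_directions(1))
  f <- tempfile(fileext = ".nii.gz")
  write_sdf(sdf, f)
  back <- read_sdf(f)
  expect_equal(back$values, sdf$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unclass(back$dirs), unclass(sdf$dirs), tolerance = 1e-9,
               ignore_attr = TRUE)
})
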