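make_small_atlas <- function() {
  grid <- make_grid(c(3, 3, 3), c(2, 2, 2))
  mask <- array(FALSE, c(3, 3, 3))
  fibers <- array(0, c(3, 3, 3, 9))
  # three voxels holding 2, 1, 3 fibers
  put <- function(i, j, k, vecs) {
    mask[i, j, k] <<- TRUE
    for (r in seq_along(vecs))
      fibers[i, j, k, (3 * r - 2):(3 * r)] <<- vecs[[r]]
  }
  put(2, 2, 2, list(c(1, 0, 0), c(0, 1, 0)))
  put(1, 3, 1, list(c(0, 0, 1)))
  put(3, 1, 2, list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  direction_atlas(mask, fibers, grid)
}

const_sdf <- function(grid, dirs, value = 3) {
  structure(list(values = matrix(value, prod(grid$dim), nrow(dirs)),
                 grid = grid, dirs = dirs,
                 valid = array(TRUE, grid$dim), n_clamped = 0L, z0 = 1),
            class = "lcfp_sdf")
}

test_that("fingerprint length, ordering and constant-field sampling", {
  atlas <- make_small_atlas()
  dirs <- icosphere_directions(2)
  sdf <- const_sdf(atlas$grid, dirs)
  fp <- extract_fingerprint(sdf, atlas, "s", "1")
  expect_length(fp$values, 6L)              # 2 + 1 + 3 fibers
  expect_true(all(fp$values == 3))
  # LPS order: voxels sorted by (i, j, k) with i slowest, rank innermost
  expect_equal(fp$index$i, c(1, 2, 2, 3, 3, 3))
  expect_equal(fp$index$rank, c(1, 1, 2, 1, 2, 3))
  # determinism: bitwise identical on re-extraction
  fp2 <- extract_fingerprint(sdf, atlas, "s", "1")
  expect_identical(fp$values, fp2$values)
  expect_identical(fp$index, fp2$index)
})

test_that("extraction picks the SDF peak at the atlas fiber direction", {
  spec <- population_spec(n_subjects = 1, sessions_days = list(0),
                          grid_shape = c(5, 5, 5), layout = "uniform-z",
                          subject_sd = 0, snr = Inf, seed = 4)
  pop <- simulate_signals(spec)
  sdf <- reconstruct_sdf(pop$sessions[[1]]$dwi)
  fp <- extract_fingerprint(sdf, pop$atlas)
  wm <- which(as.vector(pop$template$wm_mask))
  # atlas fiber is exactly z; entry must equal the SDF maximum there
  peaks <- apply(sdf$values[wm, ], 1, max)
  expect_equal(sort(fp$values), sort(peaks), tolerance = 1e-12)
})

test_that("atlas storage order does not affect the emitted fingerprint", {
  atlas <- make_small_atlas()
  dirs <- icosphere_directions(2)
  set.seed(8)
  sdf <- const_sdf(atlas$grid, dirs)
  sdf$values <- matrix(runif(length(sdf$values)), nrow(sdf$values))
  fp <- extract_fingerprint(sdf, atlas, "s", "1")
  # rebuild the same atlas content (fresh arrays, same values)
  atlas2 <- direction_atlas(atlas$mask + 0 > 0, atlas$fibers + 0, atlas$grid)
  expect_identical(atlas2$hash, atlas$hash)
  fp2 <- extract_fingerprint(sdf, atlas2, "s", "1")
  expect_identical(fp$values, fp2$values)
})

test_that("normalization gives unit variance, is idempotent, rejects constants", {
  atlas <- make_small_atlas()
  sdf <- const_sdf(atlas$grid, icosphere_directions(2))
  set.seed(3)
  sdf$values <- matrix(rexp(length(sdf$values)), nrow(sdf$values))
  fp <- extract_fingerprint(sdf, atlas, "s", "1")
  fpn <- normalize_fingerprint(fp)
  expect_equal(stats::var(fpn$values), 1, tolerance = 1e-9)
  expect_true(fpn$meta$normalized)
  fpn2 <- normalize_fingerprint(fpn)
  expect_equal(fpn2$values, fpn$values, tolerance = 1e-9)
  fpc <- extract_fingerprint(const_sdf(atlas$grid, icosphere_directions(2)),
                             atlas, "s", "1")
  expect_error(normalize_fingerprint(fpc), "degenerate")
})

test_that("subsetting partitions entries and re-normalizes", {
  atlas <- make_small_atlas()
  sdf <- const_sdf(atlas$grid, icosphere_directions(2))
  set.seed(5)
  sdf$values <- matrix(runif(length(sdf$values), 1, 2), nrow(sdf$values))
  fp <- extract_fingerprint(sdf, atlas, "s", "1")
  full_mask <- array(TRUE, atlas$grid$dim)
  expect_equal(subset_fingerprint(fp, full_mask)$values, fp$values)
  one <- array(FALSE, atlas$grid$dim); one[2, 2, 2] <- TRUE
  sub1 <- subset_fingerprint(fp, one)
  expect_length(sub1$values, 2L)
  sub2 <- subset_fingerprint(fp, !one)
  expect_length(sub2$values, length(fp$values) - 2L)
  # normalized input is re-normalized over the kept entries
  fpn <- normalize_fingerprint(fp)
  subn <- subset_fingerprint(fpn, one)
  expect_equal(stats::var(subn$values), 1, tolerance = 1e-9)
  expect_error(subset_fingerprint(fp, array(FALSE, atlas$grid$dim)),
               "no fingerprint entries")
})

test_that("joint-normalized RMSE is invariant to common positive rescaling of raw SDFs", {
  atlas <- make_small_atlas()
  dirs <- icosphere_directions(2)
  set.seed(11)
  mk <- function(scale) {
    s1 <- const_sdf(atlas$grid, dirs); s2 <- const_sdf(atlas$grid, dirs)
    v <- matrix(runif(27 * nrow(dirs), 1, 3), 27)
    s1$values <- v * scale
    s2$values <- (v + matrix(rnorm(length(v), sd = 0.2), nrow(v))) * scale
    c(a = list(extract_fingerprint(s1, atlas, "a", "1")),
      b = list(extract_fingerprint(s2, atlas, "b", "1")))
  }
  # the same underlying pair at two global scales
  set.seed(11); p1 <- mk(1)
  set.seed(11); p2 <- mk(37.3)
  d1 <- rmse_distance(normalize_fingerprint(p1$a), normalize_fingerprint(p1$b))
  d2 <- rmse_distance(normalize_fingerprint(p2$a), normalize_fingerprint(p2$b))
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("difference maps average absolute entry differences at one rank", {
  atlas <- make_small_atlas()
  dirs <- icosphere_directions(2)
  sdf <- const_sdf(atlas$grid, dirs)
  fp <- extract_fingerprint(sdf, atlas, "s", "1")
  # identical pair -> zero map
  m0 <- difference_map(list(list(fp, fp)), atlas, rank = 1)
  expect_true(all(m0$values == 0))
  # +delta at exactly one rank-1 entry
  fp2 <- fp; fp2$values[1] <- fp2$values[1] + 0.7   # voxel (1,3,1), rank 1
  m1 <- difference_map(list(list(fp, fp2)), atlas, rank = 1)
  expect_equal(m1$values[1, 3, 1], 0.7)
  expect_equal(sum(m1$values != 0), 1L)
  # two pairs with differences d1, d2 at the same entry -> mean
  fp3 <- fp; fp3$values[1] <- fp3$values[1] + 0.3
  m2 <- difference_map(list(list(fp, fp2), list(fp, fp3)), atlas, rank = 1)
  expect_equal(m2$values[1, 3, 1], (0.7 + 0.3) / 2)
  # rank-2 map is background at single-fiber voxels
  m3 <- difference_map(list(list(fp, fp2)), atlas, rank = 2)
  expect_equal(m3$values[1, 3, 1], 0)
  # mismatched atlases are rejected
  fibers2 <- atlas$fibers; fibers2[2, 2, 2, 1:3] <- c(0, 0, 1)
  atlas2 <- direction_atlas(atlas$mask, fibers2, atlas$grid)
  fp_bad <- extract_fingerprint(const_sdf(atlas2$grid, dirs), atlas2, "x", "1")
  expect_error(difference_map(list(list(fp, fp_bad)), atlas), "hash")
})

test_that("fingerprint container round-trips values, index and metadata", {
  atlas <- make_small_atlas()
  sdf <- const_sdf(atlas$grid, icosphere_directions(2))
  set.seed(2)
  sdf$values <- matrix(runif(length(sdf$values)), nrow(sdf$values))
  fp <- normalize_fingerprint(extract_fingerprint(sdf, atlas, "subj7", "2",
                                                  days = 45))
  f <- tempfile(fileext = ".csv")
  write_fingerprint(fp, f)
  back <- read_fingerprint(f)
  expect_equal(back$values, fp$values, tolerance = 1e-12)
  expect_equal(back$index, fp$index, ignore_attr = TRUE)
  expect_identical(back$meta$subject, "subj7")
  expect_identical(back$meta$atlas_hash, fp$meta$atlas_hash)
  expect_true(back$meta$normalized)
})
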