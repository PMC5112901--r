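#' Per-voxel fiber-direction atlas
#'
#' The common sampling framework: for every white-matter voxel of the
#' standard-space grid, an ordered list (rank 1..K) of unit fiber axes at
#' which SDF magnitudes are sampled. Rank order is taken as given by the
#' atlas (conventionally descending resolved-fiber prominence).
#'
#' @param mask logical 3-D array (cerebral white matter).
#' @param fibers array (x, y, z, 3*K_max): K unit 3-vectors per voxel,
#'   zero-padded for missing ranks.
#' @param grid \code{lcfp_grid}.
#' @param K_max maximum fibers per voxel (default 3).
#' @return object of class \code{lcfp_atlas} with a content \code{hash}.
#' @export
direction_atlas <- function(mask, fibers, grid, K_max = 3L) {
  stopifnot(inherits(grid, "lcfp_grid"))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(as.integer(dim(mask)), grid$dim))
    stop("mask must match the grid")
  d4 <- dim(fibers)
  if (length(d4) != 4L || !identical(as.integer(d4[1:3]), grid$dim) ||
      d4[4] %% 3L != 0L)
    stop("fibers must be (grid dim) x 3K")
  K <- d4[4] %/% 3L
  if (K > K_max) stop("per-voxel fiber count exceeds K_max")
  fib <- matrix(fibers, ncol = d4[4])               # voxel x 3K
  counts <- integer(prod(grid$dim))
  for (r in seq_len(K)) {
    v <- fib[, (3 * r - 2):(3 * r), drop = FALSE]
    nrm <- sqrt(rowSums(v^2))
    present <- nrm > 1e-6
    if (any(present & abs(nrm - 1) > 1e-6))
      stop("fiber vectors must be unit norm")
    if (any(present & !as.vector(mask)))
      stop("every voxel with fibers must lie inside the mask")
    counts <- counts + as.integer(present)
    # ranks must be contiguous from 1
    if (r > 1L && any(present & counts < r))
      stop("fiber ranks must be contiguous (no gaps)")
  }
  if (any(as.vector(mask) & counts == 0L))
    stop("every mask voxel must carry at least one fiber")
  at <- structure(list(mask = mask, fibers = fibers, grid = grid, K = K,
                       counts = array(counts, grid$dim)),
                  class = "lcfp_atlas")
  at$hash <- atlas_hash(at)
  at
}

# content hash of the canonicalized atlas (voxel order fixed by the grid,
# values rounded to 1e-8) -- detects any mismatch between atlases
atlas_hash <- function(atlas) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeBin(c(as.integer(atlas$grid$dim), as.integer(atlas$K)), con)
  writeBin(round(c(atlas$grid$spacing, atlas$grid$origin), 8), con)
  writeBin(as.integer(atlas$mask), con)
  writeBin(round(as.numeric(atlas$fibers), 8), con)
  close(con)
  unname(tools::md5sum(tf))
}

#' Read / write a direction atlas as NIfTI
#'
#' Fibers are stored as a 4-D NIfTI with 3*K components per voxel
#' (zero-padded) next to a 3-D mask NIfTI.
#'
#' @param fibers_path,mask_path NIfTI paths.
#' @return \code{lcfp_atlas}.
#' @export
read_atlas <- function(fibers_path, mask_path) {
  f <- read_nifti_lps(fibers_path)
  m <- read_nifti_lps(mask_path)
  direction_atlas(m$data != 0, f$data, f$grid,
                  K_max = max(3L, dim(f$data)[4] %/% 3L))
}

#' @rdname read_atlas
#' @param atlas \code{lcfp_atlas}.
#' @export
write_atlas <- function(atlas, fibers_path, mask_path) {
  write_nifti_lps(atlas$fibers, atlas$grid, fibers_path)
  write_nifti_lps(array(as.numeric(atlas$mask), atlas$grid$dim),
                  atlas$grid, mask_path)
  invisible(fibers_path)
}

# entry table in canonical left-posterior-superior order: voxels sorted
# lexicographically by (i, j, k) with i the slowest key, fiber rank
# innermost. Returns data.frame(i, j, k, rank, voxel_lin).
atlas_entry_index <- function(atlas) {
  idx <- grid_index_table(atlas$grid)
  counts <- as.vector(atlas$counts)
  keep <- counts > 0L
  idx <- idx[keep, , drop = FALSE]
  cnt <- counts[keep]
  lin <- which(keep)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]; cnt <- cnt[ord]; lin <- lin[ord]
  data.frame(
    i = rep(idx[, 1], cnt), j = rep(idx[, 2], cnt), k = rep(idx[, 3], cnt),
    rank = sequence(cnt), voxel_lin = rep(lin, cnt))
}
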