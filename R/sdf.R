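#' Unnormalized sinc kernel
#'
#' sin(x)/x with the removable singularity at 0 handled by series
#' expansion. This is the Fourier kernel that converts shell-sampled
#' diffusion signals into spin displacement density along a direction.
#'
#' @param arg numeric vector.
#' @return numeric vector in [-0.2172.., 1].
#' @export
sinc_kernel <- function(arg) {
  out <- numeric(length(arg))
  small <- abs(arg) < 1e-4
  x <- arg[small]
  out[small] <- 1 - x^2 / 6 + x^4 / 120
  out[!small] <- sin(arg[!small]) / arg[!small]
  out
}

#' Reconstruction configuration
#'
#' @param sigma diffusion sampling ratio (dimensionless); controls the
#'   displacement range of the spins sampled by the SDF. Default 1.25.
#' @param D_free free-water diffusivity, mm^2/s. Default 2.51e-3 (free
#'   water at body temperature).
#' @param z0 free-water normalization constant in signal units; resolved
#'   by \code{\link{estimate_z0}} when NA.
#' @param z0_estimator "max" (default) or "mean" over ventricle voxels.
#' @param out_spacing standard-space output spacing, mm.
#' @return object of class \code{lcfp_recon_config}.
#' @export
recon_config <- function(sigma = 1.25, D_free = 2.51e-3, z0 = NA_real_,
                         z0_estimator = c("max", "mean"), out_spacing = 1) {
  z0_estimator <- match.arg(z0_estimator)
  stopifnot(sigma > 0, D_free > 0, out_spacing > 0,
            is.na(z0) || z0 > 0)
  structure(list(sigma = sigma, D_free = D_free, z0 = z0,
                 z0_estimator = z0_estimator, out_spacing = out_spacing),
            class = "lcfp_recon_config")
}

# kernel matrix: n_volumes x n_directions, entry sinc(sigma*sqrt(6 D b_i) <g_i, u_d>)
sdf_kernel_matrix <- function(scheme, dirs, sigma, D_free) {
  L <- sigma * sqrt(6 * D_free * scheme$b_values)   # per-volume length scale
  dots <- scheme$directions %*% t(dirs)             # n_vol x n_dir
  m <- sinc_kernel(L * dots)                        # L recycled down columns
  matrix(m, nrow = length(L))
}

#' Estimate the free-water normalization constant Z0
#'
#' Z0 is estimated from the diffusion signals of free water in the brain
#' ventricle: the maximum (default) or mean of the per-voxel maximum
#' unnormalized SDF magnitude over the ventricle mask, so that free
#' water's peak spin density maps to 1.
#'
#' @param dwi \code{lcfp_dwi} with a non-empty \code{ventricle_mask}.
#' @param cfg \code{lcfp_recon_config}.
#' @param dirs direction set (matrix of unit vectors); default 321-axis
#'   tessellated icosahedron.
#' @return positive scalar, in signal units.
#' @export
estimate_z0 <- function(dwi, cfg = recon_config(),
                        dirs = icosphere_directions(3)) {
  vm <- dwi$ventricle_mask
  if (is.null(vm) || !any(vm)) stop("no free-water reference region")
  K <- sdf_kernel_matrix(dwi$scheme, dirs, cfg$sigma, cfg$D_free)
  nvol <- dim(dwi$signals)[4]
  W <- matrix(dwi$signals, ncol = nvol)[as.vector(vm), , drop = FALSE]
  psi <- W %*% K                                    # n_vox x n_dir, unnormalized
  vox_max <- apply(psi, 1, max)
  z0 <- switch(cfg$z0_estimator, max = max(vox_max), mean = mean(vox_max))
  if (!is.finite(z0) || z0 <= 0) stop("Z0 estimate is not positive")
  z0
}

#' Reconstruct spin distribution functions in standard space
#'
#' Computes, for every standard-space voxel r and sampling direction u,
#' \deqn{\psi(u) = |J_\phi(r)| \, Z_0^{-1} \sum_i W_i(\phi(r)) \,
#'   \mathrm{sinc}\!\big(\sigma \sqrt{6 D b_i}\,
#'   \langle g_i, J_\phi(r) u / \|J_\phi(r) u\| \rangle\big)}
#' i.e. q-space diffeomorphic reconstruction: signals are interpolated at
#' the warped subject coordinate, sampling directions are transported
#' through the Jacobian, and density is scaled by the Jacobian
#' determinant and normalized by the free-water constant Z0. With an
#' identity warp this reduces to generalized q-sampling in native space.
#'
#' Negative sums (possible because sinc takes negative values) are
#' clamped to zero; the clamp count is recorded in the result. Voxels
#' whose warped position falls outside the subject volume become
#' background (all-zero) and are flagged in \code{valid}.
#'
#' @param dwi \code{lcfp_dwi}.
#' @param warp \code{lcfp_warp} on the output grid; default identity on
#'   the DWI grid.
#' @param cfg \code{lcfp_recon_config}; \code{z0} is estimated from the
#'   ventricle mask when unresolved.
#' @param dirs direction set; default 321-axis tessellated icosahedron.
#' @return object of class \code{lcfp_sdf}: list with \code{values}
#'   (n_voxels x n_directions matrix, voxels in R array order),
#'   \code{grid}, \code{dirs}, \code{valid} (logical 3-D array),
#'   \code{n_clamped}, \code{z0}.
#' @export
reconstruct_sdf <- function(dwi, warp = NULL, cfg = recon_config(),
                            dirs = icosphere_directions(3)) {
  if (is.null(warp)) warp <- identity_warp(dwi$grid)
  stopifnot(inherits(warp, "lcfp_warp"))
  z0 <- cfg$z0
  if (is.na(z0)) z0 <- estimate_z0(dwi, cfg, dirs)
  grid <- warp$grid
  nvox <- prod(grid$dim)
  ndir <- nrow(dirs)
  nvol <- dim(dwi$signals)[4]

  # signals at warped coordinates
  phi <- matrix(warp$phi, ncol = 3L)
  pts <- grid_world_to_index(dwi$grid, phi)
  W <- trilinear_interp(dwi$signals, pts)           # nvox x nvol, NA outside
  valid <- !is.na(W[, 1])
  W[!valid, ] <- 0

  Jflat <- matrix(warp$jacobian, ncol = 9L)         # columns: J11,J21,J31,J12,...
  jd <- as.vector(warp$jac_det)
  values <- matrix(0, nvox, ndir)

  identity_J <- all(abs(sweep(Jflat, 2, as.vector(diag(3)))) < 1e-12)
  if (identity_J) {
    K <- sdf_kernel_matrix(dwi$scheme, dirs, cfg$sigma, cfg$D_free)
    values <- (W %*% K) * (jd / z0)
  } else {
    # group voxels sharing a Jacobian so constant-J warps stay fast
    key <- apply(round(Jflat, 10), 1, paste, collapse = ",")
    for (grp in split(seq_len(nvox), key)) {
      J <- matrix(Jflat[grp[1], ], 3L, 3L)
      tu <- dirs %*% t(J)                           # rows: J u (transposed product)
      nrm <- sqrt(rowSums(tu^2))
      if (any(nrm < 1e-12)) stop("degenerate Jacobian direction")
      tu <- tu / nrm
      K <- sdf_kernel_matrix(dwi$scheme, tu, cfg$sigma, cfg$D_free)
      values[grp, ] <- (W[grp, , drop = FALSE] %*% K) * (jd[grp] / z0)
    }
  }
  values[!valid, ] <- 0
  n_clamped <- sum(values < 0)
  values[values < 0] <- 0
  structure(list(values = values, grid = grid, dirs = dirs,
                 valid = array(valid, grid$dim), n_clamped = n_clamped,
                 z0 = z0),
            class = "lcfp_sdf")
}

#' Write / read an SDF field
#'
#' The field is stored as one 4-D NIfTI volume (voxel x direction) with a
#' plain-text sidecar listing the sampling directions (one "x y z" row
#' per direction).
#'
#' @param sdf \code{lcfp_sdf}.
#' @param path output NIfTI path; sidecar is \code{paste0(path, ".dirs.txt")}.
#' @export
write_sdf <- function(sdf, path) {
  arr <- array(sdf$values, c(sdf$grid$dim, nrow(sdf$dirs)))
  write_nifti_lps(arr, sdf$grid, path)
  utils::write.table(format(sdf$dirs, digits = 10, trim = TRUE),
                     paste0(path, ".dirs.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sdf
#' @export
read_sdf <- function(path) {
  v <- read_nifti_lps(path)
  dirs <- as.matrix(utils::read.table(paste0(path, ".dirs.txt")))
  dimnames(dirs) <- NULL
  nd <- dim(v$data)[4]
  if (nrow(dirs) != nd) stop("direction sidecar does not match volume")
  structure(list(values = matrix(v$data, ncol = nd), grid = v$grid,
                 dirs = direction_set(dirs),
                 valid = array(TRUE, v$grid$dim), n_clamped = 0L,
                 z0 = NA_real_),
            class = "lcfp_sdf")
}
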