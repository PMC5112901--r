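#' Standard-space voxel grid
#'
#' Axis-aligned voxel grid in LPS+ anatomical convention: voxel index
#' (i, j, k) increases toward left / posterior / superior, and world
#' coordinates (mm) are \code{origin + (index - 1) * spacing}. All volumes
#' handled by the package live on such a grid; NIfTI images are reoriented
#' to LPS on load.
#'
#' @param dim integer 3-vector of voxel counts.
#' @param spacing numeric 3-vector, mm per voxel.
#' @param origin world coordinate (mm, LPS) of voxel (1,1,1); default
#'   centers the grid on the world origin.
#' @return object of class \code{lcfp_grid}.
#' @export
make_grid <- function(dim, spacing = c(1, 1, 1),
                      origin = -(dim - 1) / 2 * spacing) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(spacing) == 3L, all(spacing > 0))
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "lcfp_grid")
}

grids_compatible <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# n x 3 matrix of 1-based voxel indices for linear indices (R array order)
grid_index_table <- function(grid) {
  d <- grid$dim
  cbind(
    i = rep_len(seq_len(d[1]), prod(d)),
    j = rep_len(rep(seq_len(d[2]), each = d[1]), prod(d)),
    k = rep(seq_len(d[3]), each = d[1] * d[2]))
}

# voxel indices (n x 3, 1-based) -> world mm (LPS)
grid_index_to_world <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3L)
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

# world mm (LPS) -> fractional 1-based voxel indices
grid_world_to_index <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3L)
  sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`) + 1
}

# RAS affine (4x4) for NIfTI output: RAS = (-x, -y, z) of LPS
grid_affine_ras <- function(grid) {
  s <- grid$spacing; o <- grid$origin
  m <- rbind(cbind(diag(c(-s[1], -s[2], s[3])),
                   c(-o[1], -o[2], o[3])),
             c(0, 0, 0, 1))
  structure(m, code = 2L)
}

#' Trilinear interpolation of a volume stack
#'
#' Interpolates one or more volumes (a 3-D array or 4-D stack) at
#' fractional voxel coordinates. Points outside the volume return NA.
#'
#' @param vol 3-D array or 4-D array (x, y, z, volume).
#' @param pts n x 3 matrix of fractional 1-based voxel indices.
#' @return n-vector (3-D input) or n x n_vol matrix.
#' @export
trilinear_interp <- function(vol, pts) {
  dv <- dim(vol)
  was3d <- length(dv) == 3L
  if (was3d) { dim(vol) <- c(dv, 1L); dv <- dim(vol) }
  pts <- matrix(as.numeric(pts), ncol = 3L)
  n <- nrow(pts); nvol <- dv[4]
  out <- matrix(NA_real_, n, nvol)
  inside <- pts[, 1] >= 1 & pts[, 1] <= dv[1] &
            pts[, 2] >= 1 & pts[, 2] <= dv[2] &
            pts[, 3] >= 1 & pts[, 3] <= dv[3]
  if (any(inside)) {
    p <- pts[inside, , drop = FALSE]
    p0 <- pmin(floor(p), rep(dv[1:3] - 1L, each = nrow(p))) # clamp so p0+1 valid
    p0 <- pmax(p0, 1)
    f <- p - p0
    dim(vol) <- c(dv[1] * dv[2] * dv[3], nvol)
    lin <- function(di, dj, dk)
      (p0[, 1] + di - 1) + (p0[, 2] + dj - 1) * dv[1] +
      (p0[, 3] + dk - 1) * dv[1] * dv[2] + 1
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) f[, 1] else 1 - f[, 1]) *
           (if (dj) f[, 2] else 1 - f[, 2]) *
           (if (dk) f[, 3] else 1 - f[, 3])
      acc <- acc + w * vol[lin(di, dj, dk), , drop = FALSE]
    }
    out[inside, ] <- acc
  }
  if (was3d) out[, 1] else out
}
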