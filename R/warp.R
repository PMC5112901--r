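#' Diffeomorphic map from standard space to subject space
#'
#' Stores, on the standard-space grid, the mapped subject coordinate
#' phi(r) (mm, LPS) per voxel, the 3x3 Jacobian field of phi, and its
#' determinant. The Jacobian transports SDF sampling directions and its
#' determinant scales spin density when reconstructing in standard space.
#'
#' @param phi array (x, y, z, 3) of subject-space mm coordinates.
#' @param grid standard-space \code{lcfp_grid}.
#' @param jacobian optional array (x, y, z, 3, 3); when absent it is
#'   computed from \code{phi} by central finite differences.
#' @param mask optional logical array restricting where positivity of the
#'   determinant is enforced (default: everywhere).
#' @return object of class \code{lcfp_warp} with fields \code{phi},
#'   \code{jacobian}, \code{jac_det}, \code{grid}.
#' @export
diffeo_map <- function(phi, grid, jacobian = NULL, mask = NULL) {
  stopifnot(inherits(grid, "lcfp_grid"))
  if (!identical(as.integer(dim(phi)), c(grid$dim, 3L)))
    stop("phi must be (grid dim) x 3")
  if (is.null(jacobian)) jacobian <- finite_difference_jacobian(phi, grid)
  if (!identical(as.integer(dim(jacobian)), c(grid$dim, 3L, 3L)))
    stop("jacobian must be (grid dim) x 3 x 3")
  jd <- jacobian_determinant(jacobian)
  if (is.null(mask)) mask <- array(TRUE, grid$dim)
  if (any(jd[mask] <= 0))
    stop("Jacobian determinant must be positive inside the mask")
  structure(list(phi = phi, jacobian = jacobian, jac_det = jd, grid = grid),
            class = "lcfp_warp")
}

#' Identity warp on a grid
#'
#' phi(r) = r, J = I, |J| = 1: reconstruct in place without spatial
#' normalization (the GQI limit of the reconstruction).
#'
#' @param grid \code{lcfp_grid}.
#' @return \code{lcfp_warp}.
#' @export
identity_warp <- function(grid) {
  w <- grid_index_to_world(grid, grid_index_table(grid))
  phi <- array(0, c(grid$dim, 3L))
  for (a in 1:3) phi[, , , a] <- array(w[, a], grid$dim)
  J <- array(0, c(grid$dim, 3L, 3L))
  for (a in 1:3) J[, , , a, a] <- 1
  diffeo_map(phi, grid, jacobian = J)
}

# d phi_a / d r_b by central differences (one-sided at borders)
finite_difference_jacobian <- function(phi, grid) {
  d <- dim(phi)[1:3]
  J <- array(0, c(d, 3L, 3L))
  for (b in 1:3) {
    h <- grid$spacing[b]
    n <- d[b]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    den <- (hi - lo) * h
    for (a in 1:3) {
      pa <- phi[, , , a, drop = FALSE]
      dim(pa) <- d
      if (b == 1L) {
        dif <- (pa[hi, , , drop = FALSE] - pa[lo, , , drop = FALSE]) / den
      } else if (b == 2L) {
        dif <- aperm(aperm(pa, c(2, 1, 3))[hi, , , drop = FALSE] -
                     aperm(pa, c(2, 1, 3))[lo, , , drop = FALSE], c(2, 1, 3))
        dif <- dif / array(rep(den, each = d[1]), d)
      } else {
        dif <- aperm(aperm(pa, c(3, 2, 1))[hi, , , drop = FALSE] -
                     aperm(pa, c(3, 2, 1))[lo, , , drop = FALSE], c(3, 2, 1))
        dif <- dif / array(rep(den, each = d[1] * d[2]), d)
      }
      J[, , , a, b] <- dif
    }
  }
  J
}

jacobian_determinant <- function(J) {
  d <- dim(J)[1:3]
  g <- function(a, b) { x <- J[, , , a, b, drop = FALSE]; dim(x) <- d; x }
  g(1, 1) * (g(2, 2) * g(3, 3) - g(2, 3) * g(3, 2)) -
  g(1, 2) * (g(2, 1) * g(3, 3) - g(2, 3) * g(3, 1)) +
  g(1, 3) * (g(2, 1) * g(3, 2) - g(2, 2) * g(3, 1))
}

#' Read a displacement-field warp from NIfTI
#'
#' The file stores per-voxel displacement (mm, LPS) from standard to
#' subject space; phi = r + displacement. An optional 9-component Jacobian
#' volume may accompany it, otherwise the Jacobian is computed by central
#' finite differences.
#'
#' @param disp_path 4-D NIfTI with 3 components.
#' @param jacobian_path optional 4-D NIfTI with 9 components (column-major
#'   3x3 per voxel).
#' @return \code{lcfp_warp}.
#' @export
read_warp <- function(disp_path, jacobian_path = NULL) {
  v <- read_nifti_lps(disp_path)
  if (length(dim(v$data)) != 4L || dim(v$data)[4] != 3L)
    stop("displacement field must have 3 components")
  iw <- identity_warp(v$grid)
  phi <- iw$phi + v$data
  jac <- NULL
  if (!is.null(jacobian_path)) {
    jv <- read_nifti_lps(jacobian_path)$data
    if (dim(jv)[4] != 9L) stop("Jacobian volume must have 9 components")
    jac <- array(jv, c(v$grid$dim, 3L, 3L))
  }
  diffeo_map(phi, v$grid, jacobian = jac)
}
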