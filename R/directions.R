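#' Unit sampling directions on the sphere
#'
#' A direction set is a matrix of unit 3-vectors used to sample spin
#' distribution functions. When \code{antipodal = TRUE} the vectors are
#' treated as axes (u and -u are the same direction), the convention used
#' throughout diffusion ODF/SDF sampling.
#'
#' @param units numeric matrix with 3 columns, one unit vector per row.
#' @param antipodal logical; treat directions as axes.
#' @return An object of class \code{lcfp_directions}: the matrix with an
#'   \code{antipodal} attribute.
#' @export
direction_set <- function(units, antipodal = TRUE) {
  units <- as.matrix(units)
  if (ncol(units) != 3L) stop("directions must be 3-vectors")
  nrm <- sqrt(rowSums(units^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  units <- units / nrm
  if (antipodal) {
    # reject duplicate axes
    d <- abs(tcrossprod(units))
    diag(d) <- 0
    if (any(d > 1 - 1e-9)) stop("duplicate axes in antipodal direction set")
  }
  structure(units, antipodal = antipodal, class = c("lcfp_directions", "matrix"))
}

#' Tessellated-icosahedron direction set
#'
#' Vertices of an icosahedron subdivided \code{subdiv} times and projected
#' onto the sphere; with antipodal reduction this gives the classical ODF
#' sampling grids (subdiv 3 gives 642 vertices, 321 axes — the default
#' reconstruction direction set).
#'
#' @param subdiv non-negative integer subdivision level.
#' @param antipodal logical; keep one vector per antipodal pair.
#' @return \code{lcfp_directions} matrix.
#' @export
icosphere_directions <- function(subdiv = 3L, antipodal = TRUE) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    verts <- vector("list", 0L)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1L]] <<- m
      idx <- nv + length(verts)
      mid_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- newf
  }
  if (antipodal) {
    keep <- v[, 3] > 1e-9 |
      (abs(v[, 3]) <= 1e-9 & v[, 2] > 1e-9) |
      (abs(v[, 3]) <= 1e-9 & abs(v[, 2]) <= 1e-9 & v[, 1] > 0)
    v <- v[keep, , drop = FALSE]
  }
  direction_set(v, antipodal = antipodal)
}

#' Quasi-uniform hemisphere directions (Fibonacci lattice)
#'
#' Deterministic near-uniform gradient directions on the upper hemisphere,
#' used as the phantom's diffusion sampling scheme.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors with positive (or zero) z.
#' @export
hemisphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- i / n                 # cos(theta) in (0, 1): upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * (seq_len(n) - 1L)
  cbind(r * cos(th), r * sin(th), z)
}

#' Transport a sampling direction through a Jacobian
#'
#' Maps a standard-space unit direction into subject space as
#' J u / ||J u||, the direction transport used when reconstructing SDFs
#' through a nonlinear warp.
#'
#' @param J 3x3 Jacobian matrix.
#' @param u_hat unit 3-vector.
#' @return unit 3-vector.
#' @export
transport_direction <- function(J, u_hat) {
  v <- as.numeric(J %*% u_hat)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate Jacobian direction")
  v / n
}

# angle (radians) between each row of A and each row of B; axes if antipodal
angular_distance_matrix <- function(A, B, antipodal = TRUE) {
  d <- tcrossprod(A, B)
  if (antipodal) d <- abs(d)
  acos(pmin(pmax(d, -1), 1))
}
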