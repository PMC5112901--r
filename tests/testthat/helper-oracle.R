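# Independent brute-force oracle for the SDF reconstruction sum:
# per voxel r and direction u,
#   psi(u) = |J(r)| / Z0 * sum_i W_i(phi(r)) *
#            sinc(sigma*sqrt(6*D*b_i) * <g_i, J u/||J u||>)
# written as explicit scalar loops, sharing no code path with
# reconstruct_sdf (interpolation done at exact grid points only).
oracle_sdf <- function(dwi, warp, z0, sigma, D_free, dirs) {
  grid <- warp$grid
  d <- grid$dim
  nvol <- dim(dwi$signals)[4]
  ndir <- nrow(dirs)
  out <- matrix(0, prod(d), ndir)
  vox <- 0L
  for (kk in seq_len(d[3])) for (jj in seq_len(d[2])) for (ii in seq_len(d[1])) {
    # linear index in R array order (i fastest)
    lin <- ii + (jj - 1) * d[1] + (kk - 1) * d[1] * d[2]
    # subject-space position and signal (exact voxel assumed for oracle)
    p <- warp$phi[ii, jj, kk, ]
    idx <- round((p - dwi$grid$origin) / dwi$grid$spacing) + 1
    if (any(idx < 1) || any(idx > dwi$grid$dim)) next
    J <- matrix(warp$jacobian[ii, jj, kk, , ], 3, 3)
    jd <- warp$jac_det[ii, jj, kk]
    for (u in seq_len(ndir)) {
      tu <- as.numeric(J %*% dirs[u, ])
      tu <- tu / sqrt(sum(tu^2))
      acc <- 0
      for (i in seq_len(nvol)) {
        w <- dwi$signals[idx[1], idx[2], idx[3], i]
        arg <- sigma * sqrt(6 * D_free * dwi$scheme$b_values[i]) *
          sum(dwi$scheme$directions[i, ] * tu)
        s <- if (abs(arg) < 1e-12) 1 else sin(arg) / arg
        acc <- acc + w * s
      }
      out[lin, u] <- max(0, jd / z0 * acc)
    }
  }
  out
}
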