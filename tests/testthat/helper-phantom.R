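# Shared fixture builders (everything generated in code at test time).

# kinship table: n_per pair-families for each relation given
make_kinship_table <- function(n_per = 30, relations = c("MZ", "DZ", "SIB")) {
  rows <- NULL
  for (r in relations) for (f in seq_len(n_per)) {
    fam <- paste0(r, "fam", f)
    rows <- rbind(rows,
                  data.frame(subject = paste0(r, f, c("a", "b")),
                             family = fam, relation = r))
  }
  rows
}

# full pipeline: population -> normalized fingerprints
phantom_fingerprints <- function(pop, dirs = icosphere_directions(3)) {
  lapply(pop$sessions, function(ss) {
    sdf <- reconstruct_sdf(ss$dwi, dirs = dirs)
    normalize_fingerprint(extract_fingerprint(
      sdf, pop$atlas, ss$subject, ss$session, ss$days))
  })
}

# full-sphere icosahedral scheme (symmetric, antipodal pairs) at one shell
symmetric_scheme <- function(b_value, subdiv = 2) {
  g <- unclass(icosphere_directions(subdiv, antipodal = FALSE))
  gradient_scheme(c(0, rep(b_value, nrow(g))), rbind(c(0, 0, 0), g))
}

# noiseless stick-and-ball signals for a population template on an
# arbitrary scheme (no subject/session effects) -- used to probe
# reconstruction symmetries with schemes the phantom does not emit
synthesize_on_scheme <- function(template, scheme, s0 = 100,
                                 d_axial = 1.7e-3, d_free = 2.51e-3) {
  d <- template$grid$dim
  nvol <- length(scheme$b_values)
  b <- scheme$b_values
  ball <- exp(-b * d_free)
  sig <- matrix(0, prod(d), nvol)
  wm_lin <- which(as.vector(template$wm_mask))
  frac_mat <- matrix(template$fracs, ncol = 3)[wm_lin, , drop = FALSE]
  fib_mat <- matrix(template$fibers, ncol = 9)[wm_lin, , drop = FALSE]
  e <- 0
  for (f in 1:3) {
    vf <- frac_mat[, f]
    if (all(vf == 0)) next
    ef <- fib_mat[, (3 * f - 2):(3 * f), drop = FALSE]
    dots <- ef %*% t(scheme$directions)
    e <- e + vf * exp(-outer(rep(1, length(vf)), b) * d_axial * dots^2)
  }
  e <- e + outer(rep(template$v_iso_wm, length(wm_lin)), ball)
  sig[wm_lin, ] <- s0 * e
  vent_lin <- which(as.vector(template$ventricle_mask))
  sig[vent_lin, ] <- s0 * outer(rep(1, length(vent_lin)), ball)
  array(sig, c(d, nvol))
}

# single-voxel-style isotropic free-water dataset on a small grid
free_water_dwi <- function(scheme, grid_dim = c(3, 3, 3), s0 = 100,
                           D_free = 2.51e-3) {
  grid <- make_grid(grid_dim, c(2, 2, 2))
  att <- s0 * exp(-scheme$b_values * D_free)
  sig <- array(rep(att, each = prod(grid_dim)),
               c(grid_dim, length(scheme$b_values)))
  vent <- array(TRUE, grid_dim)
  dwi_dataset(sig, scheme, grid, ventricle_mask = vent)
}
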