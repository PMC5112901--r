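#' Synthetic population specification for the diffusion phantom
#'
#' Describes a multi-subject, multi-session diffusion MRI study to
#' simulate: fiber geometry, between-subject density variability,
#' within-subject temporal drift, kinship sharing and Rician noise.
#' Defaults emulate a desk-scale repeat-scan identification study:
#' 10 subjects scanned twice, a crossing-fiber template on a 12 x 12 x 8
#' grid, 64 diffusion directions + 1 b0 at b = 2000 s/mm^2, log-normal
#' between-subject density variability, and Rician noise (SNR 10)
#' calibrated so that repeat-scan similarity sits in the 70-80% band
#' typical of real repeat-scan reliability; the kinship sharing defaults
#' then place mean kin-pair similarity near observed twin-study levels
#' (about 12.5% for monozygotic twins, about 5% for dizygotic twins and
#' siblings).
#'
#' @param n_subjects number of subjects.
#' @param sessions_days list (recycled per subject) of session day
#'   offsets; \code{c(0, 30)} means two scans 30 days apart.
#' @param grid_shape voxel counts; \code{voxel_size} mm per axis.
#' @param layout fiber template layout: "crossing-slab", "callosum-arc",
#'   or "uniform-z".
#' @param subject_sd log-scale SD of per-(voxel, fiber) subject density
#'   effects.
#' @param session_sd log-scale SD of per-session density wobble.
#' @param drift_rate fractional whole-voxel density decrease per 100
#'   days.
#' @param drift_sd SD of per-voxel multiplicative spread around the mean
#'   drift (0 = spatially homogeneous drift).
#' @param kinship optional data.frame(subject, family, relation); by
#'   default every subject is its own family (all unrelated).
#' @param rho_mz,rho_dz,rho_sib kinship sharing coefficients in [0, 1]:
#'   correlation of the subject density effect within a kin pair.
#' @param snr signal-to-noise ratio of the white-matter b0 signal (Rician
#'   noise); \code{Inf} disables noise.
#' @param noise_model "rician" (default) or "gaussian".
#' @param n_directions,b_value diffusion scheme to simulate.
#' @param d_axial axial stick diffusivity, mm^2/s.
#' @param d_free free-water diffusivity, mm^2/s.
#' @param s0 b0 signal level, arbitrary units.
#' @param seed mandatory RNG seed.
#' @return object of class \code{lcfp_popspec}.
#' @export
population_spec <- function(n_subjects = 10L,
                            sessions_days = list(c(0, 30)),
                            grid_shape = c(12L, 12L, 8L),
                            voxel_size = c(2, 2, 2),
                            layout = c("crossing-slab", "callosum-arc",
                                       "uniform-z"),
                            subject_sd = 0.15,
                            session_sd = 0,
                            drift_rate = 0,
                            drift_sd = 0,
                            kinship = NULL,
                            rho_mz = 0.25, rho_dz = 0.10, rho_sib = 0.10,
                            snr = 10,
                            noise_model = c("rician", "gaussian"),
                            n_directions = 64L, b_value = 2000,
                            d_axial = 1.7e-3, d_free = 2.51e-3,
                            s0 = 100, seed) {
  layout <- match.arg(layout)
  noise_model <- match.arg(noise_model)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_subjects >= 1L, all(grid_shape >= 3L),
            subject_sd >= 0, session_sd >= 0, drift_sd >= 0,
            rho_mz >= 0, rho_mz <= 1, rho_dz >= 0, rho_dz <= 1,
            rho_sib >= 0, rho_sib <= 1, snr > 0)
  if (!is.list(sessions_days)) sessions_days <- list(sessions_days)
  if (any(unlist(sessions_days) < 0)) stop("day offsets must be >= 0")
  structure(as.list(environment()), class = "lcfp_popspec")
}

#' Build the phantom fiber template and its direction atlas
#'
#' Deterministic fiber layouts on a voxel grid, plus a free-water
#' ventricle block used as the Z0 reference region:
#' \itemize{
#'   \item \code{"uniform-z"}: every white-matter voxel carries one fiber
#'     along z.
#'   \item \code{"crossing-slab"}: two orthogonal slabs (fibers along x
#'     and along y) whose intersection carries both fibers 90 degrees
#'     apart.
#'   \item \code{"callosum-arc"}: a mid-sagittal arc of single fibers
#'     tangent to a semicircle, emulating commissural geometry.
#' }
#' Atlas ranks are ordered by descending base volume fraction.
#'
#' @param grid_shape integer 3-vector (each >= 3).
#' @param layout layout name.
#' @param voxel_size mm per axis.
#' @return list(template, atlas): the template holds grid, masks, fiber
#'   axes and base volume fractions; the atlas is an \code{lcfp_atlas}.
#' @export
make_template <- function(grid_shape,
                          layout = c("crossing-slab", "callosum-arc",
                                     "uniform-z"),
                          voxel_size = c(2, 2, 2)) {
  layout <- match.arg(layout)
  d <- as.integer(grid_shape)
  stopifnot(length(d) == 3L, all(d >= 3L))
  grid <- make_grid(d, voxel_size)
  fibers <- array(0, c(d, 9L))        # up to 3 fibers per voxel
  fracs <- array(0, c(d, 3L))
  wm <- array(FALSE, d)
  # ventricle: small block in the first corner, pure free water
  vent <- array(FALSE, d)
  vent[1:2, 1:2, 1:2] <- TRUE
  interior <- function(n) max(2L, ceiling(n * 0.25)):min(n - 1L, floor(n * 0.85))
  xi <- interior(d[1]); yi <- interior(d[2]); zi <- interior(d[3])
  set_fiber <- function(ix, iy, iz, rank, v, frac) {
    for (a in 1:3)
      fibers[ix, iy, iz, 3 * (rank - 1) + a] <<- v[a]
    fracs[ix, iy, iz, rank] <<- frac
  }
  if (layout == "uniform-z") {
    wm[xi, yi, zi] <- TRUE
    set_fiber(xi, yi, zi, 1L, c(0, 0, 1), 0.8)
  } else if (layout == "crossing-slab") {
    ymid <- yi[seq_len(ceiling(length(yi) / 2))]
    xmid <- xi[seq_len(ceiling(length(xi) / 2))]
    slab_x <- array(FALSE, d); slab_x[xi, ymid, zi] <- TRUE   # fibers along x
    slab_y <- array(FALSE, d); slab_y[xmid, yi, zi] <- TRUE   # fibers along y
    wm <- slab_x | slab_y
    cross <- slab_x & slab_y
    only_x <- slab_x & !cross; only_y <- slab_y & !cross
    for (a in 1:3) {
      fx <- c(1, 0, 0)[a]; fy <- c(0, 1, 0)[a]
      f1 <- fibers[, , , a];     f1[only_x] <- fx; f1[only_y] <- fy
      f1[cross] <- fx
      f2 <- fibers[, , , 3 + a]; f2[cross] <- fy
      fibers[, , , a] <- f1; fibers[, , , 3 + a] <- f2
    }
    fr1 <- fracs[, , , 1]; fr1[only_x | only_y] <- 0.8; fr1[cross] <- 0.45
    fr2 <- fracs[, , , 2]; fr2[cross] <- 0.35
    fracs[, , , 1] <- fr1; fracs[, , , 2] <- fr2
  } else { # callosum-arc: semicircle in the (y, z) plane at mid x
    xs <- max(2L, floor(d[1] / 2))
    cy <- (d[2] + 1) / 2; cz <- 2
    R <- min(d[2] / 2 - 1, d[3] - 2.5)
    for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
      r <- sqrt((iy - cy)^2 + (iz - cz)^2)
      if (abs(r - R) <= 0.75 && iz >= cz) {
        tangent <- c(0, -(iz - cz), iy - cy)
        tn <- sqrt(sum(tangent^2))
        if (tn < 1e-9) next
        wm[xs, iy, iz] <- TRUE
        for (a in 1:3) fibers[xs, iy, iz, a] <- tangent[a] / tn
        fracs[xs, iy, iz, 1] <- 0.8
      }
    }
  }
  wm <- wm & !vent
  # zero out any fibers outside wm (ventricle overlap)
  keep <- array(rep(wm, 9L), c(d, 9L))
  fibers[!keep] <- 0
  fracs[!array(rep(wm, 3L), c(d, 3L))] <- 0
  atlas <- direction_atlas(wm, fibers, grid)
  template <- list(grid = grid, wm_mask = wm, ventricle_mask = vent,
                   brain_mask = wm | vent, fibers = fibers, fracs = fracs,
                   v_iso_wm = 0.2, layout = layout)
  list(template = template, atlas = atlas)
}

# default phantom gradient scheme: one b0 + n quasi-uniform directions
phantom_scheme <- function(n_directions = 64L, b_value = 2000) {
  gradient_scheme(c(0, rep(b_value, n_directions)),
                  rbind(c(0, 0, 0), hemisphere_directions(n_directions)))
}

#' Simulate the phantom population signals
#'
#' Noiseless voxel signal: S0 [ sum_f v_f exp(-b d_a <g, e_f>^2)
#' + v_iso exp(-b D_free) ] (stick-and-ball). Per subject, each
#' (voxel, fiber) density multiplier is v_f exp(eps) with
#' eps ~ N(0, subject_sd^2) decomposed into family-shared and unique
#' parts (eps = sqrt(rho) eps_family + sqrt(1-rho) eps_unique) so kin
#' pairs correlate at rho. Per session, the whole white-matter voxel
#' signal is scaled by (1 - drift_rate * days/100) (optionally spread
#' voxel-wise by drift_sd) and by a log-normal session wobble; Rician
#' noise is applied at the stated b0 SNR. Everything is seeded and
#' reproducible from the population spec and its seed alone.
#'
#' @param spec \code{lcfp_popspec}.
#' @return object of class \code{lcfp_population}: \code{sessions} (list
#'   with subject, session, days, dwi), \code{atlas}, \code{template},
#'   \code{truth} (per-session density multipliers), \code{scheme}.
#' @export
simulate_signals <- function(spec) {
  stopifnot(inherits(spec, "lcfp_popspec"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  tpl <- make_template(spec$grid_shape, spec$layout, spec$voxel_size)
  template <- tpl$template; atlas <- tpl$atlas
  scheme <- phantom_scheme(spec$n_directions, spec$b_value)
  d <- template$grid$dim
  nvox <- prod(d); nvol <- length(scheme$b_values)

  kin <- spec$kinship
  if (is.null(kin))
    kin <- data.frame(subject = paste0("s", seq_len(spec$n_subjects)),
                      family = paste0("f", seq_len(spec$n_subjects)),
                      relation = "NONE")
  if (nrow(kin) != spec$n_subjects) stop("kinship rows must match n_subjects")
  rho_of <- function(rel) switch(as.character(rel),
                                 MZ = spec$rho_mz, DZ = spec$rho_dz,
                                 SIB = spec$rho_sib, 0)

  # per-(voxel, fiber) base fractions for in-mask entries
  wm_lin <- which(as.vector(template$wm_mask))
  frac_mat <- matrix(template$fracs, ncol = 3L)[wm_lin, , drop = FALSE]
  n_entries <- sum(frac_mat > 0)

  # family-shared effects drawn once per family (same draw for co-members)
  fam_ids <- unique(kin$family)
  fam_eps <- lapply(fam_ids, function(f)
    stats::rnorm(n_entries))
  names(fam_eps) <- fam_ids

  # stick-and-ball design matrices
  b <- scheme$b_values
  ball <- exp(-b * spec$d_free)                       # per volume
  fib_mat <- matrix(template$fibers, ncol = 9L)[wm_lin, , drop = FALSE]

  sessions <- list(); truth <- list()
  for (s in seq_len(spec$n_subjects)) {
    rho <- rho_of(kin$relation[s])
    eps <- sqrt(rho) * fam_eps[[kin$family[s]]] +
      sqrt(1 - rho) * stats::rnorm(n_entries)
    mult_subj <- exp(spec$subject_sd * eps)           # per (voxel, fiber)
    days_vec <- spec$sessions_days[[((s - 1L) %% length(spec$sessions_days)) + 1L]]
    # per-voxel drift spread (fixed per subject, mean 1)
    drift_w <- if (spec$drift_sd > 0)
      1 + spec$drift_sd * stats::rnorm(length(wm_lin)) else rep(1, length(wm_lin))
    for (sess in seq_along(days_vec)) {
      days <- days_vec[sess]
      drift <- pmax(0, 1 - spec$drift_rate * drift_w * days / 100)
      wobble <- if (spec$session_sd > 0)
        exp(spec$session_sd * stats::rnorm(1)) else 1
      # assemble per-voxel signals
      sig <- matrix(0, nvox, nvol)
      # white matter: sticks + iso fraction, whole voxel drifts
      mult_full <- matrix(0, length(wm_lin), 3L)
      mult_full[frac_mat > 0] <- mult_subj
      e <- 0
      for (f in 1:3) {
        vf <- frac_mat[, f] * mult_full[, f]
        if (all(vf == 0)) next
        ef <- fib_mat[, (3 * f - 2):(3 * f), drop = FALSE]
        dots <- ef %*% t(scheme$directions)           # n_wm x nvol
        e <- e + vf * exp(-outer(rep(1, length(vf)), b) *
                            spec$d_axial * dots^2)
      }
      e <- e + outer(rep(template$v_iso_wm, length(wm_lin)), ball)
      sig[wm_lin, ] <- spec$s0 * (drift * wobble) * e
      # ventricle: pure free water, no drift
      vent_lin <- which(as.vector(template$ventricle_mask))
      sig[vent_lin, ] <- spec$s0 *
        outer(rep(1, length(vent_lin)), ball)
      # noise
      if (is.finite(spec$snr)) {
        s0_wm <- spec$s0 * (sum(frac_mat[1, ]) + template$v_iso_wm)
        ns <- s0_wm / spec$snr
        inb <- as.vector(template$brain_mask)
        nset <- which(inb)
        n1 <- matrix(stats::rnorm(length(nset) * nvol, sd = ns),
                     length(nset), nvol)
        if (spec$noise_model == "rician") {
          n2 <- matrix(stats::rnorm(length(nset) * nvol, sd = ns),
                       length(nset), nvol)
          sig[nset, ] <- sqrt((sig[nset, , drop = FALSE] + n1)^2 + n2^2)
        } else {
          sig[nset, ] <- pmax(0, sig[nset, , drop = FALSE] + n1)
        }
      }
      dwi <- dwi_dataset(array(sig, c(d, nvol)), scheme, template$grid,
                         brain_mask = template$brain_mask,
                         ventricle_mask = template$ventricle_mask)
      sessions[[length(sessions) + 1L]] <- list(
        subject = kin$subject[s], session = as.character(sess),
        days = days, dwi = dwi)
      truth[[length(truth) + 1L]] <- list(
        subject = kin$subject[s], session = sess,
        multipliers = mult_subj * 1, drift_factor = drift)
    }
  }
  structure(list(sessions = sessions, atlas = atlas, template = template,
                 truth = truth, scheme = scheme, kinship = kin,
                 spec = spec),
            class = "lcfp_population")
}

#' Write a simulated population to disk
#'
#' Emits exactly the inputs the command-line pipeline consumes: one 4-D
#' NIfTI DWI per session, a shared b-table, brain/ventricle/white-matter
#' masks, the direction atlas (fibers + mask), an identity displacement
#' warp, and a manifest CSV (subject_id, session_id, days_offset,
#' dwi_path, plus kinship columns).
#'
#' @param spec \code{lcfp_popspec}.
#' @param out_dir output directory (created if missing).
#' @return the population object, invisibly; files under \code{out_dir}.
#' @export
emit_dataset <- function(spec, out_dir) {
  pop <- simulate_signals(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- pop$template$grid
  write_btable(pop$scheme, file.path(out_dir, "btable.txt"))
  msk <- function(m, nm) write_nifti_lps(array(as.numeric(m), grid$dim),
                                         grid, file.path(out_dir, nm))
  msk(pop$template$brain_mask, "brain_mask.nii.gz")
  msk(pop$template$ventricle_mask, "ventricle_mask.nii.gz")
  msk(pop$template$wm_mask, "wm_mask.nii.gz")
  write_atlas(pop$atlas, file.path(out_dir, "atlas_fibers.nii.gz"),
              file.path(out_dir, "atlas_mask.nii.gz"))
  write_nifti_lps(array(0, c(grid$dim, 3L)), grid,
                  file.path(out_dir, "warp_identity.nii.gz"))
  rows <- NULL
  for (ss in pop$sessions) {
    fn <- sprintf("dwi_%s_%s.nii.gz", ss$subject, ss$session)
    write_nifti_lps(ss$dwi$signals, grid, file.path(out_dir, fn))
    rows <- rbind(rows, data.frame(
      subject_id = ss$subject, session_id = ss$session,
      days_offset = ss$days, dwi_path = fn))
  }
  rows <- merge(rows, pop$kinship, by.x = "subject_id", by.y = "subject",
                sort = FALSE)
  utils::write.csv(rows, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(pop)
}
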