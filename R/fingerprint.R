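#' Extract a local connectome fingerprint
#'
#' Samples the SDF magnitude at every atlas fiber direction of every
#' white-matter voxel and compiles the values into one flat vector in
#' canonical left-posterior-superior voxel order (fiber rank innermost).
#' The SDF value at an atlas direction is taken from the nearest
#' reconstruction direction when the angular gap is at most
#' \code{angle_tol} degrees, otherwise by inverse-angular-distance
#' interpolation over the 3 nearest directions.
#'
#' @param sdf \code{lcfp_sdf} on the atlas grid.
#' @param atlas \code{lcfp_atlas}.
#' @param subject,session subject / session identifiers.
#' @param days days from the subject's first scan (default 0).
#' @param angle_tol nearest-direction tolerance in degrees (default 4).
#' @return object of class \code{lcfp_fingerprint}: \code{values}
#'   (numeric vector), \code{index} (data.frame i, j, k, rank), and
#'   \code{meta} (subject, session, days, atlas_hash, normalized).
#' @export
extract_fingerprint <- function(sdf, atlas, subject = "s1", session = "1",
                                days = 0, angle_tol = 4) {
  stopifnot(inherits(sdf, "lcfp_sdf"), inherits(atlas, "lcfp_atlas"))
  if (!grids_compatible(sdf$grid, atlas$grid))
    stop("SDF and atlas grids do not match")
  index <- atlas_entry_index(atlas)
  if (nrow(index) == 0L) stop("atlas is empty")
  fib <- matrix(atlas$fibers, ncol = dim(atlas$fibers)[4])
  dirvec <- fib[cbind(rep(index$voxel_lin, each = 3L),
                      as.vector(t(cbind(3 * index$rank - 2,
                                        3 * index$rank - 1,
                                        3 * index$rank))))]
  dirs_at <- matrix(dirvec, ncol = 3L, byrow = TRUE)
  ang <- angular_distance_matrix(dirs_at, sdf$dirs, antipodal = TRUE)
  vals <- numeric(nrow(index))
  near3 <- t(apply(ang, 1, order)[1:3, , drop = FALSE])
  a1 <- ang[cbind(seq_len(nrow(ang)), near3[, 1])]
  use_near <- a1 <= angle_tol * pi / 180
  psi <- sdf$values[index$voxel_lin, , drop = FALSE]
  vals[use_near] <- psi[cbind(which(use_near), near3[use_near, 1])]
  if (any(!use_near)) {
    rows <- which(!use_near)
    for (r in rows) {
      w <- 1 / pmax(ang[r, near3[r, ]], 1e-12)
      vals[r] <- sum(w * psi[r, near3[r, ]]) / sum(w)
    }
  }
  structure(list(values = vals, index = index[, c("i", "j", "k", "rank")],
                 meta = list(subject = as.character(subject),
                             session = as.character(session),
                             days = as.numeric(days),
                             atlas_hash = atlas$hash,
                             normalized = FALSE)),
            class = "lcfp_fingerprint")
}

#' Scale a fingerprint to unit variance
#'
#' Density measurements have arbitrary units; the fingerprint is made
#' comparable across scans by dividing the whole compiled sequence by its
#' sample standard deviation (global variance-1 scaling).
#'
#' @param fp \code{lcfp_fingerprint}.
#' @return normalized \code{lcfp_fingerprint}.
#' @export
normalize_fingerprint <- function(fp) {
  stopifnot(inherits(fp, "lcfp_fingerprint"))
  s <- stats::sd(fp$values)
  if (!is.finite(s) || s <= 0) stop("degenerate fingerprint: zero variance")
  fp$values <- fp$values / s
  fp$meta$normalized <- TRUE
  fp
}

#' Restrict a fingerprint to a region mask
#'
#' Retains entries whose voxel lies inside \code{region_mask} (entry
#' order preserved); a normalized input is re-normalized over the kept
#' entries, e.g. the mid-sagittal corpus callosum fingerprint.
#'
#' @param fp \code{lcfp_fingerprint}.
#' @param region_mask logical 3-D array on the atlas grid.
#' @return \code{lcfp_fingerprint}.
#' @export
subset_fingerprint <- function(fp, region_mask) {
  stopifnot(inherits(fp, "lcfp_fingerprint"))
  keep <- region_mask[cbind(fp$index$i, fp$index$j, fp$index$k)]
  if (!any(keep)) stop("region mask selects no fingerprint entries")
  fp$values <- fp$values[keep]
  fp$index <- fp$index[keep, , drop = FALSE]
  rownames(fp$index) <- NULL
  if (isTRUE(fp$meta$normalized)) {
    fp$meta$normalized <- FALSE
    fp <- normalize_fingerprint(fp)
  }
  fp
}

#' Map mean absolute fingerprint differences back to voxel space
#'
#' For each voxel carrying the requested fiber rank, averages
#' |a_e - b_e| over the supplied fingerprint pairs at that entry — the
#' spatial mapping of within- or between-subject differences.
#'
#' @param pairs list of 2-element lists/pairs of \code{lcfp_fingerprint}
#'   sharing one atlas hash.
#' @param atlas the shared \code{lcfp_atlas}.
#' @param rank fiber rank to map (default 1, the first resolved fiber).
#' @return object of class \code{lcfp_diffmap}: \code{values} (3-D
#'   array, background 0) and \code{rank}.
#' @export
difference_map <- function(pairs, atlas, rank = 1L) {
  stopifnot(length(pairs) >= 1L)
  index <- atlas_entry_index(atlas)
  sel <- index$rank == rank
  if (!any(sel)) stop("no atlas entries at the requested fiber rank")
  acc <- numeric(sum(sel))
  for (p in pairs) {
    a <- p[[1]]; b <- p[[2]]
    if (!identical(a$meta$atlas_hash, atlas$hash) ||
        !identical(b$meta$atlas_hash, atlas$hash))
      stop("fingerprint atlas hashes do not match")
    acc <- acc + abs(a$values[sel] - b$values[sel])
  }
  acc <- acc / length(pairs)
  vol <- array(0, atlas$grid$dim)
  vol[cbind(index$i[sel], index$j[sel], index$k[sel])] <- acc
  structure(list(values = vol, grid = atlas$grid, rank = rank),
            class = "lcfp_diffmap")
}

#' Write / read a fingerprint container
#'
#' Single-file CSV layout (entry, x, y, z, rank, value) plus a JSON
#' sidecar holding the metadata (subject, session, days, atlas hash,
#' normalized flag).
#'
#' @param fp \code{lcfp_fingerprint}.
#' @param path CSV path; sidecar is \code{paste0(path, ".json")}.
#' @export
write_fingerprint <- function(fp, path) {
  df <- data.frame(entry = seq_along(fp$values),
                   x = fp$index$i, y = fp$index$j, z = fp$index$k,
                   rank = fp$index$rank, value = fp$values)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(fp$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(values = df$value,
                 index = data.frame(i = df$x, j = df$y, k = df$z,
                                    rank = df$rank),
                 meta = meta),
            class = "lcfp_fingerprint")
}
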