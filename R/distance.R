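#' Root-mean-squared-error distance between two fingerprints
#'
#' The single difference estimate between two scans:
#' sqrt(mean((a - b)^2)). Accepts \code{lcfp_fingerprint} objects (with
#' atlas-hash and normalization-state checks) or plain equal-length
#' numeric vectors, so any external feature vector (diffusivity map,
#' flattened connectivity matrix) can be run through the same distance
#' layer.
#'
#' @param a,b fingerprints or numeric vectors.
#' @return non-negative scalar.
#' @export
rmse_distance <- function(a, b) {
  if (inherits(a, "lcfp_fingerprint") && inherits(b, "lcfp_fingerprint")) {
    if (!identical(a$meta$atlas_hash, b$meta$atlas_hash))
      stop("fingerprints come from different atlases")
    if (!identical(isTRUE(a$meta$normalized), isTRUE(b$meta$normalized)))
      stop("fingerprints differ in normalization state")
    a <- a$values; b <- b$values
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("feature vectors differ in length")
  sqrt(mean((a - b)^2))
}

#' Pairwise distance matrix over scans
#'
#' @param features list of \code{lcfp_fingerprint}s, or a numeric matrix
#'   with one scan per row.
#' @param labels data.frame with columns \code{subject}, \code{session}
#'   and optionally \code{days}; taken from fingerprint metadata when
#'   absent.
#' @return object of class \code{lcfp_distmat}: symmetric \code{values}
#'   matrix with zero diagonal and a \code{labels} data.frame.
#' @export
distance_matrix <- function(features, labels = NULL) {
  if (is.list(features) && all(vapply(features, inherits, TRUE,
                                      "lcfp_fingerprint"))) {
    if (is.null(labels))
      labels <- data.frame(
        subject = vapply(features, function(f) f$meta$subject, ""),
        session = vapply(features, function(f) f$meta$session, ""),
        days = vapply(features, function(f) as.numeric(f$meta$days), 0))
    hashes <- vapply(features, function(f) as.character(f$meta$atlas_hash), "")
    if (length(unique(hashes)) > 1L)
      stop("fingerprints come from different atlases")
    mat <- do.call(rbind, lapply(features, `[[`, "values"))
  } else {
    mat <- as.matrix(features)
    if (is.null(labels)) stop("labels required for plain feature matrices")
  }
  if (nrow(mat) != nrow(labels)) stop("labels do not match feature rows")
  d <- as.matrix(stats::dist(mat)) / sqrt(ncol(mat))  # dist is sqrt(sum sq)
  dimnames(d) <- NULL
  structure(list(values = d, labels = labels), class = "lcfp_distmat")
}

#' Partition pairwise distances into within- and between-subject sets
#'
#' Every unordered off-diagonal pair is classified once: within when both
#' scans share a subject id, between otherwise.
#'
#' @param dm \code{lcfp_distmat}.
#' @return object of class \code{lcfp_pairdiff}: \code{within},
#'   \code{between} (numeric), and \code{pair_index} (data.frame row, col,
#'   type).
#' @export
partition_differences <- function(dm) {
  stopifnot(inherits(dm, "lcfp_distmat"))
  lab <- dm$labels
  if (nrow(lab) < 2L) stop("at least two sessions required")
  if (anyDuplicated(paste(lab$subject, lab$session, sep = "\r")))
    stop("duplicate (subject, session) labels")
  n <- nrow(lab)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- lab$subject[pr[, 1]] == lab$subject[pr[, 2]]
  vals <- dm$values[pr]
  structure(list(
    within = vals[same], between = vals[!same],
    pair_index = data.frame(row = pr[, 1], col = pr[, 2],
                            type = ifelse(same, "within", "between"))),
    class = "lcfp_pairdiff")
}

#' Write a distance matrix as CSV
#'
#' Row/column names are \code{subject_session}.
#'
#' @param dm \code{lcfp_distmat}.
#' @param path CSV path.
#' @export
write_distance_matrix <- function(dm, path) {
  nm <- paste(dm$labels$subject, dm$labels$session, sep = "_")
  m <- dm$values
  dimnames(m) <- list(nm, nm)
  utils::write.csv(m, path)
  invisible(path)
}
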