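#' Diffusion gradient scheme
#'
#' Per-volume diffusion weighting: b-value (s/mm^2) and unit gradient
#' direction. Volumes with b below \code{b0_threshold} are b0 (non
#' diffusion-weighted) images.
#'
#' @param b_values numeric vector of b-values, s/mm^2.
#' @param directions matrix (n x 3) of gradient directions; rows for b0
#'   volumes may be zero.
#' @param b0_threshold b-values at or below this count as b0 (default 50).
#' @return object of class \code{lcfp_scheme}.
#' @export
gradient_scheme <- function(b_values, directions, b0_threshold = 50) {
  b_values <- as.numeric(b_values)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must have 3 columns")
  if (length(b_values) != nrow(directions))
    stop("b_values and directions must have equal length")
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b-values must be finite and non-negative")
  b0 <- b_values <= b0_threshold
  if (!any(b0)) stop("scheme must contain at least one b0 volume")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm[!b0] - 1) > 1e-6))
    stop("diffusion-weighted directions must be unit vectors")
  directions[!b0, ] <- directions[!b0, , drop = FALSE] / nrm[!b0]
  structure(list(b_values = b_values, directions = directions, b0 = b0),
            class = "lcfp_scheme")
}

#' Read / write a b-table
#'
#' Plain-text b-table with one row per volume: \code{b gx gy gz},
#' whitespace separated (DSI-Studio style).
#'
#' @param path file path.
#' @return \code{read_btable}: an \code{lcfp_scheme}.
#' @export
read_btable <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   col.names = c("b", "gx", "gy", "gz")))
  gradient_scheme(m[, 1], m[, 2:4])
}

#' @rdname read_btable
#' @param scheme an \code{lcfp_scheme}.
#' @export
write_btable <- function(scheme, path) {
  m <- cbind(scheme$b_values, scheme$directions)
  utils::write.table(format(m, digits = 10, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
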