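#' d-prime separation of two difference distributions
#'
#' Standardized separation between the between-subject and
#' within-subject distance distributions:
#' (mean(between) - mean(within)) / sqrt((var(between) + var(within))/2),
#' with sample (n - 1) variances.
#'
#' @param within,between numeric vectors (each length >= 2).
#' @return scalar d-prime.
#' @export
dprime <- function(within, between) {
  if (length(within) < 2L || length(between) < 2L)
    stop("both difference sets need at least 2 values")
  (mean(between) - mean(within)) /
    sqrt((stats::var(between) + stats::var(within)) / 2)
}

# 1-D two-class LDA on distances: shared pooled variance, configurable priors.
# Returns a classifier function mapping x -> TRUE (within) / FALSE (between).
lda_fit_1d <- function(within, between, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  nw <- length(within); nb <- length(between)
  if (nw < 1L || nb < 1L) stop("a training fold has an empty class")
  mw <- mean(within); mb <- mean(between)
  s2 <- (sum((within - mw)^2) + sum((between - mb)^2)) / (nw + nb - 2)
  pw <- if (priors == "empirical") nw / (nw + nb) else 0.5
  pb <- 1 - pw
  function(x) {
    dw <- x * mw / s2 - mw^2 / (2 * s2) + log(pw)
    db <- x * mb / s2 - mb^2 / (2 * s2) + log(pb)
    dw > db
  }
}

#' Leave-one-out cross-validated LDA classification of scan pairs
#'
#' Each pairwise distance is held out in turn; a 1-D linear discriminant
#' (shared pooled variance) is fit on the remaining distances and used to
#' classify the held-out pair as within- or between-subject. Reports the
#' misclassification count and rate over all pairs.
#'
#' @param diffs \code{lcfp_pairdiff} (or list with \code{within},
#'   \code{between}).
#' @param priors "empirical" (class-frequency, the default of standard
#'   LDA implementations) or "equal".
#' @return list(errors, n, rate).
#' @export
lda_loocv <- function(diffs, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  w <- diffs$within; b <- diffs$between
  if (length(w) < 1L || length(b) < 1L) stop("both classes must be non-empty")
  err <- 0L
  for (i in seq_along(w)) {
    cl <- lda_fit_1d(w[-i], b, priors)
    if (!cl(w[i])) err <- err + 1L
  }
  for (i in seq_along(b)) {
    cl <- lda_fit_1d(w, b[-i], priors)
    if (cl(b[i])) err <- err + 1L
  }
  n <- length(w) + length(b)
  list(errors = err, n = n, rate = err / n)
}

#' Full identification analysis of a scan collection
#'
#' Runs the identification layer end-to-end on a distance matrix:
#' within/between partition, d-prime, LOOCV-LDA classification error, GEV
#' fits of both difference distributions (shape constrained positive),
#' and the GEV-modeled classification error P(within > between).
#'
#' @param dm \code{lcfp_distmat}.
#' @param priors LDA priors, see \code{\link{lda_loocv}}.
#' @return object of class \code{lcfp_ident_report}.
#' @export
identification_report <- function(dm, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  diffs <- partition_differences(dm)
  loocv <- lda_loocv(diffs, priors)
  gw <- fit_gev(diffs$within)
  gb <- fit_gev(diffs$between)
  structure(list(
    n_within = length(diffs$within), n_between = length(diffs$between),
    dprime = dprime(diffs$within, diffs$between),
    loocv_errors = loocv$errors, loocv_n = loocv$n, loocv_rate = loocv$rate,
    gev_within = gw, gev_between = gb,
    modeled_error = gev_classification_error(gw, gb)),
    class = "lcfp_ident_report")
}

#' @export
print.lcfp_ident_report <- function(x, ...) {
  cat("Identification report\n")
  cat(sprintf("  pairs: %d within, %d between\n", x$n_within, x$n_between))
  cat(sprintf("  d-prime: %.3f\n", x$dprime))
  cat(sprintf("  LOOCV: %d / %d misclassified (rate %.4g)\n",
              x$loocv_errors, x$loocv_n, x$loocv_rate))
  cat(sprintf("  GEV within:  k=%.4f sigma=%.4g mu=%.4g\n",
              x$gev_within$k, x$gev_within$sigma, x$gev_within$mu))
  cat(sprintf("  GEV between: k=%.4f sigma=%.4g mu=%.4g\n",
              x$gev_between$k, x$gev_between$sigma, x$gev_between$mu))
  cat(sprintf("  modeled classification error: %.4g\n", x$modeled_error))
  invisible(x)
}
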