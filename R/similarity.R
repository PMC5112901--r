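#' Expected unrelated-subject distance
#'
#' d0: the mean of between-subject distances under the same protocol.
#' When a kinship table is supplied, pairs of subjects from the same
#' family (twins, siblings) are excluded so that d0 reflects genetically
#' unrelated pairs only.
#'
#' @param dm \code{lcfp_distmat}.
#' @param kinship optional data.frame(subject, family) mapping subject
#'   ids to family ids.
#' @return positive scalar.
#' @export
expected_unrelated_distance <- function(dm, kinship = NULL) {
  diffs <- partition_differences(dm)
  pi <- diffs$pair_index
  sel <- pi$type == "between"
  if (!is.null(kinship)) {
    fam <- kinship$family[match(dm$labels$subject, kinship$subject)]
    same_fam <- !is.na(fam[pi$row]) & !is.na(fam[pi$col]) &
      fam[pi$row] == fam[pi$col]
    sel <- sel & !same_fam
  }
  if (!any(sel)) stop("no qualifying unrelated pairs")
  mean(dm$values[cbind(pi$row[sel], pi$col[sel])])
}

#' Similarity index
#'
#' 100 * (1 - d1/d0): a pair's distance d1 relative to the expected
#' unrelated-subject distance d0. 100 means identical fingerprints; 0
#' means as different as unrelated subjects; negative values are
#' possible.
#'
#' @param d1 pair distance (>= 0).
#' @param d0 expected unrelated distance (> 0).
#' @return percent.
#' @export
similarity_index <- function(d1, d0) {
  if (any(d0 <= 0)) stop("d0 must be positive")
  if (any(d1 < 0)) stop("d1 must be non-negative")
  100 * (1 - d1 / d0)
}

#' Mann-Kendall trend test
#'
#' S = sum over time-ordered pairs of sign(value_j - value_i). The
#' two-sided p-value uses the normal approximation with tie-corrected
#' variance and continuity correction; for n <= 10 with no tied values
#' the exact null distribution of S is used instead.
#'
#' @param time,value numeric vectors (n >= 3; times not all equal).
#' @return list(S, p_value, n).
#' @export
mann_kendall <- function(time, value) {
  stopifnot(length(time) == length(value))
  n <- length(value)
  if (n < 3L) stop("Mann-Kendall needs at least 3 points")
  if (length(unique(time)) < 2L) stop("times are all equal")
  ord <- order(time)
  v <- value[ord]
  sgn <- sign(outer(v, v, `-`))
  S <- sum(sgn[upper.tri(sgn)] * -1)    # pairs (i<j): sign(v_j - v_i)
  ties <- table(v)
  no_ties <- all(ties == 1L)
  if (n <= 10L && no_ties) {
    p <- mk_exact_p(S, n)
  } else {
    t <- as.numeric(ties)
    varS <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
    z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(S = S, p_value = min(1, p), n = n)
}

# exact two-sided P(|S| >= |s|) under the permutation null (no ties):
# S = C(n,2) - 2 * inversions; inversion counts follow the Mahonian
# distribution, built by iterated polynomial convolution.
mk_exact_p <- function(s, n) {
  counts <- 1
  for (i in 1:(n - 1)) {
    counts <- stats::convolve(c(counts, numeric(i)), rev(rep(1, i + 1)),
                              type = "open")
  }
  counts <- round(counts)            # counts[m+1] = # permutations with m inversions
  m <- seq_along(counts) - 1
  Svals <- choose(n, 2) - 2 * m
  sum(counts[abs(Svals) >= abs(s)]) / sum(counts)
}

#' Similarity trend slope
#'
#' Ordinary least-squares slope of similarity (%) against time,
#' expressed per 100 days.
#'
#' @param days,similarity numeric vectors.
#' @return slope in percent per 100 days.
#' @export
similarity_slope <- function(days, similarity) {
  stopifnot(length(days) == length(similarity))
  if (length(unique(days)) < 2L) stop("need at least 2 distinct times")
  unname(stats::coef(stats::lm(similarity ~ days))[2] * 100)
}

#' Kruskal-Wallis omnibus test over similarity groups
#'
#' Rank-based H statistic with tie correction (delegated to
#' \code{stats::kruskal.test}); df = number of groups - 1.
#'
#' @param groups named list of numeric vectors.
#' @return list(chi2, df, p_value, n).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  kt <- stats::kruskal.test(groups)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = sum(lengths(groups)))
}

#' Scheffe simultaneous pairwise comparisons
#'
#' Scheffe's S procedure applied, by default, to rank-transformed values
#' (keeping the family coherent with the Kruskal-Wallis omnibus); a
#' classic raw-value variant is available. For each group pair the
#' statistic (mdiff^2 / (MSE (1/ni + 1/nj))) / (g - 1) is referred to an
#' F(g - 1, N - g) distribution.
#'
#' @param groups named list of numeric vectors (>= 3 groups).
#' @param on "ranks" (default) or "raw".
#' @return data.frame(group1, group2, p_value).
#' @export
scheffe_posthoc <- function(groups, on = c("ranks", "raw")) {
  on <- match.arg(on)
  g <- length(groups)
  if (g < 3L) stop("Scheffe post-hoc needs at least 3 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(g))
  pooled <- unlist(groups, use.names = FALSE)
  if (on == "ranks") pooled <- rank(pooled)
  idx <- rep(seq_len(g), lengths(groups))
  N <- length(pooled)
  m <- tapply(pooled, idx, mean)
  ni <- as.numeric(table(idx))
  sse <- sum((pooled - m[idx])^2)
  mse <- sse / (N - g)
  out <- NULL
  for (a in 1:(g - 1)) for (b in (a + 1):g) {
    Fab <- (m[a] - m[b])^2 / (mse * (1 / ni[a] + 1 / ni[b])) / (g - 1)
    out <- rbind(out, data.frame(
      group1 = nm[a], group2 = nm[b],
      p_value = stats::pf(Fab, g - 1, N - g, lower.tail = FALSE)))
  }
  rownames(out) <- NULL
  out
}

#' Permutation tests over similarity groups
#'
#' Shuffles group labels over the pooled values. Statistics:
#' \code{"kruskal_wallis_chi2"} (omnibus; one p-value) or
#' \code{"pairwise_mean_diff"} (absolute mean difference for every group
#' pair). The p-value uses the add-one estimator
#' (1 + #\{permuted >= observed\}) / (1 + n_perm), so it is never exactly
#' zero.
#'
#' @param groups named list of numeric vectors.
#' @param statistic which statistic to permute.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return data.frame(comparison, observed, p_value).
#' @export
permutation_test <- function(groups,
                             statistic = c("kruskal_wallis_chi2",
                                           "pairwise_mean_diff"),
                             n_perm = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_along(groups), lengths(groups))
  if (statistic == "kruskal_wallis_chi2") {
    r <- rank(pooled)                 # ranks invariant under label shuffles
    ties <- table(r)
    corr <- 1 - sum(ties^3 - ties) / (length(r)^3 - length(r))
    obs <- kw_chi2_ranked(r, idx, corr)
    cnt <- 0L
    for (p in seq_len(n_perm))
      if (kw_chi2_ranked(r, sample(idx), corr) >= obs) cnt <- cnt + 1L
    data.frame(comparison = "omnibus", observed = obs,
               p_value = (1 + cnt) / (1 + n_perm))
  } else {
    pairs <- utils::combn(seq_along(groups), 2)
    out <- NULL
    for (cix in seq_len(ncol(pairs))) {
      a <- pairs[1, cix]; b <- pairs[2, cix]
      x <- c(groups[[a]], groups[[b]])
      la <- lengths(groups)[a]
      obs <- abs(mean(x[seq_len(la)]) - mean(x[-seq_len(la)]))
      tot <- sum(x)
      cnt <- 0L
      for (p in seq_len(n_perm)) {
        sa <- sum(x[sample.int(length(x), la)])
        st <- abs(sa / la - (tot - sa) / (length(x) - la))
        if (st >= obs - 1e-12) cnt <- cnt + 1L
      }
      out <- rbind(out, data.frame(
        comparison = paste(nm[a], "vs", nm[b]), observed = obs,
        p_value = (1 + cnt) / (1 + n_perm)))
    }
    out
  }
}

# tie-corrected Kruskal-Wallis chi2 from precomputed pooled ranks
kw_chi2_ranked <- function(r, idx, corr = NULL) {
  N <- length(r)
  sums <- rowsum(r, idx)
  ni <- tabulate(idx)
  H <- 12 / (N * (N + 1)) * sum(sums^2 / ni) - 3 * (N + 1)
  if (is.null(corr)) {
    ties <- table(r)
    corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  }
  if (corr > 0) H / corr else H
}

#' Longitudinal similarity analysis of repeat scans
#'
#' For every within-subject scan pair, computes the similarity index
#' relative to the expected unrelated-subject distance, then tests the
#' similarity-vs-interval trend (Mann-Kendall) and fits the linear slope
#' per 100 days.
#'
#' @param dm \code{lcfp_distmat} whose labels carry a \code{days} column.
#' @return object of class \code{lcfp_trend}: per-pair records plus
#'   \code{S}, \code{p_value}, \code{slope_per_100_days}, \code{d0}.
#' @export
similarity_trend <- function(dm) {
  diffs <- partition_differences(dm)
  if (length(diffs$within) < 3L) stop("need >= 3 within-subject pairs")
  d0 <- expected_unrelated_distance(dm)
  pi <- diffs$pair_index
  wi <- pi[pi$type == "within", ]
  interval <- abs(dm$labels$days[wi$row] - dm$labels$days[wi$col])
  sim <- similarity_index(dm$values[cbind(wi$row, wi$col)], d0)
  mk <- mann_kendall(interval, sim)
  structure(list(
    records = data.frame(row = wi$row, col = wi$col,
                         interval_days = interval, similarity = sim),
    d0 = d0, S = mk$S, p_value = mk$p_value,
    slope_per_100_days = similarity_slope(interval, sim)),
    class = "lcfp_trend")
}

#' Kinship group comparison of similarity indices
#'
#' Builds per-pair similarity records for MZ twin, DZ twin, non-twin
#' sibling and unrelated pairs, then runs the Kruskal-Wallis omnibus,
#' Scheffe post-hoc and permutation tests.
#'
#' @param dm \code{lcfp_distmat} (one scan per subject).
#' @param kinship data.frame(subject, family, relation) with relation in
#'   MZ, DZ, SIB, NONE; co-members of a family with relation MZ/DZ/SIB
#'   form a kin pair.
#' @param n_perm,seed permutation settings.
#' @return object of class \code{lcfp_kinship}: \code{groups} (named
#'   list of similarity values), \code{kw}, \code{scheffe},
#'   \code{perm_omnibus}, \code{perm_pairwise}, \code{d0}.
#' @export
kinship_groups <- function(dm, kinship, n_perm = 10000L, seed = 1L) {
  d0 <- expected_unrelated_distance(dm, kinship)
  diffs <- partition_differences(dm)
  pi <- diffs$pair_index
  bt <- pi[pi$type == "between", ]
  fam <- kinship$family[match(dm$labels$subject, kinship$subject)]
  rel <- kinship$relation[match(dm$labels$subject, kinship$subject)]
  same_fam <- !is.na(fam[bt$row]) & !is.na(fam[bt$col]) &
    fam[bt$row] == fam[bt$col]
  grp <- ifelse(same_fam, as.character(rel[bt$row]), "NONE")
  sim <- similarity_index(dm$values[cbind(bt$row, bt$col)], d0)
  groups <- split(sim, factor(grp, levels = c("MZ", "DZ", "SIB", "NONE")))
  groups <- groups[lengths(groups) > 0L]
  structure(list(
    groups = groups, d0 = d0,
    kw = kruskal_wallis(groups),
    scheffe = scheffe_posthoc(groups),
    perm_omnibus = permutation_test(groups, "kruskal_wallis_chi2",
                                    n_perm, seed),
    perm_pairwise = permutation_test(groups, "pairwise_mean_diff",
                                     n_perm, seed + 1L)),
    class = "lcfp_kinship")
}
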