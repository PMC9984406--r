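# Two-group tests for heterogeneous samples: Welch t, Mann-Whitney U with an
# exact tied null, TNOM, and InfoScore.  The three rank-based nulls condition
# on the observed value multiset: they are distributions over the C(n, n1)
# equally likely assignments of group labels to the pooled observed values.

#' Welch two-sample t test p value
#'
#' Two-sided p with Welch-Satterthwaite degrees of freedom.  Degenerate
#' inputs follow a documented convention: when both groups have zero variance
#' the p value is 1 for equal means and 0 for different means.
#'
#' @param x,y numeric samples (each length >= 2).
#' @return two-sided p value.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t needs at least two observations per group")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

# ---------------------------------------------------------------------------
# Mann-Whitney U

# U statistic for group x (ties count 1/2), returned doubled so it is integer
mwu_2u <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + 2 * sum(xi > y) + sum(xi == y)
  s
}

# tie-group sizes of the pooled sample, ascending
tie_groups <- function(values) {
  as.integer(table(factor(values, levels = sort(unique(values)))))
}

# Exact null distribution of 2U over label assignments, conditioning on the
# observed (possibly tied) values.  Returns counts indexed by 2U = 0..2*n1*n2.
mwu_exact_null <- function(groups, n1) {
  n <- sum(groups)
  n2 <- n - n1
  maxu <- 2 * n1 * n2
  # dp[[k + 1]] = counts over 2U given k group-1 labels placed so far
  dp <- lapply(seq_len(n1 + 1), function(i) numeric(maxu + 1))
  dp[[1]][1] <- 1
  processed <- 0L
  for (g in groups) {
    ndp <- lapply(seq_len(n1 + 1), function(i) numeric(maxu + 1))
    for (k in 0:min(n1, processed)) {
      v <- dp[[k + 1]]
      nzi <- which(v > 0)
      if (length(nzi) == 0) next
      prev_g2 <- processed - k
      for (ka in 0:min(g, n1 - k)) {
        du <- 2 * ka * prev_g2 + ka * (g - ka)
        w <- choose(g, ka)
        tgt <- nzi + du
        ndp[[k + ka + 1]][tgt] <- ndp[[k + ka + 1]][tgt] + w * v[nzi]
      }
    }
    dp <- ndp
    processed <- processed + g
  }
  dp[[n1 + 1]]
}

#' Mann-Whitney U test p value
#'
#' Two-sided p for the hypothesis that the two samples come from the same
#' distribution.  With at most `exact_max` observations in total the null is
#' exact: the distribution of U over all equally likely label assignments of
#' the pooled observed values (ties handled by conditioning on the value
#' multiset).  Larger samples use the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples (each length >= 1).
#' @param exact_max exact-null size limit (default 64).
#' @return two-sided p value.
#' @export
mann_whitney <- function(x, y, exact_max = 64L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u2 <- mwu_2u(x, y)
  if (n <= exact_max) {
    null <- mwu_exact_null(tie_groups(c(x, y)), n1)
    dev <- abs(seq(0, 2 * n1 * n2) - n1 * n2)
    p <- sum(null[dev >= abs(u2 - n1 * n2)]) / sum(null)
    return(min(1, p))
  }
  # asymptotic with tie and continuity correction
  u <- u2 / 2
  mu <- n1 * n2 / 2
  tg <- tie_groups(c(x, y))
  tie_term <- sum(tg^3 - tg) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# ---------------------------------------------------------------------------
# TNOM

# A threshold never splits equal values: candidate cuts are tie-group
# boundaries of the pooled sorted values (including the two ends).
# Prefix label counts per tie group for the observed labelling.
observed_prefixes <- function(x, y) {
  vals <- sort(unique(c(x, y)))
  ka <- cumsum(vapply(vals, function(v) sum(x == v), numeric(1)))
  kb <- cumsum(vapply(vals, function(v) sum(y == v), numeric(1)))
  list(groups = vapply(vals, function(v) sum(x == v) + sum(y == v),
                       numeric(1)),
       ka = c(0, ka), kb = c(0, kb))  # cuts: before group 1 .. after last
}

#' Total Number of Mistakes (TNOM) statistic and p value
#'
#' TNOM is the minimum number of misclassified observations over all single
#' thresholds on the pooled values (both orientations).  The p value is
#' P(TNOM <= observed) over all equally likely assignments of the group
#' labels to the observed values.
#'
#' @param x,y numeric samples (each length >= 1).
#' @return list with `statistic` and `p.value`.
#' @export
tnom <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pref <- observed_prefixes(x, y)
  mistakes <- pmin(pref$ka + (n2 - pref$kb), pref$kb + (n1 - pref$ka))
  stat <- min(mistakes)
  p <- label_null_prob(pref$groups, n1, n2,
                       absorb = function(k, P) {
                         min(k + (n2 - (P - k)), (P - k) + (n1 - k)) <= stat
                       })
  list(statistic = stat, p.value = p)
}

# ---------------------------------------------------------------------------
# InfoScore

binary_entropy <- function(p) {
  p <- p[p > 0 & p < 1]
  h <- 0
  if (length(p)) h <- -sum(c(p, 1 - p) * log2(c(p, 1 - p)))
  h
}

# mutual information (bits) between threshold side and label for a cut with
# k group-1 of P pooled observations on the left
cut_mutual_information <- function(k, P, n1, n2) {
  n <- n1 + n2
  h_label <- binary_entropy(n1 / n)
  h_cond <- 0
  if (P > 0) h_cond <- h_cond + P / n * binary_entropy(k / P)
  if (P < n) h_cond <- h_cond + (n - P) / n * binary_entropy((n1 - k) / (n - P))
  h_label - h_cond
}

#' InfoScore statistic and p value
#'
#' InfoScore is the maximum, over single thresholds on the pooled values, of
#' the mutual information (bits) between the side of the threshold and the
#' group label.  The p value is P(InfoScore >= observed) over all equally
#' likely label assignments, evaluated by dynamic programming over lattice
#' paths.
#'
#' @param x,y numeric samples (each length >= 1).
#' @return list with `statistic` and `p.value`.
#' @export
infoscore <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pref <- observed_prefixes(x, y)
  mis <- vapply(seq_along(pref$ka), function(i) {
    cut_mutual_information(pref$ka[i], pref$ka[i] + pref$kb[i], n1, n2)
  }, numeric(1))
  stat <- max(mis)
  tol <- 1e-9
  p <- label_null_prob(pref$groups, n1, n2,
                       absorb = function(k, P) {
                         cut_mutual_information(k, P, n1, n2) >= stat - tol
                       })
  list(statistic = stat, p.value = p)
}

# Probability, over the C(n, n1) equally likely label assignments to the
# observed value multiset, that some valid threshold (a tie-group boundary)
# satisfies `absorb(k, P)` where k = group-1 labels left of the cut and P =
# pooled observations left of the cut.  Absorbing DP over tie groups.
label_null_prob <- function(groups, n1, n2, absorb) {
  n <- n1 + n2
  if (absorb(0, 0)) return(1)
  # state: number of group-1 labels among processed values, counts of paths
  dp <- numeric(n1 + 1)
  dp[1] <- 1
  absorbed <- 0
  processed <- 0
  for (g in groups) {
    ndp <- numeric(n1 + 1)
    for (k in 0:min(n1, processed)) {
      if (dp[k + 1] == 0) next
      # group-2 labels used so far = processed - k; never exceed n2
      ka_min <- max(0, g - (n2 - (processed - k)))
      if (ka_min > min(g, n1 - k)) next
      for (ka in ka_min:min(g, n1 - k)) {
        ndp[k + ka + 1] <- ndp[k + ka + 1] + choose(g, ka) * dp[k + 1]
      }
    }
    processed <- processed + g
    # check the cut after this tie group; an absorbed partial assignment
    # stands for all its completions over the remaining values
    for (k in 0:min(n1, processed)) {
      if (ndp[k + 1] > 0 && absorb(k, processed)) {
        absorbed <- absorbed + ndp[k + 1] * choose(n - processed, n1 - k)
        ndp[k + 1] <- 0
      }
    }
    dp <- ndp
  }
  absorbed / choose(n, n1)
}

# ---------------------------------------------------------------------------
# HET test over posterior PSI

HET_STATS <- c("welch", "mwu", "tnom", "infoscore")

het_stat_p <- function(stat, x, y) {
  switch(stat,
         welch = welch_t(x, y),
         mwu = mann_whitney(x, y),
         tnom = tnom(x, y)$p.value,
         infoscore = infoscore(x, y)$p.value,
         stop("unknown statistic: ", stat))
}

# nearest-rank empirical quantile
nearest_rank_quantile <- function(p, q = 0.95) {
  sort(p)[ceiling(q * length(p))]
}

#' Heterogeneous two-group test for one LSV edge
#'
#' Each experiment carries its own posterior PSI distribution.  For each of
#' `n_rep` repetitions one PSI value is drawn per experiment from its
#' discretized posterior and every requested statistic's p value computed;
#' the reported `p_quantile` is the nearest-rank 95th percentile over the
#' repetitions.  `p_mean` applies each test to the posterior means.  Group
#' medians of the posterior means and their difference are reported
#' alongside.
#'
#' @param dens1,dens2 matrices (experiments x B) of discretized posterior
#'   densities for the edge in group 1 / group 2; rows of unquantifiable
#'   experiments must already be dropped.
#' @param means1,means2 posterior means per experiment.
#' @param grid the PSI grid (see [psi_grid()]).
#' @param stats character subset of `c("welch","mwu","tnom","infoscore")`.
#' @param n_rep number of PSI samplings (default 30).
#' @param seed integer seed.
#' @param q quantile reported over repetitions (default 0.95).
#' @return list of class `het_result` with `p_quantile`, `p_mean` (named per
#'   statistic), `median1`, `median2`, `median_diff`.
#' @export
het_test <- function(dens1, means1, dens2, means2, grid = psi_grid(40L),
                     stats = HET_STATS, n_rep = 30L, seed = 1L, q = 0.95) {
  n1 <- nrow(dens1); n2 <- nrow(dens2)
  if (n1 == 0 || n2 == 0) stop("both groups need quantified experiments")
  set.seed(seed)
  pmat <- matrix(NA_real_, n_rep, length(stats),
                 dimnames = list(NULL, stats))
  for (rep in seq_len(n_rep)) {
    s1 <- vapply(seq_len(n1), function(i)
      grid$centers[sample.int(grid$B, 1, prob = dens1[i, ])], numeric(1))
    s2 <- vapply(seq_len(n2), function(i)
      grid$centers[sample.int(grid$B, 1, prob = dens2[i, ])], numeric(1))
    for (st in stats) pmat[rep, st] <- het_stat_p(st, s1, s2)
  }
  p_quantile <- apply(pmat, 2, nearest_rank_quantile, q = q)
  p_mean <- vapply(stats, function(st) het_stat_p(st, means1, means2),
                   numeric(1))
  names(p_mean) <- stats
  structure(list(p_quantile = p_quantile, p_mean = p_mean,
                 median1 = median(means1), median2 = median(means2),
                 median_diff = median(means2) - median(means1)),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("HET: medians %.3f vs %.3f (diff %+.3f)\n",
              x$median1, x$median2, x$median_diff))
  for (st in names(x$p_mean))
    cat(sprintf("  %-10s p_mean = %.4g  p_quantile = %.4g\n", st,
                x$p_mean[st], x$p_quantile[st]))
  invisible(x)
}
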