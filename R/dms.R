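## Vectorized likelihood-ratio test for a habitat effect on per-read
## methylation status.  For a single binary covariate the binomial-logistic
## MLE pools counts within each group, so the LR statistic has the closed
## form 2*(ll(p_urban) + ll(p_forest) - ll(p_pooled)) evaluated on pooled
## counts; this is identical to the glm(..., family = binomial) deviance
## drop and is what makes whole-matrix permutation feasible.
.ll_binom <- function(m, t, p) {
  u <- t - m
  out <- numeric(length(m))
  pos <- m > 0
  out[pos] <- m[pos] * log(p[pos])
  pos <- u > 0
  out[pos] <- out[pos] + u[pos] * log(1 - p[pos])
  out
}

.dm_test_all <- function(M, Tt, urban) {
  forest <- setdiff(seq_len(ncol(M)), urban)
  mu <- rowSums(M[, urban, drop = FALSE])
  tu <- rowSums(Tt[, urban, drop = FALSE])
  mf <- rowSums(M[, forest, drop = FALSE])
  tf <- rowSums(Tt[, forest, drop = FALSE])
  pu <- ifelse(tu > 0, mu / tu, 0)
  pf <- ifelse(tf > 0, mf / tf, 0)
  p0 <- (mu + mf) / pmax(tu + tf, 1)
  g <- 2 * (.ll_binom(mu, tu, pu) + .ll_binom(mf, tf, pf) -
              .ll_binom(mu + mf, tu + tf, p0))
  g <- pmax(g, 0)
  p_value <- stats::pchisq(g, df = 1, lower.tail = FALSE)
  frac <- M / pmax(Tt, 1L)
  meth_urban <- 100 * rowMeans(frac[, urban, drop = FALSE])
  meth_forest <- 100 * rowMeans(frac[, forest, drop = FALSE])
  list(p_value = p_value, meth_urban = meth_urban,
       meth_forest = meth_forest,
       meth_diff = meth_urban - meth_forest, statistic = g)
}

#' Test one CpG site for differential methylation
#'
#' Logistic regression of per-read methylation status on habitat, using the
#' aggregated (methylated, unmethylated) counts of each sample; the p-value
#' comes from the likelihood-ratio chi-square with one degree of freedom.
#' The methylation difference is the difference of the group means of the
#' per-sample methylation fractions, in percentage points (urban minus
#' forest).
#'
#' @param count_methylated,count_total integer vectors, one entry per
#'   sample.
#' @param habitat character vector of "urban"/"forest" labels.
#' @return list with `p_value`, `meth_diff`, `meth_urban`, `meth_forest`.
#' @export
site_test <- function(count_methylated, count_total, habitat) {
  stopifnot(length(count_methylated) == length(count_total),
            length(habitat) == length(count_total),
            all(count_total >= 1),
            all(count_methylated >= 0),
            all(count_methylated <= count_total))
  urban <- which(habitat == "urban")
  if (length(urban) < 2 || length(urban) > length(habitat) - 2) {
    stop("need at least two samples in each habitat")
  }
  r <- .dm_test_all(matrix(count_methylated, nrow = 1),
                    matrix(count_total, nrow = 1), urban)
  list(p_value = r$p_value, meth_diff = r$meth_diff,
       meth_urban = r$meth_urban, meth_forest = r$meth_forest)
}

#' Estimate the proportion of true nulls by a sliding linear model
#'
#' Fits straight lines to the empirical CDF of the p-values over a sliding
#' window of points on a lambda grid. On the flat part of the CDF (beyond
#' the signal near zero) the local slope estimates the null proportion pi0;
#' the window whose point-to-point slopes are most stable (minimum variance)
#' is taken, and its ordinary least-squares slope, bounded to (0, 1], is
#' returned.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda grid of evaluation points (default 0.05 to 0.95 by 0.05).
#' @param window number of grid points per fitted segment (default 5).
#' @return pi0 estimate in (0, 1]. With fewer than 100 p-values the
#'   estimate falls back to 1 (pure Benjamini-Hochberg) with a warning.
#' @export
slim_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05), window = 5) {
  stopifnot(all(p >= 0 & p <= 1))
  if (length(p) < 100) {
    warning("fewer than 100 p-values; pi0 set to 1 (pure BH adjustment)")
    return(1)
  }
  Fhat <- vapply(lambda, function(l) mean(p <= l), numeric(1))
  n_win <- length(lambda) - window + 1L
  slope <- numeric(n_win)
  instab <- numeric(n_win)
  local <- diff(Fhat) / diff(lambda)
  for (i in seq_len(n_win)) {
    idx <- i:(i + window - 1L)
    x <- lambda[idx]
    y <- Fhat[idx]
    slope[i] <- stats::cov(x, y) / stats::var(x)
    instab[i] <- stats::var(local[i:(i + window - 2L)])
  }
  best <- which.min(instab)
  ## the right-tail estimate (1 - F(lambda_max)) / (1 - lambda_max) bounds
  ## pi0 from below; it guards against degenerate inputs (e.g. a point mass
  ## of p-values at 1, where every CDF slope on the grid is zero)
  tail_est <- (1 - Fhat[length(lambda)]) / (1 - lambda[length(lambda)])
  min(max(slope[best], tail_est, 1e-8), 1)
}

#' SLIM-adjusted q-values
#'
#' Benjamini-Hochberg adjusted p-values scaled by the [slim_pi0()] estimate
#' of the true-null proportion, capped at 1 and made monotone
#' non-decreasing in p.
#'
#' @param p numeric vector of p-values.
#' @param ... passed to [slim_pi0()].
#' @return numeric vector of q-values, with the pi0 estimate attached as
#'   attribute `"pi0"`.
#' @export
slim_qvalues <- function(p, ...) {
  pi0 <- slim_pi0(p, ...)
  q <- pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
  o <- order(p)
  q[o] <- cummax(q[o])
  attr(q, "pi0") <- pi0
  q
}

#' Call differentially methylated sites
#'
#' Runs the likelihood-ratio site test on every site of a united matrix,
#' adjusts p-values to SLIM q-values jointly across sites, and calls as
#' DMSs the sites with an absolute methylation difference strictly greater
#' than `diff_threshold` percentage points and a q-value strictly below
#' `q_threshold`.
#'
#' @param mm a `meth_matrix` from [unite()].
#' @param diff_threshold minimum absolute difference in percentage points
#'   (default 25, strict inequality).
#' @param q_threshold q-value cutoff (default 0.01, strict inequality).
#' @param test `"lr"` for the likelihood-ratio logistic test (default) or
#'   `"fisher"` for Fisher's exact test on pooled group counts
#'   (sensitivity analysis).
#' @return object of class `dms_calls`: list with `all` (per-site test
#'   table), `dms` (called subset with direction), `pi0` and the
#'   thresholds. Rows are ordered by (chrom, pos).
#' @export
call_dms <- function(mm, diff_threshold = 25, q_threshold = 0.01,
                     test = c("lr", "fisher")) {
  stopifnot(inherits(mm, "meth_matrix"))
  test <- match.arg(test)
  urban <- which(mm$samples$habitat == "urban")
  n <- nrow(mm$sites)
  if (n == 0) {
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        meth_urban = numeric(0), meth_forest = numeric(0),
                        meth_diff = numeric(0), p_value = numeric(0),
                        q_value = numeric(0), direction = character(0))
    return(structure(list(all = empty, dms = empty, pi0 = NA_real_,
                          diff_threshold = diff_threshold,
                          q_threshold = q_threshold, test = test),
                     class = "dms_calls"))
  }
  if (test == "lr") {
    r <- .dm_test_all(mm$M, mm$T, urban)
    p <- r$p_value
  } else {
    forest <- setdiff(seq_len(ncol(mm$M)), urban)
    mu <- rowSums(mm$M[, urban, drop = FALSE])
    tu <- rowSums(mm$T[, urban, drop = FALSE])
    mf <- rowSums(mm$M[, forest, drop = FALSE])
    tf <- rowSums(mm$T[, forest, drop = FALSE])
    p <- vapply(seq_len(n), function(i) {
      stats::fisher.test(matrix(c(mu[i], tu[i] - mu[i],
                                  mf[i], tf[i] - mf[i]), 2))$p.value
    }, numeric(1))
    r <- .dm_test_all(mm$M, mm$T, urban)
  }
  q <- slim_qvalues(p)
  all_tab <- data.frame(
    chrom = mm$sites$chrom, pos = mm$sites$pos,
    meth_urban = r$meth_urban, meth_forest = r$meth_forest,
    meth_diff = r$meth_diff, p_value = p, q_value = as.numeric(q)
  )
  called <- abs(all_tab$meth_diff) > diff_threshold &
    all_tab$q_value < q_threshold
  dms <- all_tab[called, , drop = FALSE]
  dms$direction <- ifelse(dms$meth_diff > 0, "hyper", "hypo")
  rownames(dms) <- NULL
  structure(list(all = all_tab, dms = dms, pi0 = attr(q, "pi0"),
                 diff_threshold = diff_threshold,
                 q_threshold = q_threshold, test = test),
            class = "dms_calls")
}

#' @export
print.dms_calls <- function(x, ...) {
  cat(sprintf("dms_calls: %d of %d sites called (|diff| > %g%%, q < %g)\n",
              nrow(x$dms), nrow(x$all), x$diff_threshold, x$q_threshold))
  if (nrow(x$dms)) {
    tab <- table(x$dms$direction)
    cat(sprintf("  direction: %s; pi0 = %.3f\n",
                paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
                x$pi0))
  }
  invisible(x)
}

#' Permutation test of the habitat effect
#'
#' Reruns the complete DMS calling (site tests, SLIM q-values, both
#' thresholds) under habitat labels permuted uniformly at random among
#' balanced reassignments (the same group sizes as observed), and compares
#' the observed statistic with the permutation distribution. The default
#' statistic is the number of called DMSs; the mean absolute methylation
#' difference of called sites is available as an alternative. The add-one
#' estimator `p = (1 + #\{null >= observed\}) / (n_iter + 1)` keeps p
#' strictly positive; permutations may coincide with the observed labelling
#' (sampling with replacement -- only 924 distinct balanced 6 vs 6 splits
#' exist).
#'
#' @param mm a `meth_matrix`.
#' @param n_iter number of permutations (default 1000, minimum 100).
#' @param seed integer seed, recorded in the result.
#' @param diff_threshold,q_threshold DMS thresholds as in [call_dms()].
#' @param statistic `"count"` (default) or `"mean_abs_diff"`.
#' @return object of class `permutation_result`: list with
#'   `observed_statistic`, `null_statistics`, `p_value`, `n_iter`, `seed`.
#' @export
permutation_test <- function(mm, n_iter = 1000, seed = 1,
                             diff_threshold = 25, q_threshold = 0.01,
                             statistic = c("count", "mean_abs_diff")) {
  stopifnot(inherits(mm, "meth_matrix"), n_iter >= 100)
  statistic <- match.arg(statistic)
  n_urban <- sum(mm$samples$habitat == "urban")
  n_samp <- ncol(mm$M)
  stat_fun <- function(urban_idx) {
    r <- .dm_test_all(mm$M, mm$T, urban_idx)
    q <- suppressWarnings(slim_qvalues(r$p_value))
    called <- abs(r$meth_diff) > diff_threshold & q < q_threshold
    if (statistic == "count") {
      sum(called)
    } else {
      if (any(called)) mean(abs(r$meth_diff[called])) else 0
    }
  }
  observed <- stat_fun(which(mm$samples$habitat == "urban"))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_iter), function(i) {
    stat_fun(sample.int(n_samp, n_urban))
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (n_iter + 1)
  structure(list(observed_statistic = observed,
                 null_statistics = null_stats,
                 p_value = p, n_iter = n_iter, seed = seed,
                 statistic = statistic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed %s = %g, p = %.4g (%d iterations)\n",
    x$statistic, x$observed_statistic, x$p_value, x$n_iter))
  invisible(x)
}
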