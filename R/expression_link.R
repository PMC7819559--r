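#' Variance-stabilizing transform of expression counts
#'
#' Median-of-ratios size-factor normalization followed by `log2(x + 1)`.
#' This is a light-weight approximation to the regularized-log transform:
#' it stabilizes the count scale and removes library-size differences
#' without the shrinkage component. Size factors are estimated with
#' `DESeq2::estimateSizeFactorsForMatrix()` unless supplied.
#'
#' @param counts genes x samples matrix of raw integer counts.
#' @param size_factors optional numeric vector of per-sample size factors;
#'   estimated when `NULL`.
#' @return matrix of log2-scale expression values, with the size factors
#'   attached as attribute `"size_factors"`.
#' @export
transform_counts <- function(counts, size_factors = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (any(colSums(counts) == 0)) {
    stop("sample with all-zero counts: size factor undefined")
  }
  if (is.null(size_factors)) {
    size_factors <- DESeq2::estimateSizeFactorsForMatrix(counts)
  }
  stopifnot(length(size_factors) == ncol(counts),
            all(is.finite(size_factors)), all(size_factors > 0))
  out <- log2(sweep(counts, 2, size_factors, "/") + 1)
  attr(out, "size_factors") <- size_factors
  out
}

#' Build the methylation-expression observation table
#'
#' One row per (DMS, gene, feature, sample) combination for every DMS that
#' overlaps the gene body, promoter or TSS region of a gene with quantified
#' expression. A DMS falling in several features of one gene contributes
#' one row per feature.
#'
#' @param dms data.frame with chrom, pos (the called DMS set).
#' @param catalog a `feature_catalog`.
#' @param mm the `meth_matrix` the DMSs were called from.
#' @param expression transformed expression matrix (genes x samples) from
#'   [transform_counts()].
#' @return data.frame with columns site, gene_id, feature, sample_id,
#'   methylation (percent) and expression.
#' @export
build_observations <- function(dms, catalog, mm, expression) {
  stopifnot(inherits(catalog, "feature_catalog"))
  if (nrow(dms) == 0) {
    return(data.frame(site = character(0), gene_id = character(0),
                      feature = character(0), sample_id = character(0),
                      methylation = numeric(0), expression = numeric(0)))
  }
  key_mm <- paste(mm$sites$chrom, mm$sites$pos)
  ridx <- match(paste(dms$chrom, dms$pos), key_mm)
  stopifnot(!anyNA(ridx))
  meth_pct <- 100 * mm$M[ridx, , drop = FALSE] /
    pmax(mm$T[ridx, , drop = FALSE], 1L)
  rows <- list()
  for (feat in c("gene_body", "promoter", "tss")) {
    hits <- .overlap_pairs(dms, catalog[[feat]])
    if (nrow(hits) == 0) next
    hits <- hits[hits$gene_id %in% rownames(expression), , drop = FALSE]
    if (nrow(hits) == 0) next
    for (r in seq_len(nrow(hits))) {
      i <- hits$site_idx[r]
      g <- hits$gene_id[r]
      rows[[length(rows) + 1L]] <- data.frame(
        site = paste0(dms$chrom[i], ":", dms$pos[i]),
        gene_id = g, feature = feat,
        sample_id = colnames(mm$M),
        methylation = as.numeric(meth_pct[i, ]),
        expression = as.numeric(expression[g, colnames(mm$M)])
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(site = character(0), gene_id = character(0),
                      feature = character(0), sample_id = character(0),
                      methylation = numeric(0), expression = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the methylation-by-feature interaction model
#'
#' Models expression as a function of methylation level, genomic feature
#' and their interaction, with a random intercept per individual
#' (`expression ~ methylation * feature + (1 | sample_id)`). When the
#' estimated random-intercept variance is numerically zero -- the expected
#' situation when between-individual variation is absorbed by the
#' size-factor normalization -- the model is refit as a fixed-effects
#' linear model, and all reported quantities come from that fit. Reported:
#' per-feature marginal slopes with 95% confidence intervals, the
#' interaction F test, and pairwise slope differences with Tukey
#' (studentized-range over three groups) adjusted p-values.
#'
#' @param observations data.frame from [build_observations()].
#' @param var_tol variance threshold below which the random intercept is
#'   treated as zero (default 1e-8).
#' @return object of class `meth_expr_fit`: list with `slopes` (data.frame
#'   feature, slope, se, df, lower, upper), `interaction`
#'   (F, df1, df2, p_value), `pairwise` (data.frame with Tukey-adjusted
#'   p-values), `random_variance`, `used_mixed`, `n_obs` and the underlying
#'   `model`.
#' @export
fit_meth_expr <- function(observations, var_tol = 1e-8) {
  obs <- observations
  obs$feature <- factor(obs$feature)
  feats <- levels(obs$feature)
  if (length(feats) < 2 || any(table(obs$feature) < 3)) {
    stop("need at least two features with three or more observations each")
  }
  rand_var <- NA_real_
  used_mixed <- FALSE
  mixed <- tryCatch(
    lme4::lmer(expression ~ methylation * feature + (1 | sample_id),
               data = obs, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (!is.null(mixed)) {
    vc <- as.data.frame(lme4::VarCorr(mixed))
    rand_var <- vc$vcov[vc$grp == "sample_id"][1]
  }
  if (!is.null(mixed) && rand_var > var_tol) {
    used_mixed <- TRUE
    fit <- mixed
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    ## residual df approximation: observations minus fixed-effect rank
    ## minus (individuals - 1) absorbed by the random intercept
    df_res <- nrow(obs) - length(beta) -
      (length(unique(obs$sample_id)) - 1L)
  } else {
    fit <- stats::lm(expression ~ methylation * feature, data = obs)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    df_res <- stats::df.residual(fit)
  }

  ## per-feature slope contrast vectors on the coefficient basis
  cn <- names(beta)
  contrast <- function(feat) {
    v <- numeric(length(beta))
    names(v) <- cn
    v["methylation"] <- 1
    inter <- paste0("methylation:feature", feat)
    if (inter %in% cn) v[inter] <- 1
    v
  }
  slopes <- data.frame(feature = feats, slope = NA_real_, se = NA_real_,
                       df = df_res, lower = NA_real_, upper = NA_real_)
  tcrit <- stats::qt(0.975, df_res)
  cvecs <- lapply(feats, contrast)
  for (i in seq_along(feats)) {
    v <- cvecs[[i]]
    est <- sum(v * beta)
    se <- sqrt(drop(t(v) %*% V %*% v))
    slopes$slope[i] <- est
    slopes$se[i] <- se
    slopes$lower[i] <- est - tcrit * se
    slopes$upper[i] <- est + tcrit * se
  }

  ## interaction F test
  if (used_mixed) {
    a <- stats::anova(fit)
    row <- grep("methylation:feature", rownames(a))
    Fval <- a[row, "F value"]
    df1 <- a[row, "npar"]
    interaction <- list(F = Fval, df1 = df1, df2 = df_res,
                        p_value = stats::pf(Fval, df1, df_res,
                                            lower.tail = FALSE))
  } else {
    a <- stats::anova(fit)
    row <- match("methylation:feature", rownames(a))
    interaction <- list(F = a[row, "F value"], df1 = a[row, "Df"],
                        df2 = df_res, p_value = a[row, "Pr(>F)"])
  }

  ## pairwise slope differences, studentized-range (Tukey) adjustment
  pairs <- utils::combn(seq_along(feats), 2)
  k <- length(feats)
  pw <- data.frame(contrast = character(ncol(pairs)),
                   estimate = NA_real_, se = NA_real_, t = NA_real_,
                   p_value = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    v <- cvecs[[i1]] - cvecs[[i2]]
    est <- sum(v * beta)
    se <- sqrt(drop(t(v) %*% V %*% v))
    tval <- est / se
    pw$contrast[j] <- paste(feats[i1], "-", feats[i2])
    pw$estimate[j] <- est
    pw$se[j] <- se
    pw$t[j] <- tval
    pw$p_value[j] <- stats::ptukey(abs(tval) * sqrt(2), nmeans = k,
                                   df = df_res, lower.tail = FALSE)
  }

  structure(list(slopes = slopes, interaction = interaction, pairwise = pw,
                 random_variance = rand_var, used_mixed = used_mixed,
                 n_obs = nrow(obs), model = fit),
            class = "meth_expr_fit")
}

#' @export
print.meth_expr_fit <- function(x, ...) {
  cat(sprintf("meth_expr_fit: %d observations, %s\n", x$n_obs,
              if (x$used_mixed) "mixed model (individual intercept)"
              else sprintf(
                "fixed-effects fit (random-intercept variance %.2g)",
                x$random_variance)))
  cat(sprintf("  interaction: F(%d, %d) = %.3g, p = %.3g\n",
              x$interaction$df1, x$interaction$df2, x$interaction$F,
              x$interaction$p_value))
  for (i in seq_len(nrow(x$slopes))) {
    cat(sprintf("  %-10s slope %+.4g  [%.4g, %.4g]\n",
                x$slopes$feature[i], x$slopes$slope[i],
                x$slopes$lower[i], x$slopes$upper[i]))
  }
  invisible(x)
}

#' @export
summary.meth_expr_fit <- function(object, ...) {
  print(object)
  cat("  pairwise slope differences (Tukey-adjusted):\n")
  for (j in seq_len(nrow(object$pairwise))) {
    cat(sprintf("    %-22s %+.4g  p = %.3g\n",
                object$pairwise$contrast[j], object$pairwise$estimate[j],
                object$pairwise$p_value[j]))
  }
  invisible(object)
}

#' @export
coef.meth_expr_fit <- function(object, ...) {
  stats::setNames(object$slopes$slope, object$slopes$feature)
}

#' @export
confint.meth_expr_fit <- function(object, parm, level = 0.95, ...) {
  tcrit <- stats::qt(1 - (1 - level) / 2, object$slopes$df)
  out <- cbind(object$slopes$slope - tcrit * object$slopes$se,
               object$slopes$slope + tcrit * object$slopes$se)
  dimnames(out) <- list(object$slopes$feature,
                        sprintf("%g %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  out
}

#' @export
plot.meth_expr_fit <- function(x, observations, ...) {
  stopifnot(is.data.frame(observations))
  feats <- x$slopes$feature
  cols <- stats::setNames(seq_along(feats) + 1L, feats)
  plot(observations$methylation, observations$expression,
       col = cols[observations$feature], pch = 16, cex = 0.5,
       xlab = "methylation (%)", ylab = "expression (log2 scale)", ...)
  beta <- if (x$used_mixed) lme4::fixef(x$model) else stats::coef(x$model)
  for (f in feats) {
    sub <- observations[observations$feature == f, ]
    icpt <- beta[["(Intercept)"]]
    fterm <- paste0("feature", f)
    if (fterm %in% names(beta)) icpt <- icpt + beta[[fterm]]
    slope <- x$slopes$slope[x$slopes$feature == f]
    graphics::abline(icpt, slope, col = cols[[f]], lwd = 2)
  }
  graphics::legend("topright", legend = feats, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
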