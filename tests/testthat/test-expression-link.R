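test_that("the count transform normalizes and preserves order", {
  counts <- matrix(c(0L, 0L, 0L, 10L, 20L, 30L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  tr <- transform_counts(counts, size_factors = c(1, 1, 1))
  expect_equal(unname(tr["g1", ]), c(0, 0, 0))
  # monotone within a sample
  counts2 <- matrix(c(5L, 50L, 500L), 3, 1,
                    dimnames = list(c("a", "b", "c"), "s1"))
  tr2 <- transform_counts(counts2, size_factors = 1)
  expect_true(all(diff(tr2[, 1]) > 0))
})

test_that("doubling one sample's counts is undone by size factors", {
  set.seed(89)
  counts <- matrix(rnbinom(300, mu = 100, size = 10) + 1L, 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:6)))
  doubled <- counts
  doubled[, 3] <- counts[, 3] * 2L
  sf_ref <- attr(transform_counts(counts), "size_factors")
  sf_dbl <- attr(transform_counts(doubled), "size_factors")
  # size factors are defined up to a common scale: anchor on sample 1,
  # after which normalized counts of the doubled matrix match the original
  norm_ref <- sweep(counts, 2, sf_ref / sf_ref[1], "/")
  norm_dbl <- sweep(doubled, 2, sf_dbl / sf_dbl[1], "/")
  expect_equal(norm_dbl, norm_ref, tolerance = 1e-10)
  expect_equal(unname(sf_dbl[3] / sf_dbl[1]), unname(2 * sf_ref[3] / sf_ref[1]),
               tolerance = 1e-10)
})

test_that("an all-zero sample is rejected", {
  counts <- matrix(c(5L, 7L, 0L, 0L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(transform_counts(counts), "all-zero")
})

test_that("observation rows multiply over features, genes and samples", {
  cl <- c(chr1 = 50000L)
  genes <- data.frame(chrom = "chr1", start = 10000L, end = 12000L,
                      gene_id = "g1", score = 0L, strand = "+")
  cat <- build_feature_catalog(genes = genes,
                               cgi = data.frame(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0)),
                               chrom_lengths = cl)
  ids <- sprintf("s%02d", 1:12)
  mm <- structure(list(
    sites = data.frame(chrom = "chr1", pos = c(9800L, 10020L)),
    M = matrix(5L, 2, 12, dimnames = list(NULL, ids)),
    T = matrix(10L, 2, 12, dimnames = list(NULL, ids)),
    samples = data.frame(sample_id = ids,
                         habitat = rep(c("urban", "forest"), each = 6))),
    class = "meth_matrix")
  expr <- matrix(1, 1, 12, dimnames = list("g1", ids))

  # site in the TSS only: 12 rows
  obs1 <- build_observations(mm$sites[1, , drop = FALSE], cat, mm, expr)
  expect_equal(nrow(obs1), 12)
  expect_equal(unique(obs1$feature), "tss")
  # site in TSS and gene body of the same gene: 24 rows
  obs2 <- build_observations(mm$sites[2, , drop = FALSE], cat, mm, expr)
  expect_equal(nrow(obs2), 24)
  expect_setequal(unique(obs2$feature), c("tss", "gene_body"))
  expect_equal(unique(obs2$methylation), 50)
})

test_that("observation counts match a brute-force recount on simulated data", {
  res <- small_pipeline()
  obs <- res$observations
  counts <- small_study()$expression$counts
  quantified <- names(which(expressed_gene_flag(counts)))
  dms <- res$dms$dms
  n_expect <- 0L
  for (feat in c("gene_body", "promoter", "tss")) {
    iv <- res$catalog[[feat]]
    for (i in seq_len(nrow(dms))) {
      hits <- iv$gene_id[iv$chrom == dms$chrom[i] &
                           iv$start <= dms$pos[i] & iv$end > dms$pos[i]]
      n_expect <- n_expect + 12L * length(unique(
        hits[hits %in% quantified]))
    }
  }
  expect_equal(nrow(obs), n_expect)
})

test_that("planted slopes of (0, 0, -0.03) are recovered", {
  set.seed(97)
  n_genes_per_feat <- 8
  rows <- list()
  for (feat in c("gene_body", "promoter", "tss")) {
    slope <- if (feat == "tss") -0.03 else 0
    for (g in seq_len(n_genes_per_feat)) {
      meth <- runif(12, 0, 100)
      expr <- 8 + slope * meth + rnorm(12, sd = 0.3)
      rows[[length(rows) + 1L]] <- data.frame(
        site = sprintf("%s_%d", feat, g), gene_id = sprintf("%s_g%d", feat, g),
        feature = feat, sample_id = sprintf("s%02d", 1:12),
        methylation = meth, expression = expr)
    }
  }
  fit <- fit_meth_expr(do.call(rbind, rows))
  tss <- fit$slopes[fit$slopes$feature == "tss", ]
  expect_lt(tss$lower, -0.03)
  expect_gt(tss$upper, -0.03)
  expect_lt(tss$upper, 0)  # excludes zero
  gb <- fit$slopes[fit$slopes$feature == "gene_body", ]
  expect_lt(gb$lower, 0)
  expect_gt(gb$upper, 0)
  expect_lt(fit$interaction$p_value, 0.05)
})

test_that("identical expression values give zero slopes", {
  obs <- data.frame(
    site = "s", gene_id = "g",
    feature = rep(c("gene_body", "promoter", "tss"), each = 12),
    sample_id = rep(sprintf("s%02d", 1:12), 3),
    methylation = runif(36, 0, 100), expression = 5)
  fit <- suppressWarnings(fit_meth_expr(obs))
  expect_equal(fit$slopes$slope, rep(0, 3), tolerance = 1e-10)
})

test_that("fixed-effects and mixed fits agree when the random variance is zero", {
  set.seed(101)
  obs <- data.frame(
    feature = rep(c("gene_body", "tss"), each = 60),
    sample_id = rep(sprintf("s%02d", 1:12), 10),
    methylation = runif(120, 0, 100))
  obs$expression <- 6 - 0.02 * obs$methylation *
    (obs$feature == "tss") + rnorm(120, sd = 0.4)
  fit <- fit_meth_expr(obs)
  lm_fit <- lm(expression ~ methylation * feature, data = obs)
  if (!fit$used_mixed) {
    expect_equal(unname(coef(fit)["tss"]),
                 unname(coef(lm_fit)["methylation"] +
                          coef(lm_fit)["methylation:featuretss"]),
                 tolerance = 1e-10)
  }
  # in either case the slope estimates agree to numerical tolerance
  expect_equal(unname(coef(fit)["gene_body"]),
               unname(coef(lm_fit)["methylation"]), tolerance = 1e-6)
})

test_that("slopes are invariant to recentring methylation", {
  set.seed(103)
  obs <- data.frame(
    feature = rep(c("gene_body", "promoter", "tss"), each = 36),
    sample_id = rep(sprintf("s%02d", 1:12), 9),
    methylation = runif(108, 0, 100))
  obs$expression <- 5 - 0.01 * obs$methylation + rnorm(108, sd = 0.3)
  f1 <- fit_meth_expr(obs)
  obs2 <- obs
  obs2$methylation <- obs2$methylation - 50
  f2 <- fit_meth_expr(obs2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("slope reports match the emmeans reference implementation", {
  skip_if_not_installed("emmeans")
  set.seed(112)
  obs <- data.frame(
    feature = rep(c("gene_body", "promoter", "tss"), each = 36),
    sample_id = rep(sprintf("s%02d", 1:12), 9),
    methylation = runif(108, 0, 100))
  obs$expression <- 7 - 0.025 * obs$methylation * (obs$feature == "tss") +
    0.005 * obs$methylation * (obs$feature == "promoter") +
    rnorm(108, sd = 0.35)
  fit <- fit_meth_expr(obs)
  # no individual effect was simulated; the fit falls back to fixed effects
  expect_false(fit$used_mixed)
  lm_fit <- lm(expression ~ methylation * feature, data = obs)
  emt <- emmeans::emtrends(lm_fit, ~ feature, var = "methylation")
  ref <- as.data.frame(emt)
  expect_equal(fit$slopes$slope,
               ref$methylation.trend[match(fit$slopes$feature, ref$feature)],
               tolerance = 1e-8)
  expect_equal(fit$slopes$lower,
               ref$lower.CL[match(fit$slopes$feature, ref$feature)],
               tolerance = 1e-6)
  ref_pairs <- as.data.frame(pairs(emt))
  ours <- fit$pairwise
  ref_key <- gsub("[()]", "", ref_pairs$contrast)
  for (j in seq_len(nrow(ours))) {
    idx <- match(ours$contrast[j], ref_key)
    expect_false(is.na(idx))
    expect_equal(ours$estimate[j], ref_pairs$estimate[idx],
                 tolerance = 1e-8)
    expect_equal(ours$p_value[j], ref_pairs$p.value[idx], tolerance = 1e-6)
  }
})

test_that("a null interaction is rarely declared significant", {
  set.seed(109)
  sig <- replicate(20, {
    obs <- data.frame(
      feature = rep(c("gene_body", "promoter", "tss"), each = 24),
      sample_id = rep(sprintf("s%02d", 1:12), 6),
      methylation = runif(72, 0, 100))
    obs$expression <- 6 - 0.01 * obs$methylation + rnorm(72, sd = 0.3)
    fit_meth_expr(obs)$interaction$p_value < 0.05
  })
  expect_gte(mean(!sig), 0.9)
})

test_that("the planted TSS slope is recovered with nominal CI coverage", {
  st <- small_study()
  cat <- build_feature_catalog(genome = st$genome, genes = st$genes)
  covered <- logical(20)
  for (r in 1:20) {
    cfg_r <- st$config
    cfg_r$rng_seed <- 1000L + r
    expr_r <- simulate_expression(cfg_r, st$genes, st$methylomes)
    tr <- transform_counts(expr_r$counts)
    uc <- st$methylomes$unit_counts
    mm <- structure(list(sites = uc$sites, M = uc$M, T = uc$T,
                         samples = st$methylomes$metadata),
                    class = "meth_matrix")
    planted <- st$methylomes$truth$sites
    dms_like <- planted[planted$planted != "none",
                        c("chrom", "pos"), drop = FALSE]
    obs <- build_observations(dms_like, cat, mm, tr)
    fit <- fit_meth_expr(obs)
    tss <- fit$slopes[fit$slopes$feature == "tss", ]
    covered[r] <- tss$lower <= -0.03 && tss$upper >= -0.03
  }
  expect_gte(mean(covered), 0.9)
})
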