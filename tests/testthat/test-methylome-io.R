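cov_file <- function(lines) {
  f <- tempfile(fileext = ".cov")
  writeLines(lines, f)
  f
}

test_that("coverage parsing converts coordinates and sums counts", {
  f <- cov_file("chr1\t101\t101\t50.0\t5\t5")
  out <- read_coverage(f)
  expect_equal(out$pos, 100L)
  expect_equal(out$count_methylated, 5L)
  expect_equal(out$count_total, 10L)
})

test_that("empty and zero-coverage inputs give empty results", {
  f <- cov_file(character(0))
  expect_equal(nrow(read_coverage(f)), 0)
  f2 <- cov_file("chr1\t10\t10\t0\t0\t0")
  expect_equal(nrow(read_coverage(f2)), 0)
})

test_that("malformed coverage lines are rejected with a line number", {
  f <- cov_file(c("chr1\t101\t101\t50.0\t5\t5",
                  "chr1\t201\t201\t50.0\t-2\t5"))
  expect_error(read_coverage(f), "line 2")
  f2 <- cov_file("chr1\t101\t101\tfifty\t5\t5")
  expect_error(read_coverage(f2), "line 1")
})

test_that("inconsistent percentages warn but counts are trusted", {
  f <- cov_file("chr1\t101\t101\t90.0\t5\t5")
  expect_warning(out <- read_coverage(f), "inconsistent")
  expect_equal(out$count_methylated, 5L)
})

test_that("strand merging pools counts of a CpG unit", {
  genome <- c(chr1 = "AACGTT")  # CG at 0-based pos 2
  sites <- data.frame(chrom = "chr1", pos = c(2L, 3L),
                      count_methylated = c(5L, 3L),
                      count_total = c(10L, 10L))
  out <- merge_strands(sites, genome)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 2L)
  expect_equal(out$count_methylated, 8L)
  expect_equal(out$count_total, 20L)

  # one covered strand passes through unchanged
  out1 <- merge_strands(sites[1, ], genome)
  expect_equal(out1$count_methylated, 5L)
  expect_equal(out1$count_total, 10L)
})

test_that("non-CpG records pass through with a warning; bad positions error", {
  genome <- c(chr1 = "AACGTT")
  sites <- data.frame(chrom = "chr1", pos = 0L,
                      count_methylated = 1L, count_total = 2L)
  expect_warning(out <- merge_strands(sites, genome), "not in CpG context")
  expect_equal(out$pos, 0L)
  bad <- data.frame(chrom = "chr1", pos = 10L,
                    count_methylated = 1L, count_total = 2L)
  expect_error(merge_strands(bad, genome), "beyond end")
})

test_that("merged methylation equals the pooled fraction, and totals are conserved", {
  set.seed(11)
  n_units <- 50
  pos <- sort(sample.int(400, n_units)) * 2L
  bases <- rep("A", 1000)
  bases[pos + 1] <- "C"
  bases[pos + 2] <- "G"
  genome <- c(chr1 = paste(bases, collapse = ""))
  t1 <- rpois(n_units, 15) + 1L
  t2 <- rpois(n_units, 15) + 1L
  m1 <- rbinom(n_units, t1, 0.3)
  m2 <- rbinom(n_units, t2, 0.3)
  sites <- data.frame(
    chrom = "chr1", pos = c(pos, pos + 1L),
    count_methylated = c(m1, m2), count_total = c(t1, t2))
  out <- merge_strands(sites, genome)
  expect_equal(nrow(out), n_units)
  expect_equal(sum(out$count_total), sum(sites$count_total))
  # pooled fraction, not mean of per-strand fractions
  expect_equal(out$count_methylated / out$count_total,
               (m1 + m2) / (t1 + t2))
})

test_that("coverage filter enforces the inclusive lower bound and quantile cap", {
  sites <- data.frame(chrom = "chr1", pos = 1:3 * 10L,
                      count_methylated = c(1L, 1L, 1L),
                      count_total = c(9L, 10L, 11L))
  out <- filter_coverage(sites, min_coverage = 10, max_quantile = 1)
  expect_equal(out$count_total, c(10L, 11L))

  set.seed(3)
  big <- data.frame(chrom = "chr1", pos = seq_len(10000) * 2L,
                    count_methylated = 0L,
                    count_total = c(rpois(9999, 30) + 10L, 100000L))
  filt <- filter_coverage(big, min_coverage = 10, max_quantile = 0.999)
  cap <- quantile(big$count_total, 0.999, names = FALSE)
  expect_false(100000L %in% filt$count_total)
  expect_true(all(filt$count_total <= cap))
  # sites at or below the cap are retained
  expect_equal(sum(big$count_total > cap), 10000 - nrow(filt))
})

test_that("filtering is idempotent", {
  set.seed(5)
  sites <- data.frame(chrom = "chr1", pos = seq_len(500) * 2L,
                      count_methylated = 0L,
                      count_total = rpois(500, 25))
  once <- filter_coverage(sites)
  twice <- filter_coverage(once)
  expect_equal(once, twice)
})

test_that("unite intersects site sets across samples", {
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos,
                                 count_methylated = 1L, count_total = 12L)
  pos_all <- seq_len(100) * 10L
  samples <- c(lapply(1:11, function(i) mk(pos_all)),
               list(mk(pos_all[-(1:10)])))
  names(samples) <- sprintf("s%02d", 1:12)
  meta <- data.frame(sample_id = names(samples),
                     habitat = rep(c("urban", "forest"), each = 6))
  mm <- unite(samples, meta)
  expect_equal(nrow(mm$sites), 90)

  # single shared site
  samples2 <- list(a = mk(c(10L, 20L)), b = mk(20L),
                   c = mk(c(20L, 30L)), d = mk(c(20L, 40L)))
  meta2 <- data.frame(sample_id = c("a", "b", "c", "d"),
                      habitat = c("urban", "urban", "forest", "forest"))
  mm2 <- unite(samples2, meta2)
  expect_equal(nrow(mm2$sites), 1)
  expect_equal(mm2$sites$pos, 20L)

  # empty intersection errors with advice
  samples3 <- list(a = mk(10L), b = mk(20L), c = mk(10L), d = mk(20L))
  expect_error(unite(samples3, meta2), "relax")
})

test_that("unite is invariant to sample list order", {
  st <- small_study()
  raw <- lapply(st$methylomes$samples, function(df) {
    data.frame(chrom = df$chrom, pos = df$start - 1L,
               count_methylated = df$count_methylated,
               count_total = df$count_methylated + df$count_unmethylated)
  })
  genome <- st$genome
  merged <- lapply(raw, merge_strands, genome = genome)
  filt <- lapply(merged, filter_coverage)
  meta <- st$methylomes$metadata
  mm1 <- unite(filt, meta)
  mm2 <- unite(rev(filt), meta)
  expect_equal(mm1$sites, mm2$sites)
  expect_equal(mm1$M, mm2$M)
  expect_equal(mm1$T, mm2$T)
})

test_that("united mean coverage tracks the simulated coverage mean", {
  st <- small_study()
  res <- small_pipeline()
  mm <- res$matrix
  se <- sd(mm$T) / sqrt(length(mm$T))
  expect_lt(abs(mean(mm$T) - st$config$coverage_mean), max(2 * se, 1))
})

test_that("relaxed background applies the 3-reads-in-one-sample rule", {
  mk <- function(pos, t) data.frame(chrom = "chr1", pos = pos,
                                    count_methylated = 0L,
                                    count_total = t)
  samples <- list(a = mk(c(10L, 20L), c(3L, 2L)),
                  b = mk(c(10L, 20L), c(1L, 2L)))
  bg <- relaxed_background(samples)
  expect_equal(bg$pos, 10L)  # 3 reads in one sample in; max 2 out
})

test_that("relaxed background is a superset of the united analysis set", {
  res <- small_pipeline()
  key_bg <- paste(res$background$chrom, res$background$pos)
  key_mm <- paste(res$matrix$sites$chrom, res$matrix$sites$pos)
  expect_true(all(key_mm %in% key_bg))
})

test_that("matrix TSV round trip preserves counts and metadata", {
  res <- small_pipeline()
  f <- tempfile(fileext = ".tsv")
  write_meth_matrix(res$matrix, f)
  back <- read_meth_matrix(f)
  expect_equal(back$sites, res$matrix$sites)
  expect_equal(back$M, res$matrix$M)
  expect_equal(back$T, res$matrix$T)
  expect_equal(back$samples$habitat, res$matrix$samples$habitat)
})
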