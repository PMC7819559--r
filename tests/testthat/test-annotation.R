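test_that("extreme compositions are classified correctly", {
  cg <- c(chr1 = paste(rep("CG", 150), collapse = ""))
  out <- detect_cgi(cg)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 0L)
  expect_equal(out$end, 300L)

  at <- c(chr1 = paste(rep("AT", 150), collapse = ""))
  expect_equal(nrow(detect_cgi(at)), 0)
})

test_that("islands shorter than min_len are not reported", {
  # 100 bp of CpG-rich sequence inside AT background; single qualifying
  # window span stays under 200 bp only in per-window mode
  seqs <- c(chr1 = paste0(paste(rep("AT", 200), collapse = ""),
                          paste(rep("CG", 50), collapse = ""),
                          paste(rep("AT", 200), collapse = "")))
  out <- detect_cgi(seqs, per_window = TRUE, min_len = 200)
  expect_equal(nrow(out), 0)
  out2 <- detect_cgi(seqs, per_window = TRUE, min_len = 100)
  expect_equal(nrow(out2), 1)
})

test_that("planted islands are recovered at base level", {
  st <- small_study()
  det <- detect_cgi(st$genome)
  tr <- st$cgi_truth
  tr_ir <- IRanges::IRanges(tr$start + 1L, tr$end)
  dt_ir <- IRanges::IRanges(det$start + 1L, det$end)
  ov <- sum(IRanges::width(IRanges::intersect(tr_ir, dt_ir)))
  recovery <- ov / sum(IRanges::width(tr_ir))
  fp <- (sum(IRanges::width(dt_ir)) - ov) /
    (sum(nchar(st$genome)) - sum(IRanges::width(tr_ir)))
  expect_gte(recovery, 0.95)
  expect_lte(fp, 0.05)
})

test_that("detected intervals are sorted and non-overlapping", {
  st <- small_study()
  det <- detect_cgi(st$genome)
  expect_false(is.unsorted(det$start))
  expect_true(all(det$start[-1] >= det$end[-nrow(det)]))
})

test_that("shores flank islands and exclude island bases", {
  cl <- c(chr1 = 20000L)
  cgi <- data.frame(chrom = "chr1", start = 5000L, end = 5500L)
  sh <- make_shores(cgi, cl)
  expect_equal(sh$start, c(3000L, 5500L))
  expect_equal(sh$end, c(5000L, 7500L))

  # island at chromosome start: left shore empty after clipping
  cgi0 <- data.frame(chrom = "chr1", start = 0L, end = 300L)
  sh0 <- make_shores(cgi0, cl)
  expect_equal(nrow(sh0), 1)
  expect_equal(c(sh0$start, sh0$end), c(300L, 2300L))
})

test_that("shores between nearby islands are counted once", {
  cl <- c(chr1 = 30000L)
  cgi <- data.frame(chrom = "chr1", start = c(5000L, 6500L),
                    end = c(5500L, 7000L))
  sh <- make_shores(cgi, cl)
  # brute-force base set: within 2 kb of an island edge but in no island
  base_truth <- logical(30000)
  for (i in 1:2) {
    lo <- max(cgi$start[i] - 2000, 0)
    hi <- min(cgi$end[i] + 2000, 30000)
    base_truth[(lo + 1):hi] <- TRUE
  }
  for (i in 1:2) base_truth[(cgi$start[i] + 1):cgi$end[i]] <- FALSE
  got <- logical(30000)
  for (i in seq_len(nrow(sh))) got[(sh$start[i] + 1):sh$end[i]] <- TRUE
  expect_equal(got, base_truth)
  # the 1 kb inter-island gap appears exactly once
  expect_equal(sum(got[5501:6500]), 1000)
})

test_that("gene feature arithmetic follows the strand", {
  cl <- c(chr1 = 50000L)
  plus <- data.frame(chrom = "chr1", start = 10000L, end = 12000L,
                     gene_id = "gp", score = 0L, strand = "+")
  f <- derive_gene_features(plus, cl)
  expect_equal(c(f$tss$start, f$tss$end), c(9700L, 10050L))
  expect_equal(c(f$promoter$start, f$promoter$end), c(7000L, 9700L))
  expect_equal(c(f$gene_body$start, f$gene_body$end), c(10000L, 12000L))

  minus <- data.frame(chrom = "chr1", start = 8000L, end = 10000L,
                      gene_id = "gm", score = 0L, strand = "-")
  fm <- derive_gene_features(minus, cl)
  expect_equal(c(fm$tss$start, fm$tss$end), c(9950L, 10300L))
  expect_equal(c(fm$promoter$start, fm$promoter$end), c(10300L, 13000L))

  near0 <- data.frame(chrom = "chr1", start = 1000L, end = 3000L,
                      gene_id = "g0", score = 0L, strand = "+")
  f0 <- derive_gene_features(near0, cl)
  expect_equal(f0$promoter$start, 0L)  # clipped at chromosome start

  bad <- data.frame(chrom = "chr1", start = 10L, end = 10L,
                    gene_id = "gb", score = 0L, strand = "+")
  expect_error(derive_gene_features(bad, cl), "end <= start")
})

test_that("overlapping same-gene intervals are merged per class", {
  cl <- c(chr1 = 50000L)
  two <- data.frame(chrom = "chr1", start = c(10000L, 11000L),
                    end = c(12000L, 13000L),
                    gene_id = "g1", score = 0L, strand = "+")
  f <- derive_gene_features(two, cl)
  expect_equal(nrow(f$gene_body), 1)
  expect_equal(c(f$gene_body$start, f$gene_body$end), c(10000L, 13000L))
})

test_that("sites can belong to several classes and nonregulatory is the complement", {
  cl <- c(chr1 = 50000L)
  genes <- data.frame(chrom = "chr1", start = 10000L, end = 12000L,
                      gene_id = "g1", score = 0L, strand = "+")
  cgi <- data.frame(chrom = "chr1", start = 10500L, end = 11000L)
  cat <- build_feature_catalog(genes = genes, cgi = cgi, chrom_lengths = cl)
  sites <- data.frame(chrom = "chr1", pos = c(10700L, 30000L, 9800L))
  ann <- annotate_sites(sites, cat)
  expect_true(ann$gene_body[1] && ann$cgi[1])       # both flags at once
  expect_true(ann$nonregulatory[2])                 # 5 kb from anything
  expect_true(ann$tss[3] && !ann$nonregulatory[3])
  expect_equal(ann$genes[[1]], "g1")
  # nonregulatory XOR any-class, for every site
  any_class <- ann$promoter | ann$tss | ann$gene_body | ann$cgi |
    ann$cgi_shore
  expect_true(all(xor(ann$nonregulatory, any_class)))
})

test_that("unknown chromosomes are annotated nonregulatory with a warning", {
  cl <- c(chr1 = 50000L)
  cgi <- data.frame(chrom = "chr1", start = 0L, end = 500L)
  cat <- build_feature_catalog(cgi = cgi, chrom_lengths = cl)
  sites <- data.frame(chrom = c("chr1", "chrZ"), pos = c(100L, 100L))
  expect_warning(ann <- annotate_sites(sites, cat), "unknown")
  expect_true(ann$cgi[1])
  expect_true(ann$nonregulatory[2])
})

test_that("interval engine agrees with the all-pairs oracle", {
  set.seed(21)
  cl <- c(chr1 = 100000L, chr2 = 60000L)
  rand_iv <- function(n, gene = TRUE) {
    ch <- sample(names(cl), n, replace = TRUE)
    s <- vapply(ch, function(c_) sample.int(cl[[c_]] - 600L, 1L), 1L)
    d <- data.frame(chrom = ch, start = s, end = s + sample(50:500, n, TRUE))
    if (gene) {
      d$gene_id <- sprintf("g%02d", sample.int(30, n, TRUE))
      d$strand <- sample(c("+", "-"), n, TRUE)
    }
    d
  }
  catalog <- structure(list(
    promoter = rand_iv(40), tss = rand_iv(40), gene_body = rand_iv(40),
    cgi = rand_iv(30, gene = FALSE), cgi_shore = rand_iv(30, gene = FALSE),
    chrom_lengths = cl), class = "feature_catalog")
  sites <- data.frame(chrom = sample(names(cl), 400, TRUE),
                      pos = sample.int(90000L, 400))
  ann <- annotate_sites(sites, catalog)
  for (cls in c("promoter", "tss", "gene_body", "cgi", "cgi_shore")) {
    expect_equal(ann[[cls]], brute_overlap_count(sites, catalog[[cls]]) > 0,
                 info = cls)
  }
  # flags stable under catalog row shuffling
  shuffled <- catalog
  for (cls in c("promoter", "tss", "gene_body", "cgi", "cgi_shore")) {
    d <- shuffled[[cls]]
    shuffled[[cls]] <- d[sample.int(nrow(d)), , drop = FALSE]
  }
  ann2 <- annotate_sites(sites, shuffled)
  for (cls in c("promoter", "tss", "gene_body", "cgi", "cgi_shore")) {
    expect_equal(ann[[cls]], ann2[[cls]], info = cls)
  }
  expect_equal(ann$genes, ann2$genes)
})
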