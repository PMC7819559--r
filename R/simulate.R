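#' Simulation configuration for a two-habitat RRBS study
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults emulate a desk-scale version of a 6 urban vs 6 forest RRBS +
#' RNA-seq comparison: a mostly hypomethylated methylome (median site
#' methylation close to 10%), per-CpG read coverage in the 10-35x range,
#' a planted set of sites whose between-habitat methylation shift exceeds
#' 25 percentage points (some clustered within 2 kb so that region calling
#' has signal), CpG islands planted into the genome sequence, and gene
#' expression negatively coupled to methylation at TSS-linked sites.
#'
#' @param n_per_group samples per habitat.
#' @param n_chromosomes,chrom_length number and length (bp) of chromosomes.
#' @param baseline_beta shape parameters of the Beta distribution of
#'   per-site baseline methylation proportions. The default `c(0.35, 1.31)`
#'   has median 0.10 and SD 0.25, i.e. a right-skewed, hypomethylated
#'   majority.
#' @param coverage_mean,coverage_size negative-binomial mean and size of
#'   per-site, per-sample total read coverage of a merged CpG unit.
#' @param n_cpg_sites number of CpG units assayed (sampled from the CG
#'   dinucleotides actually present in the genome, emulating the reduced
#'   representation of RRBS).
#' @param n_true_dms number of planted differential sites; `n_tss_dms` of
#'   them are singleton "driver" sites inside TSS regions of expressed
#'   genes (these also drive expression), and of the remainder a fraction
#'   `dmr_fraction` is planted in clusters of three consecutive assayed
#'   CpGs spanning under 2 kb.
#' @param n_tss_dms number of TSS driver sites (see above).
#' @param true_effect additive shift of the urban methylation proportion at
#'   planted sites, on the proportion scale; must lie in (0.25, 0.75].
#' @param hyper_fraction fraction of planted sites/clusters shifted upwards
#'   (hypermethylated in urban birds).
#' @param dmr_fraction fraction of non-TSS planted sites placed in 2 kb
#'   clusters of three.
#' @param n_cgi,cgi_length number of planted CpG islands and the range their
#'   lengths are drawn from (bp).
#' @param n_genes,gene_length number of genes and range of gene lengths (bp).
#' @param nonexpressed_fraction fraction of genes simulated at expression
#'   levels below the expressed-gene rule (raw count under 10 in most
#'   samples).
#' @param expression_tss_slope change in log2-scale expression per
#'   percentage point of methylation at the gene's TSS driver site.
#' @param expr_log2_range range of baseline log2 mean expression for
#'   expressed genes.
#' @param expr_nb_size negative-binomial size (inverse dispersion) of
#'   expression counts.
#' @param rng_seed integer seed; with a fixed seed all generator outputs are
#'   reproducible bit for bit.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_group = 6,
                       n_chromosomes = 1,
                       chrom_length = 5e5,
                       baseline_beta = c(0.35, 1.31),
                       coverage_mean = 25,
                       coverage_size = 60,
                       n_cpg_sites = 4000,
                       n_true_dms = 60,
                       n_tss_dms = 12,
                       true_effect = 0.4,
                       hyper_fraction = 0.5,
                       dmr_fraction = 0.6,
                       n_cgi = 8,
                       cgi_length = c(800, 1200),
                       n_genes = 100,
                       gene_length = c(1500, 3500),
                       nonexpressed_fraction = 0.25,
                       expression_tss_slope = -0.03,
                       expr_log2_range = c(4, 9),
                       expr_nb_size = 10,
                       rng_seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    baseline_beta = as.numeric(baseline_beta),
    coverage_mean = coverage_mean,
    coverage_size = coverage_size,
    n_cpg_sites = as.integer(n_cpg_sites),
    n_true_dms = as.integer(n_true_dms),
    n_tss_dms = as.integer(n_tss_dms),
    true_effect = true_effect,
    hyper_fraction = hyper_fraction,
    dmr_fraction = dmr_fraction,
    n_cgi = as.integer(n_cgi),
    cgi_length = as.integer(cgi_length),
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    nonexpressed_fraction = nonexpressed_fraction,
    expression_tss_slope = expression_tss_slope,
    expr_log2_range = as.numeric(expr_log2_range),
    expr_nb_size = expr_nb_size,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$n_per_group >= 2,
    cfg$n_chromosomes >= 1,
    cfg$chrom_length >= 1e4,
    length(cfg$baseline_beta) == 2, all(cfg$baseline_beta > 0),
    cfg$coverage_mean > 0, cfg$coverage_size > 0,
    cfg$n_cpg_sites > 0,
    cfg$n_true_dms >= 0, cfg$n_tss_dms >= 0,
    cfg$n_tss_dms <= cfg$n_true_dms,
    cfg$hyper_fraction >= 0, cfg$hyper_fraction <= 1,
    cfg$dmr_fraction >= 0, cfg$dmr_fraction <= 1,
    cfg$n_cgi >= 0, cfg$n_genes >= 0,
    cfg$nonexpressed_fraction >= 0, cfg$nonexpressed_fraction < 1,
    cfg$expr_nb_size > 0
  )
  if (cfg$n_true_dms > 0 &&
      (cfg$true_effect <= 0.25 || cfg$true_effect > 0.75)) {
    stop("true_effect must lie in (0.25, 0.75]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-habitat RRBS simulation config\n")
  cat(sprintf("  %d + %d samples; %d chromosome(s) of %s bp\n",
              x$n_per_group, x$n_per_group, x$n_chromosomes,
              format(x$chrom_length, big.mark = ",")))
  cat(sprintf("  %d assayed CpG units; %d planted DMSs (effect %.2f)\n",
              x$n_cpg_sites, x$n_true_dms, x$true_effect))
  cat(sprintf("  %d CpG islands; %d genes; TSS slope %.3g log2/%%\n",
              x$n_cgi, x$n_genes, x$expression_tss_slope))
  invisible(x)
}

## Background sequence: i.i.d. bases at A/C/G/T = .3/.2/.2/.3, then 78% of
## the G's that complete a CG dinucleotide are rewritten to A or T.  This
## yields GC ~ 37-40% and CpG obs/exp ~ 0.25, i.e. the genome-wide CpG
## depletion typical of vertebrate DNA outside islands.
.sim_background_seq <- function(n) {
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  is_cg <- which(bases[-n] == "C" & bases[-1] == "G") + 1L
  hit <- is_cg[stats::runif(length(is_cg)) < 0.78]
  if (length(hit)) {
    bases[hit] <- sample(c("A", "T"), length(hit), replace = TRUE)
  }
  bases
}

## Island sequence: i.i.d. with C = G = 0.34 (GC ~ 68%, obs/exp ~ 1), which
## clears the detector thresholds (GC >= 50%, obs/exp >= 0.6) with margin
## even when averaged together with flanking background windows.
.sim_island_seq <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c(0.16, 0.34, 0.34, 0.16))
}

#' Generate a genome with planted CpG islands
#'
#' Draws a CpG-depleted background sequence (GC about 40%, CpG
#' observed/expected about 0.25) and overwrites randomly placed,
#' non-overlapping stretches with CpG-island-like composition (GC above 60%,
#' observed/expected near 1), recording the island coordinates as ground
#' truth. Islands are kept at least 3 kb apart and 2.5 kb from chromosome
#' ends so planted islands and their shores do not abut.
#'
#' @param config a [sim_config()] object.
#' @return A list with `genome` (named character vector of chromosome
#'   sequences) and `cgi_truth` (data.frame of chrom, start, end; 0-based
#'   half-open intervals).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 11L)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome <- character(config$n_chromosomes)
  names(genome) <- chroms
  truth <- list()
  per_chrom <- .split_count(config$n_cgi, config$n_chromosomes)
  for (i in seq_along(chroms)) {
    L <- config$chrom_length
    bases <- .sim_background_seq(L)
    n_isl <- per_chrom[i]
    placed <- integer(0)
    lens <- integer(0)
    tries <- 0L
    while (length(placed) < n_isl) {
      tries <- tries + 1L
      if (tries > 200L) {
        stop("could not place CpG islands without overlap; ",
             "reduce n_cgi or enlarge chrom_length")
      }
      len <- sample(seq(config$cgi_length[1], config$cgi_length[2]), 1L)
      start <- sample.int(L - len - 5000L, 1L) + 2500L  # 0-based
      ok <- all(abs(start - placed) > (3000L + max(lens, len)))
      if (ok) {
        placed <- c(placed, start)
        lens <- c(lens, len)
        bases[(start + 1L):(start + len)] <- .sim_island_seq(len)
      }
    }
    genome[i] <- paste(bases, collapse = "")
    if (n_isl > 0) {
      truth[[i]] <- data.frame(chrom = chroms[i], start = placed,
                               end = placed + lens)
    }
  }
  cgi_truth <- if (length(truth)) {
    out <- do.call(rbind, truth)
    out[order(out$chrom, out$start), , drop = FALSE]
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  rownames(cgi_truth) <- NULL
  list(genome = genome, cgi_truth = cgi_truth)
}

.split_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Generate non-overlapping gene models
#'
#' Places `n_genes` genes of random length and strand on the simulated
#' genome, leaving a 3.5 kb margin between genes and from chromosome ends so
#' promoters and TSS regions never collide between neighbouring genes.
#'
#' @param config a [sim_config()] object.
#' @param genome named character vector of chromosome sequences.
#' @return BED6-like data.frame (chrom, start, end, gene_id, score, strand),
#'   0-based half-open.
#' @export
simulate_genes <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 23L)
  chroms <- names(genome)
  per_chrom <- .split_count(config$n_genes, length(chroms))
  margin <- 600L
  rows <- list()
  gid <- 0L
  for (i in seq_along(chroms)) {
    L <- nchar(genome[[i]])
    n <- per_chrom[i]
    if (n == 0) next
    starts <- integer(0)
    ends <- integer(0)
    tries <- 0L
    while (length(starts) < n) {
      tries <- tries + 1L
      if (tries > 5000L) {
        stop("could not place genes without overlap; reduce n_genes")
      }
      len <- sample(seq(config$gene_length[1], config$gene_length[2]), 1L)
      s <- sample.int(L - len - 2L * margin, 1L) + margin
      e <- s + len
      if (all(e + margin < starts | s - margin > ends)) {
        starts <- c(starts, s)
        ends <- c(ends, e)
      }
    }
    o <- order(starts)
    gid_new <- gid + seq_len(n)
    rows[[i]] <- data.frame(
      chrom = chroms[i], start = starts[o], end = ends[o],
      gene_id = sprintf("g%03d", gid_new), score = 0L,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
    gid <- gid + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate per-sample methylomes with planted habitat differences
#'
#' Assayed CpG units are sampled from the CG dinucleotides present in the
#' genome. Each unit gets a baseline methylation proportion from the
#' configured Beta distribution; planted units have the urban proportion
#' shifted by `true_effect` (up or down) and clipped to `[0.01, 0.99]`.
#' Clipped units are recorded as true DMSs only when the realized shift
#' still exceeds 25 percentage points. Read counts are drawn per strand
#' (negative-binomial totals, binomial methylated reads), so that the two
#' strands of a unit carry independent sampling noise as in real bisulphite
#' coverage files.
#'
#' @param config a [sim_config()] object.
#' @param genome named character vector of chromosome sequences.
#' @param genes gene models from [simulate_genes()] (used to place TSS
#'   driver sites); may be `NULL`, in which case no TSS drivers are planted.
#' @return A list with elements
#'   `samples` (named list of per-sample Bismark-style coverage
#'   data.frames: chrom, start, end (1-based inclusive), meth_pct,
#'   count_methylated, count_unmethylated; one row per strand),
#'   `metadata` (sample_id, habitat),
#'   `unit_counts` (list of matrices `M`, `T` of per-unit merged counts,
#'   rows aligned to `truth$sites`), and
#'   `truth` (list: `sites` data.frame with per-site true proportions and
#'   DMS flags, `dmrs` data.frame of true clustered intervals).
#' @export
simulate_methylomes <- function(config, genome, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 37L)

  ## CpG unit positions (0-based position of the + strand C)
  pos_list <- lapply(names(genome), function(ch) {
    m <- gregexpr("CG", genome[[ch]], fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  })
  names(pos_list) <- names(genome)
  all_sites <- data.frame(
    chrom = rep(names(genome), lengths(pos_list)),
    pos = unlist(pos_list, use.names = FALSE)
  )
  n_avail <- nrow(all_sites)
  if (config$n_true_dms > n_avail) {
    stop("n_true_dms exceeds the number of available CpG sites")
  }
  n_take <- min(config$n_cpg_sites, n_avail)
  if (n_take < config$n_cpg_sites) {
    warning("fewer CpG sites available than requested; using all ", n_avail)
  }
  keep <- sort(sample.int(n_avail, n_take))
  sites <- all_sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)

  baseline <- stats::rbeta(n, config$baseline_beta[1], config$baseline_beta[2])

  ## --- plant differential sites -------------------------------------------
  planted_type <- rep("none", n)
  cluster_id <- rep(NA_integer_, n)
  direction <- rep(NA_character_, n)
  tss_gene <- rep(NA_character_, n)

  n_tss <- 0L
  if (!is.null(genes) && config$n_tss_dms > 0 && nrow(genes) > 0) {
    chrom_lengths <- nchar(genome)
    feats <- derive_gene_features(genes, chrom_lengths)
    tss <- feats$tss
    ## sites falling in a TSS region, one candidate driver per gene
    hit <- .overlap_pairs(sites, tss)
    ## keep the planted expression coupling attributable to the TSS class:
    ## driver sites must not fall inside any gene body as well
    if (nrow(hit)) {
      body_hit <- .overlap_pairs(sites, feats$gene_body)
      hit <- hit[!(hit$site_idx %in% body_hit$site_idx), , drop = FALSE]
    }
    if (nrow(hit)) {
      cand <- hit[!duplicated(hit$gene_id), , drop = FALSE]
      n_tss <- min(config$n_tss_dms, nrow(cand))
      pick <- cand[sample.int(nrow(cand), n_tss), , drop = FALSE]
      planted_type[pick$site_idx] <- "tss"
      direction[pick$site_idx] <- ifelse(
        stats::runif(n_tss) < config$hyper_fraction, "hyper", "hypo")
      tss_gene[pick$site_idx] <- pick$gene_id
    }
  }

  n_rest <- config$n_true_dms - n_tss
  n_clustered <- 3L * (round(config$dmr_fraction * n_rest) %/% 3L)
  n_clusters <- n_clustered %/% 3L
  ## cluster and singleton sites avoid TSS regions so that each
  ## expression-coupled gene responds to exactly one planted TSS site
  ## (keeps the planted slope identifiable from per-site regressions)
  in_tss <- rep(FALSE, n)
  if (!is.null(genes) && nrow(genes) > 0) {
    feats_tss <- derive_gene_features(genes, nchar(genome))$tss
    in_tss[.overlap_pairs(sites, feats_tss)$site_idx] <- TRUE
  }
  free <- which(planted_type == "none" & !in_tss)
  ## clusters: runs of 3 consecutive assayed CpGs spanning < 2 kb
  cl_done <- 0L
  if (n_clusters > 0) {
    ord <- free  # sites are already sorted by (chrom, pos)
    span_ok <- which(
      sites$chrom[ord[-c(1, 2)]] == sites$chrom[ord[seq_len(length(ord) - 2)]] &
        sites$pos[ord[-c(1, 2)]] - sites$pos[ord[seq_len(length(ord) - 2)]] < 1500
    )
    if (length(span_ok) > 1) span_ok <- sample(span_ok)
    used <- rep(FALSE, length(ord))
    for (s in span_ok) {
      if (cl_done >= n_clusters) break
      trio <- s:(s + 2L)
      if (any(used[trio])) next
      used[trio] <- TRUE
      cl_done <- cl_done + 1L
      idx <- ord[trio]
      planted_type[idx] <- "cluster"
      cluster_id[idx] <- cl_done
      direction[idx] <- if (stats::runif(1) < config$hyper_fraction)
        "hyper" else "hypo"
    }
  }
  n_single <- n_rest - 3L * cl_done
  free <- which(planted_type == "none" & !in_tss)
  if (n_single > 0) {
    idx <- free[sample.int(length(free), n_single)]
    planted_type[idx] <- "single"
    direction[idx] <- ifelse(stats::runif(n_single) < config$hyper_fraction,
                             "hyper", "hypo")
  }

  shift <- ifelse(is.na(direction), 0,
                  ifelse(direction == "hyper", config$true_effect,
                         -config$true_effect))
  p_forest <- baseline
  p_urban <- pmin(pmax(baseline + shift, 0.01), 0.99)
  realized <- p_urban - p_forest
  is_dms <- abs(realized) > 0.25

  truth_sites <- data.frame(
    chrom = sites$chrom, pos = sites$pos,
    baseline = baseline, p_urban = p_urban, p_forest = p_forest,
    realized_shift = realized,
    planted = planted_type, cluster_id = cluster_id,
    direction = ifelse(is_dms, direction, NA_character_),
    tss_gene = tss_gene,
    true_dms = is_dms
  )

  ## every planted site falling in a TSS region couples that gene's
  ## expression to its methylation (designated drivers plus incidental
  ## cluster/single sites that happen to land in a TSS)
  tss_pairs <- data.frame(chrom = character(0), pos = integer(0),
                          gene_id = character(0))
  if (!is.null(genes) && nrow(genes) > 0 && any(planted_type != "none")) {
    feats_all <- derive_gene_features(genes, nchar(genome))
    pl_idx <- which(planted_type != "none")
    hit_all <- .overlap_pairs(sites[pl_idx, , drop = FALSE], feats_all$tss)
    if (nrow(hit_all)) {
      tss_pairs <- data.frame(
        chrom = sites$chrom[pl_idx[hit_all$site_idx]],
        pos = sites$pos[pl_idx[hit_all$site_idx]],
        gene_id = hit_all$gene_id)
    }
  }

  ## true DMR intervals: clusters that kept >= 3 true DMSs within 2 kb
  dmr_rows <- list()
  for (cl in unique(stats::na.omit(cluster_id))) {
    idx <- which(cluster_id == cl & is_dms)
    if (length(idx) >= 3) {
      p <- sites$pos[idx]
      if (max(p) - min(p) + 1L <= 2000L) {
        dmr_rows[[length(dmr_rows) + 1L]] <- data.frame(
          chrom = sites$chrom[idx[1]], start = min(p), end = max(p) + 1L,
          n_sites = length(idx), cluster_id = cl,
          direction = direction[idx[1]]
        )
      }
    }
  }
  truth_dmrs <- if (length(dmr_rows)) do.call(rbind, dmr_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_sites = integer(0), cluster_id = integer(0),
               direction = character(0))

  ## --- draw reads ---------------------------------------------------------
  n_samp <- 2L * config$n_per_group
  ids <- c(sprintf("urban_%02d", seq_len(config$n_per_group)),
           sprintf("forest_%02d", seq_len(config$n_per_group)))
  habitat <- rep(c("urban", "forest"), each = config$n_per_group)
  p_mat <- cbind(matrix(p_urban, n, config$n_per_group),
                 matrix(p_forest, n, config$n_per_group))

  M_unit <- matrix(0L, n, n_samp, dimnames = list(NULL, ids))
  T_unit <- matrix(0L, n, n_samp, dimnames = list(NULL, ids))
  samples <- vector("list", n_samp)
  names(samples) <- ids
  for (j in seq_len(n_samp)) {
    cov_p <- stats::rnbinom(n, size = config$coverage_size / 2,
                            mu = config$coverage_mean / 2)
    cov_m <- stats::rnbinom(n, size = config$coverage_size / 2,
                            mu = config$coverage_mean / 2)
    m_p <- stats::rbinom(n, cov_p, p_mat[, j])
    m_m <- stats::rbinom(n, cov_m, p_mat[, j])
    M_unit[, j] <- m_p + m_m
    T_unit[, j] <- cov_p + cov_m
    ## Bismark coverage dialect: 1-based inclusive, one row per strand C
    df <- data.frame(
      chrom = rep(sites$chrom, 2L),
      start = c(sites$pos + 1L, sites$pos + 2L),
      meth = c(m_p, m_m),
      unmeth = c(cov_p - m_p, cov_m - m_m)
    )
    df <- df[df$meth + df$unmeth > 0L, , drop = FALSE]
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    samples[[j]] <- data.frame(
      chrom = df$chrom, start = df$start, end = df$start,
      meth_pct = round(100 * df$meth / (df$meth + df$unmeth), 6),
      count_methylated = df$meth, count_unmethylated = df$unmeth
    )
  }

  list(
    samples = samples,
    metadata = data.frame(sample_id = ids, habitat = habitat),
    unit_counts = list(M = M_unit, T = T_unit,
                       sites = sites),
    truth = list(sites = truth_sites, dmrs = truth_dmrs,
                 tss_pairs = tss_pairs)
  )
}

## which sites (point pos) fall inside which intervals; returns one row per
## (site, interval) pair with the interval's gene_id
.overlap_pairs <- function(sites, intervals) {
  if (nrow(intervals) == 0 || nrow(sites) == 0) {
    return(data.frame(site_idx = integer(0), gene_id = character(0)))
  }
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1L,
                                               intervals$end))
  h <- GenomicRanges::findOverlaps(q, s)
  data.frame(site_idx = S4Vectors::queryHits(h),
             gene_id = intervals$gene_id[S4Vectors::subjectHits(h)])
}

#' Generate expression counts coupled to TSS methylation
#'
#' Expressed genes receive a baseline log2 mean drawn from
#' `expr_log2_range`; a configured fraction of genes is simulated as
#' non-expressed (low counts). Genes carrying a planted TSS driver site have
#' their log2-scale mean shifted by `expression_tss_slope` times the
#' sample's realized methylation percentage at that site, producing the
#' negative methylation-expression coupling at TSS regions that the
#' interaction model is designed to recover.
#'
#' @param config a [sim_config()] object.
#' @param genes gene models.
#' @param methylomes output of [simulate_methylomes()].
#' @return list with `counts` (genes x samples integer matrix),
#'   `expressed_truth` (logical vector: gene simulated as expressed) and
#'   `baseline_log2` (per-gene baseline).
#' @export
simulate_expression <- function(config, genes, methylomes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 53L)
  n_g <- nrow(genes)
  ids <- methylomes$metadata$sample_id
  n_s <- length(ids)

  pairs <- methylomes$truth$tss_pairs
  coupled_genes <- unique(pairs$gene_id)

  expressed <- rep(TRUE, n_g)
  names(expressed) <- genes$gene_id
  ## TSS-coupled genes stay expressed so the methylation-expression link is
  ## observable
  eligible <- setdiff(genes$gene_id, coupled_genes)
  n_off <- round(config$nonexpressed_fraction * n_g)
  off <- sample(eligible, min(n_off, length(eligible)))
  expressed[off] <- FALSE

  b0 <- ifelse(expressed,
               stats::runif(n_g, config$expr_log2_range[1],
                            config$expr_log2_range[2]),
               stats::runif(n_g, 0, 2))
  names(b0) <- genes$gene_id
  ## genes under TSS methylation control sit in the upper-middle of the
  ## expression range: a narrow band keeps the planted slope identifiable
  ## under the gene-blind interaction model fitted downstream (their
  ## between-gene baseline spread stays small), and robust expression
  ## keeps counts away from the floor where the log scale flattens even
  ## when methylation suppresses the gene strongly
  if (length(coupled_genes)) {
    mid <- config$expr_log2_range[1] + 0.6 * diff(config$expr_log2_range)
    span <- diff(config$expr_log2_range) / 4
    b0[coupled_genes] <- stats::runif(length(coupled_genes),
                                      mid - span / 2, mid + span / 2)
  }

  log2_mu <- matrix(rep(b0, n_s), n_g, n_s,
                    dimnames = list(genes$gene_id, ids))
  if (nrow(pairs)) {
    key <- paste(methylomes$unit_counts$sites$chrom,
                 methylomes$unit_counts$sites$pos)
    ridx <- match(paste(pairs$chrom, pairs$pos), key)
    meth_pct <- 100 * methylomes$unit_counts$M[ridx, , drop = FALSE] /
      pmax(methylomes$unit_counts$T[ridx, , drop = FALSE], 1L)
    for (g in coupled_genes) {
      rows <- which(pairs$gene_id == g)
      ## a gene with several TSS-linked planted sites responds to their mean
      g_meth <- colMeans(meth_pct[rows, , drop = FALSE])
      log2_mu[g, ] <- log2_mu[g, ] + config$expression_tss_slope * g_meth
    }
  }
  counts <- matrix(
    stats::rnbinom(n_g * n_s, size = config$expr_nb_size,
                   mu = 2^as.vector(log2_mu)),
    n_g, n_s, dimnames = list(genes$gene_id, ids)
  )
  list(counts = counts, expressed_truth = expressed, baseline_log2 = b0)
}

#' Run the full generator
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_genes()],
#' [simulate_methylomes()] and [simulate_expression()] under the seed stored
#' in the configuration.
#'
#' @param config a [sim_config()] object.
#' @return list with `config`, `genome`, `cgi_truth`, `genes`, `methylomes`
#'   and `expression`.
#' @export
simulate_study <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  genes <- simulate_genes(config, gen$genome)
  meth <- simulate_methylomes(config, gen$genome, genes)
  expr <- simulate_expression(config, genes, meth)
  structure(
    list(config = config, genome = gen$genome, cgi_truth = gen$cgi_truth,
         genes = genes, methylomes = meth, expression = expr),
    class = "rrbs_study"
  )
}

#' @export
print.rrbs_study <- function(x, ...) {
  cat("Synthetic two-habitat RRBS study\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp total\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  %d assayed CpG units, %d true DMSs, %d true DMR cluster(s)\n",
              nrow(x$methylomes$truth$sites),
              sum(x$methylomes$truth$sites$true_dms),
              nrow(x$methylomes$truth$dmrs)))
  cat(sprintf("  %d genes (%d simulated as expressed)\n",
              nrow(x$genes), sum(x$expression$expressed_truth)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Serializes the study in the plain-text formats the analysis side of the
#' package reads back: genome FASTA, gene models as BED6 TSV, one Bismark
#' coverage file per sample, an expression count TSV and ground-truth TSVs.
#'
#' @param study an `rrbs_study` from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "rrbs_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$genome), fa)
  paths$genome <- fa

  paths$genes <- file.path(dir, "genes.bed")
  utils::write.table(study$genes, paths$genes, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  cov_dir <- file.path(dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  paths$coverage <- character(0)
  for (id in names(study$methylomes$samples)) {
    f <- file.path(cov_dir, paste0(id, ".cov"))
    utils::write.table(study$methylomes$samples[[id]], f, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths$coverage[id] <- f
  }

  paths$metadata <- file.path(dir, "samples.tsv")
  utils::write.table(study$methylomes$metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  paths$expression <- file.path(dir, "expression_counts.tsv")
  utils::write.table(
    data.frame(gene_id = rownames(study$expression$counts),
               study$expression$counts, check.names = FALSE),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$truth_sites <- file.path(dir, "truth_sites.tsv")
  utils::write.table(study$methylomes$truth$sites, paths$truth_sites,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth_dmrs <- file.path(dir, "truth_dmrs.tsv")
  utils::write.table(study$methylomes$truth$dmrs, paths$truth_dmrs,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth_cgi <- file.path(dir, "truth_cgi.tsv")
  utils::write.table(study$cgi_truth, paths$truth_cgi,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
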