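#' Detect CpG islands by a trailing-window average rule
#'
#' Scans each chromosome in consecutive non-overlapping 100 bp windows and
#' computes per-window GC content and the CpG observed/expected ratio
#' `(N_CG * L) / (N_C * N_G)` (zero when a window has no C or no G;
#' ambiguous bases count toward window length but not toward GC or CpG). A
#' window qualifies when the trailing average over up to `n_windows_avg`
#' consecutive windows (the window itself plus up to nine predecessors)
#' meets both thresholds. The reported island is the union of the spans the
#' qualifying averages were computed over; merged regions shorter than
#' `min_len` are discarded. Returned intervals are sorted and
#' non-overlapping.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param window window width in bp (default 100).
#' @param n_windows_avg number of consecutive windows averaged (default 10).
#'   Set `per_window = TRUE` to qualify each window on its own composition
#'   instead (sensitivity analysis).
#' @param min_len minimum island length in bp (default 200).
#' @param gc_min minimum average GC fraction (default 0.50).
#' @param obs_exp_min minimum average observed/expected CpG ratio
#'   (default 0.60).
#' @param per_window logical; bypass the trailing average.
#' @return data.frame chrom, start, end (0-based half-open).
#' @export
detect_cgi <- function(genome, window = 100, n_windows_avg = 10,
                       min_len = 200, gc_min = 0.50, obs_exp_min = 0.60,
                       per_window = FALSE) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  k <- if (per_window) 1L else as.integer(n_windows_avg)
  out <- list()
  for (ch in names(genome)) {
    s <- toupper(genome[[ch]])
    L <- nchar(s)
    nw <- ceiling(L / window)
    if (nw == 0) next
    widx <- function(p0) p0 %/% window + 1L  # 0-based pos -> window number
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    w_of <- widx(seq_len(L) - 1L)
    nC <- tabulate(w_of[chars == "C"], nbins = nw)
    nG <- tabulate(w_of[chars == "G"], nbins = nw)
    cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
    cg <- if (cg[1] == -1) integer(0) else as.integer(cg) - 1L  # 0-based
    ## count a CG pair in the window holding both of its bases
    cg <- cg[widx(cg) == widx(cg + 1L)]
    nCG <- tabulate(widx(cg), nbins = nw)
    len <- rep(window, nw)
    len[nw] <- L - (nw - 1L) * window
    gc <- (nC + nG) / len
    oe <- ifelse(nC * nG == 0, 0, nCG * len / (nC * nG))
    ## trailing means over up to k windows
    kk <- pmin(seq_len(nw), k)
    cum_gc <- cumsum(gc)
    cum_oe <- cumsum(oe)
    lag <- function(cs, i, m) cs[i] - ifelse(i - m >= 1, cs[pmax(i - m, 1)], 0)
    i <- seq_len(nw)
    avg_gc <- lag(cum_gc, i, kk) / kk
    avg_oe <- lag(cum_oe, i, kk) / kk
    qual <- which(avg_gc >= gc_min & avg_oe >= obs_exp_min)
    if (!length(qual)) next
    span_start <- (qual - kk[qual]) * window
    span_end <- pmin(qual * window, L)
    ir <- IRanges::reduce(IRanges::IRanges(span_start + 1L, span_end))
    ir <- ir[IRanges::width(ir) >= min_len]
    if (length(ir)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Derive CpG island shores
#'
#' Shores are the 2 kb regions flanking each island on either side, clipped
#' to chromosome bounds, with bases falling inside any island excluded and
#' overlapping shores merged (so the gap between two nearby islands is
#' counted once).
#'
#' @param cgi data.frame chrom, start, end (0-based half-open).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param flank shore width in bp (default 2000).
#' @return data.frame chrom, start, end.
#' @export
make_shores <- function(cgi, chrom_lengths, flank = 2000) {
  if (nrow(cgi) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  out <- list()
  for (ch in unique(cgi$chrom)) {
    d <- cgi[cgi$chrom == ch, , drop = FALSE]
    L <- chrom_lengths[[ch]]
    isl <- IRanges::IRanges(d$start + 1L, d$end)
    cand <- c(IRanges::IRanges(pmax(d$start - flank, 0L) + 1L,
                               pmax(d$start, 0L)),
              IRanges::IRanges(pmin(d$end, L) + 1L, pmin(d$end + flank, L)))
    cand <- cand[IRanges::width(cand) > 0]
    sh <- IRanges::setdiff(IRanges::reduce(cand), IRanges::reduce(isl))
    if (length(sh)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = IRanges::start(sh) - 1L, end = IRanges::end(sh))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Derive strand-aware gene features
#'
#' For a gene whose strand-aware 5' start is `g`: the TSS region spans 300
#' bp upstream to 50 bp downstream of `g`; the promoter spans 3 kb upstream
#' of `g` excluding the TSS region (i.e. from -3000 to -300); the gene body
#' is the full annotated gene span. Upstream/downstream follow the strand,
#' intervals are clipped to chromosome bounds, and same-class intervals of
#' one gene are merged.
#'
#' @param genes BED6-like data.frame (chrom, start, end, gene_id, score,
#'   strand), 0-based half-open.
#' @param chrom_lengths named integer vector.
#' @param promoter_bp,tss_up,tss_down feature sizes in bp (defaults 3000,
#'   300, 50).
#' @return list of data.frames `promoter`, `tss`, `gene_body`, each with
#'   chrom, start, end, gene_id, strand.
#' @export
derive_gene_features <- function(genes, chrom_lengths,
                                 promoter_bp = 3000, tss_up = 300,
                                 tss_down = 50) {
  if (any(genes$end <= genes$start)) {
    stop("gene with end <= start")
  }
  plus <- genes$strand == "+"
  g5 <- ifelse(plus, genes$start, genes$end)
  tss_start <- ifelse(plus, g5 - tss_up, g5 - tss_down)
  tss_end <- ifelse(plus, g5 + tss_down, g5 + tss_up)
  prom_start <- ifelse(plus, g5 - promoter_bp, g5 + tss_up)
  prom_end <- ifelse(plus, g5 - tss_up, g5 + promoter_bp)
  clip <- function(start, end) {
    L <- chrom_lengths[genes$chrom]
    data.frame(chrom = genes$chrom,
               start = pmax(as.integer(start), 0L),
               end = pmin(as.integer(end), as.integer(L)),
               gene_id = genes$gene_id, strand = genes$strand)
  }
  drop_empty <- function(d) {
    d <- d[d$end > d$start, , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(
    promoter = drop_empty(.merge_per_gene(clip(prom_start, prom_end))),
    tss = drop_empty(.merge_per_gene(clip(tss_start, tss_end))),
    gene_body = drop_empty(.merge_per_gene(clip(genes$start, genes$end)))
  )
}

## merge overlapping same-class intervals annotated to the same gene
.merge_per_gene <- function(d) {
  if (nrow(d) == 0) return(d)
  key <- paste(d$chrom, d$gene_id, d$strand, sep = "\r")
  parts <- split(seq_len(nrow(d)), key)
  rows <- lapply(parts, function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start[idx] + 1L, d$end[idx]))
    data.frame(chrom = d$chrom[idx[1]], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), gene_id = d$gene_id[idx[1]],
               strand = d$strand[idx[1]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the full feature catalog
#'
#' Combines CpG-island detection, shore derivation and strand-aware gene
#' features into one catalog object used for site annotation.
#'
#' @param genome named character vector or `DNAStringSet` (used for CGI
#'   detection and chromosome lengths); may be `NULL` if `cgi` and
#'   `chrom_lengths` are supplied.
#' @param genes BED6-like gene models (may be `NULL` for a CGI-only
#'   catalog).
#' @param cgi precomputed island intervals; detected from `genome` when
#'   `NULL`.
#' @param chrom_lengths named integer vector; derived from `genome` when
#'   `NULL`.
#' @param shore_bp shore width (default 2000).
#' @param ... further arguments passed to [detect_cgi()].
#' @return object of class `feature_catalog`: list of interval data.frames
#'   `promoter`, `tss`, `gene_body`, `cgi`, `cgi_shore` plus
#'   `chrom_lengths`.
#' @export
build_feature_catalog <- function(genome = NULL, genes = NULL, cgi = NULL,
                                  chrom_lengths = NULL, shore_bp = 2000,
                                  ...) {
  if (is.null(chrom_lengths)) {
    stopifnot(!is.null(genome))
    if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
    chrom_lengths <- nchar(genome)
  }
  if (is.null(cgi)) {
    stopifnot(!is.null(genome))
    cgi <- detect_cgi(genome, ...)
  }
  shores <- make_shores(cgi, chrom_lengths, flank = shore_bp)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      strand = character(0))
  gf <- if (is.null(genes) || nrow(genes) == 0) {
    list(promoter = empty, tss = empty, gene_body = empty)
  } else {
    derive_gene_features(genes, chrom_lengths)
  }
  structure(list(promoter = gf$promoter, tss = gf$tss,
                 gene_body = gf$gene_body, cgi = cgi, cgi_shore = shores,
                 chrom_lengths = chrom_lengths),
            class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("feature_catalog\n")
  for (cl in c("promoter", "tss", "gene_body", "cgi", "cgi_shore")) {
    d <- x[[cl]]
    cat(sprintf("  %-10s %5d interval(s), %s bp\n", cl, nrow(d),
                format(sum(d$end - d$start), big.mark = ",")))
  }
  invisible(x)
}

#' Annotate CpG sites with feature-class membership
#'
#' Point-in-interval tests of each site against every feature class of the
#' catalog. A site may belong to several classes at once; a site in none of
#' the five classes is flagged nonregulatory. Gene identifiers are collected
#' from overlapping gene-linked features (promoter, TSS, gene body). Sites
#' on chromosomes absent from the catalog are annotated nonregulatory with a
#' warning.
#'
#' @param sites data.frame with chrom, pos (0-based).
#' @param catalog a `feature_catalog`.
#' @return data.frame with chrom, pos, logical columns per class,
#'   `nonregulatory`, and a list-column `genes` of linked gene ids.
#' @export
annotate_sites <- function(sites, catalog) {
  stopifnot(inherits(catalog, "feature_catalog"))
  n <- nrow(sites)
  unknown <- !(sites$chrom %in% names(catalog$chrom_lengths))
  if (any(unknown)) {
    warning(sum(unknown), " site(s) on chromosomes unknown to the catalog; ",
            "annotated nonregulatory")
  }
  q <- GenomicRanges::GRanges(
    ifelse(unknown, names(catalog$chrom_lengths)[1], sites$chrom),
    IRanges::IRanges(ifelse(unknown, 1L, sites$pos + 1L), width = 1L))
  classes <- c("promoter", "tss", "gene_body", "cgi", "cgi_shore")
  flags <- matrix(FALSE, n, length(classes),
                  dimnames = list(NULL, classes))
  genes <- vector("list", n)
  for (i in seq_len(n)) genes[[i]] <- character(0)
  for (cl in classes) {
    d <- catalog[[cl]]
    if (nrow(d) == 0) next
    s <- GenomicRanges::GRanges(d$chrom,
                                IRanges::IRanges(d$start + 1L, d$end))
    h <- GenomicRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(h)
    flags[unique(qh), cl] <- TRUE
    if (!is.null(d$gene_id)) {
      sh <- S4Vectors::subjectHits(h)
      for (k in seq_along(qh)) {
        genes[[qh[k]]] <- c(genes[[qh[k]]], d$gene_id[sh[k]])
      }
    }
  }
  flags[unknown, ] <- FALSE
  genes[unknown] <- list(character(0))
  genes <- lapply(genes, function(g) sort(unique(g)))
  out <- data.frame(chrom = sites$chrom, pos = sites$pos)
  for (cl in classes) out[[cl]] <- flags[, cl]
  out$nonregulatory <- !apply(flags, 1, any)
  out$genes <- I(genes)
  out
}

#' Read BED6 gene models
#'
#' @param path path to a 6-column BED file (chrom, start, end, name, score,
#'   strand; 0-based half-open).
#' @return data.frame with columns chrom, start, end, gene_id, score,
#'   strand.
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id",
                                        "score", "strand"))
  df$chrom <- as.character(df$chrom)
  df$gene_id <- as.character(df$gene_id)
  df
}
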