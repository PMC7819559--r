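#' Read a Bismark-style coverage file
#'
#' Parses the six-column coverage dialect (chrom, start, end, methylation
#' percentage, count methylated, count unmethylated; positions 1-based
#' inclusive, optionally gzip-compressed). Positions are converted to the
#' package-internal 0-based convention and rows with zero total coverage are
#' dropped. The percentage column is checked against the counts (within 0.5
#' percentage points); a mismatch triggers a warning and the counts are
#' trusted.
#'
#' @param path path to the coverage file.
#' @return data.frame with columns chrom, pos (0-based), count_methylated,
#'   count_total.
#' @export
read_coverage <- function(path) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      count_methylated = integer(0),
                      count_total = integer(0))
  if (file.exists(path) && file.size(path) == 0) return(empty)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1),
                      showProgress = FALSE),
    error = function(e) stop("malformed coverage file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) != 6) {
    stop("coverage file '", path, "' must have 6 columns, found ", ncol(dt))
  }
  names(dt) <- c("chrom", "start", "end", "meth_pct", "m", "u")
  num_ok <- vapply(dt[, c("start", "end", "meth_pct", "m", "u")],
                   is.numeric, logical(1))
  if (!all(num_ok)) {
    bad_col <- names(num_ok)[!num_ok][1]
    col_idx <- match(bad_col, names(dt))
    bad_line <- which(is.na(suppressWarnings(
      as.numeric(as.character(dt[[col_idx]])))))[1]
    stop("malformed line ", bad_line, " in '", path,
         "': non-numeric value in column ", col_idx)
  }
  bad <- which(dt$m < 0 | dt$u < 0 | dt$start < 1 | dt$m != round(dt$m) |
                 dt$u != round(dt$u))
  if (length(bad)) {
    stop("malformed line ", bad[1], " in '", path,
         "': negative or non-integer counts")
  }
  total <- dt$m + dt$u
  keep <- total > 0
  expect_pct <- ifelse(keep, 100 * dt$m / pmax(total, 1L), 0)
  off <- which(keep & abs(dt$meth_pct - expect_pct) > 0.5)
  if (length(off)) {
    warning(length(off), " line(s) in '", basename(path),
            "' have a methylation percentage inconsistent with the counts; ",
            "counts are trusted")
  }
  out <- data.frame(
    chrom = dt$chrom[keep],
    pos = as.integer(dt$start[keep]) - 1L,
    count_methylated = as.integer(dt$m[keep]),
    count_total = as.integer(total[keep])
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Merge the two strands of each CpG dinucleotide
#'
#' Bisulphite callers report the C of each strand separately: the + strand C
#' at position p and the - strand C at p + 1 belong to the same CpG unit.
#' This function locates CpG dinucleotides in the genome and sums the read
#' counts of the two strand records into a single unit anchored at the +
#' strand C. Positions that are not in CpG context are passed through
#' unmerged, and their number is attached as attribute `n_non_cpg` (with a
#' warning when positive).
#'
#' @param sites data.frame from [read_coverage()].
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @return data.frame chrom, pos, count_methylated, count_total with one row
#'   per CpG unit.
#' @export
merge_strands <- function(sites, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (nrow(sites) == 0) {
    return(sites)
  }
  missing_chr <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) not in genome: ", paste(missing_chr, collapse = ", "))
  }
  parts <- split(seq_len(nrow(sites)), sites$chrom)
  unit_pos <- integer(nrow(sites))
  non_cpg <- logical(nrow(sites))
  for (ch in names(parts)) {
    idx <- parts[[ch]]
    seq_ch <- genome[[ch]]
    L <- nchar(seq_ch)
    p <- sites$pos[idx]
    if (any(p >= L | p < 0)) {
      stop("position beyond end of chromosome ", ch)
    }
    base <- strsplit(seq_ch, "", fixed = TRUE)[[1]]
    here <- base[p + 1L]
    nxt <- ifelse(p + 2L <= L, base[p + 2L], "")
    prv <- ifelse(p >= 1L, base[pmax(p, 1L)], "")
    is_plus <- here == "C" & nxt == "G"
    is_minus <- here == "G" & prv == "C"
    unit_pos[idx] <- ifelse(is_plus, p, ifelse(is_minus, p - 1L, p))
    non_cpg[idx] <- !is_plus & !is_minus
  }
  if (any(non_cpg)) {
    warning(sum(non_cpg), " record(s) not in CpG context passed through ",
            "unmerged")
  }
  dt <- data.table::data.table(
    chrom = sites$chrom, pos = unit_pos,
    m = sites$count_methylated, t = sites$count_total
  )
  agg <- dt[, list(count_methylated = sum(m), count_total = sum(t)),
            by = c("chrom", "pos")]
  data.table::setorderv(agg, c("chrom", "pos"))
  out <- as.data.frame(agg)
  attr(out, "n_non_cpg") <- sum(non_cpg)
  out
}

#' Apply per-sample coverage filters
#'
#' Retains sites whose total read count is at least `min_coverage` and not
#' above the sample's `max_quantile` coverage quantile (linear-interpolation
#' quantile; sites exactly at the quantile are retained, only strictly
#' greater values are removed).
#'
#' @param sites data.frame with a `count_total` column (one sample).
#' @param min_coverage minimum total reads (default 10).
#' @param max_quantile upper coverage quantile cap (default 0.999).
#' @return the filtered data.frame.
#' @export
filter_coverage <- function(sites, min_coverage = 10, max_quantile = 0.999) {
  if (nrow(sites) == 0) return(sites)
  cap <- stats::quantile(sites$count_total, max_quantile, names = FALSE,
                         type = 7)
  keep <- sites$count_total >= min_coverage & sites$count_total <= cap
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unite samples into a methylation matrix
#'
#' Intersects the (already strand-merged and coverage-filtered) site sets of
#' all samples, keeping only CpG units covered in every sample, and arranges
#' the methylated/total counts into aligned matrices ordered by (chrom,
#' pos). Both habitats must contribute at least `min_per_habitat` samples.
#'
#' @param samples named list of per-sample data.frames (chrom, pos,
#'   count_methylated, count_total).
#' @param metadata data.frame with columns sample_id, habitat (values
#'   "urban"/"forest"); row order defines column order.
#' @param min_per_habitat minimum samples per habitat (default 2).
#' @return an object of class `meth_matrix`: list with `sites` (chrom, pos),
#'   matrices `M` and `T` (sites x samples) and `samples` metadata.
#' @export
unite <- function(samples, metadata, min_per_habitat = 2) {
  stopifnot(is.list(samples), length(samples) >= 2,
            all(metadata$sample_id %in% names(samples)))
  tab <- table(metadata$habitat)
  if (length(tab) < 2 || any(tab < min_per_habitat)) {
    stop("need at least ", min_per_habitat, " samples in each habitat")
  }
  samples <- samples[metadata$sample_id]
  keys <- lapply(samples, function(s) paste(s$chrom, s$pos, sep = ":"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0) {
    stop("no CpG site is covered in all samples after filtering; ",
         "consider relaxing min_coverage or max_quantile")
  }
  first <- samples[[1]]
  sel <- match(shared, keys[[1]])
  sites <- data.frame(chrom = first$chrom[sel], pos = first$pos[sel])
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  shared <- shared[o]
  n <- length(shared)
  ids <- metadata$sample_id
  M <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  Tt <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    s <- samples[[j]]
    idx <- match(shared, paste(s$chrom, s$pos, sep = ":"))
    M[, j] <- s$count_methylated[idx]
    Tt[, j] <- s$count_total[idx]
  }
  structure(list(sites = sites, M = M, T = Tt,
                 samples = as.data.frame(metadata)),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  tab <- table(x$samples$habitat)
  cat(sprintf("meth_matrix: %d CpG units x %d samples (%s)\n",
              nrow(x$sites), ncol(x$M),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  cat(sprintf("  mean coverage %.1f; mean methylation %.1f%%\n",
              mean(x$T), 100 * mean(x$M / pmax(x$T, 1L))))
  invisible(x)
}

#' Relaxed-coverage background site set
#'
#' Builds the genome-wide background used for distribution summaries and
#' enrichment tests: the union of CpG units with at least `min_coverage`
#' reads in at least `min_samples` samples. By construction this is a
#' superset of the strictly filtered analysis set.
#'
#' @param samples named list of per-sample data.frames (chrom, pos,
#'   count_methylated, count_total), strand-merged but unfiltered.
#' @param min_coverage minimum total reads (default 3).
#' @param min_samples minimum number of samples reaching it (default 1).
#' @return data.frame of chrom, pos sorted by position.
#' @export
relaxed_background <- function(samples, min_coverage = 3, min_samples = 1) {
  dt <- data.table::rbindlist(lapply(samples, function(s) {
    data.table::data.table(chrom = s$chrom, pos = s$pos,
                           ok = s$count_total >= min_coverage)
  }))
  agg <- dt[, list(n_ok = sum(ok)), by = c("chrom", "pos")]
  agg <- agg[agg$n_ok >= min_samples, ]
  data.table::setorderv(agg, c("chrom", "pos"))
  out <- as.data.frame(agg[, c("chrom", "pos")])
  out
}

#' Write / read a united methylation matrix as TSV
#'
#' The matrix is written with a header line and 1-based positions
#' (`chrom`, `pos`, then `<sample>.meth` / `<sample>.total` column pairs),
#' alongside a sample metadata TSV.
#'
#' @param mm a `meth_matrix`.
#' @param path output TSV path; the metadata is written next to it with
#'   suffix `.samples.tsv`.
#' @return invisibly, the paths written.
#' @export
write_meth_matrix <- function(mm, path) {
  stopifnot(inherits(mm, "meth_matrix"))
  df <- data.frame(chrom = mm$sites$chrom, pos = mm$sites$pos + 1L)
  for (id in colnames(mm$M)) {
    df[[paste0(id, ".meth")]] <- mm$M[, id]
    df[[paste0(id, ".total")]] <- mm$T[, id]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- paste0(path, ".samples.tsv")
  utils::write.table(mm$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = path, samples = meta_path))
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- utils::read.delim(paste0(path, ".samples.tsv"))
  ids <- meta$sample_id
  M <- as.matrix(df[paste0(ids, ".meth")])
  Tt <- as.matrix(df[paste0(ids, ".total")])
  colnames(M) <- colnames(Tt) <- ids
  structure(list(sites = data.frame(chrom = df$chrom, pos = df$pos - 1L),
                 M = M, T = Tt, samples = meta),
            class = "meth_matrix")
}
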