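#' Cluster DMSs into differentially methylated regions
#'
#' Greedy left-to-right chaining per chromosome: starting from the leftmost
#' unassigned DMS, the chain absorbs every following DMS as long as the
#' chain's total span (first to last member, inclusive) stays within
#' `window` bp; maximal chains with at least `min_sites` members are
#' reported as DMRs. Each DMS belongs to at most one DMR. The direction
#' class is `constitutive_hyper`/`constitutive_hypo` when all members share
#' a direction and `mixed` otherwise.
#'
#' @param dms data.frame with columns chrom, pos and direction
#'   ("hyper"/"hypo"), e.g. the `dms` element of a [call_dms()] result.
#' @param window maximum region span in bp (default 2000).
#' @param min_sites minimum member count (default 3).
#' @return data.frame with chrom, start, end (0-based half-open span of
#'   member sites), n_sites, direction_class, and a list-column
#'   `member_pos` of member site positions.
#' @export
call_dmrs <- function(dms, window = 2000, min_sites = 3) {
  if (nrow(dms) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      direction_class = character(0),
                      member_pos = I(list())))
  }
  dms <- dms[order(dms$chrom, dms$pos), , drop = FALSE]
  rows <- list()
  for (ch in unique(dms$chrom)) {
    d <- dms[dms$chrom == ch, , drop = FALSE]
    pos <- d$pos
    i <- 1L
    n <- length(pos)
    while (i <= n) {
      j <- i
      while (j < n && pos[j + 1L] - pos[i] + 1L <= window) j <- j + 1L
      if (j - i + 1L >= min_sites) {
        members <- i:j
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos[i], end = pos[j] + 1L,
          n_sites = j - i + 1L,
          direction_class = classify_dmr(d$direction[members]),
          member_pos = I(list(pos[members]))
        )
      }
      i <- j + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      direction_class = character(0),
                      member_pos = I(list())))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the direction of a DMR
#'
#' @param directions character vector of member directions
#'   ("hyper"/"hypo").
#' @return `"constitutive_hyper"`, `"constitutive_hypo"` or `"mixed"`.
#' @export
classify_dmr <- function(directions) {
  stopifnot(length(directions) >= 1, !anyNA(directions))
  if (all(directions == "hyper")) return("constitutive_hyper")
  if (all(directions == "hypo")) return("constitutive_hypo")
  "mixed"
}
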