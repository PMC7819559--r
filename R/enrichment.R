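#' Two-by-two over-representation test
#'
#' Builds the contingency table of a focal site set against a background set
#' for one binary property, reports the sample cross-product odds ratio
#' `(a/b)/(c/d)` and the two-sided Fisher exact p-value. Degenerate tables
#' (a zero margin) are flagged: an odds ratio of `Inf` or 0 is reported as
#' such rather than silently adjusted.
#'
#' @param focal_in,focal_out counts of focal sites with / without the
#'   property.
#' @param bg_in,bg_out counts of background sites with / without the
#'   property.
#' @param label optional label describing the comparison.
#' @return object of class `enrichment_result`: list with the four counts,
#'   `odds_ratio`, `p_value`, `direction` ("over"/"under") and
#'   `degenerate` flag.
#' @export
enrichment_test <- function(focal_in, focal_out, bg_in, bg_out,
                            label = "") {
  counts <- c(focal_in, focal_out, bg_in, bg_out)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (focal_in + focal_out == 0 && bg_in + bg_out == 0) {
    stop("both focal and background sets are empty")
  }
  degenerate <- focal_out == 0 || bg_in == 0 || focal_in == 0 || bg_out == 0
  or <- (focal_in / focal_out) / (bg_in / bg_out)
  p <- stats::fisher.test(matrix(c(focal_in, focal_out, bg_in, bg_out),
                                 nrow = 2))$p.value
  structure(list(label = label, focal_in = focal_in, focal_out = focal_out,
                 bg_in = bg_in, bg_out = bg_out,
                 odds_ratio = or, p_value = p,
                 direction = if (is.nan(or) || or >= 1) "over" else "under",
                 degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  focal %d/%d vs background %d/%d\n",
              x$focal_in, x$focal_in + x$focal_out,
              x$bg_in, x$bg_in + x$bg_out))
  cat(sprintf("  odds ratio = %.3g (%s), p = %.3g%s\n",
              x$odds_ratio, x$direction, x$p_value,
              if (x$degenerate) " [degenerate table]" else ""))
  invisible(x)
}

#' Feature-class over-representation of DMSs
#'
#' Tests whether DMSs are over- or under-represented in one feature class
#' relative to the background of all sequenced CpG sites (the relaxed
#' 3x-coverage set, annotated with the same catalog). The background is not
#' purged of the focal sites. `feature_class = "regulatory"` tests
#' membership in any of the five regulatory classes (the complement of
#' `nonregulatory`).
#'
#' @param dms_annotation annotation data.frame (from [annotate_sites()]) of
#'   the DMS set.
#' @param bg_annotation annotation data.frame of the background set.
#' @param feature_class one of `"promoter"`, `"tss"`, `"gene_body"`,
#'   `"cgi"`, `"cgi_shore"`, `"nonregulatory"`, `"regulatory"`.
#' @return an `enrichment_result`.
#' @export
feature_enrichment <- function(dms_annotation, bg_annotation,
                               feature_class) {
  pick <- function(ann) {
    if (feature_class == "regulatory") !ann$nonregulatory
    else ann[[feature_class]]
  }
  stopifnot(feature_class %in% c("promoter", "tss", "gene_body", "cgi",
                                 "cgi_shore", "nonregulatory", "regulatory"))
  f <- pick(dms_annotation)
  b <- pick(bg_annotation)
  if (sum(f) == 0 && sum(b) == 0) {
    stop("feature class '", feature_class,
         "' is empty in both focal and background sets")
  }
  enrichment_test(sum(f), sum(!f), sum(b), sum(!b), label = feature_class)
}

#' Flag expressed genes
#'
#' A gene is expressed when its raw count reaches `min_count` in at least
#' `ceiling(min_fraction * n_samples)` samples (with the defaults and 12
#' samples: a count of ten or more in three or more individuals).
#'
#' @param counts genes x samples matrix of raw integer counts with gene ids
#'   as rownames.
#' @param min_count count threshold (default 10).
#' @param min_fraction minimum fraction of samples (default 0.25).
#' @return named logical vector.
#' @export
expressed_gene_flag <- function(counts, min_count = 10,
                                min_fraction = 0.25) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  need <- ceiling(min_fraction * ncol(counts))
  rowSums(counts >= min_count) >= need
}

## site qualifies when it lies in a window of <= `window` bp containing
## >= min_sites assayed sites (the DMR span convention)
.in_proximity <- function(sites, window = 2000, min_sites = 3) {
  ord <- order(sites$chrom, sites$pos)
  qual <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- ord[sites$chrom[ord] == ch]
    pos <- sites$pos[idx]
    n <- length(pos)
    if (n < min_sites) next
    k <- min_sites - 1L
    ok <- logical(n)
    for (off in 0:k) {
      lo <- seq_len(n) - off
      hi <- lo + k
      valid <- lo >= 1L & hi <= n
      span_ok <- valid
      span_ok[valid] <- pos[hi[valid]] - pos[lo[valid]] + 1L <= window
      ok <- ok | span_ok
    }
    qual[idx] <- ok
  }
  qual
}

#' Expressed-gene over-representation of DMSs
#'
#' Tests whether DMSs lie in regulatory regions linked to expressed genes
#' (site property: at least one of the gene-linked features -- promoter,
#' TSS, gene body -- connects the site to a gene flagged expressed). With
#' `dmr_restricted = TRUE` the focal set is restricted to DMSs inside DMRs
#' and the background to CpG sites located within 2 kb of two or more other
#' background sites (the same span convention as DMR calling).
#'
#' @param dms_annotation annotation of the DMS set.
#' @param bg_annotation annotation of the background set.
#' @param expressed named logical vector from [expressed_gene_flag()].
#' @param dmr_restricted logical (default `FALSE`).
#' @param dmrs DMR table from [call_dmrs()], required when
#'   `dmr_restricted = TRUE`.
#' @param window proximity span in bp for the restricted background
#'   (default 2000).
#' @return an `enrichment_result`.
#' @export
expression_enrichment <- function(dms_annotation, bg_annotation, expressed,
                                  dmr_restricted = FALSE, dmrs = NULL,
                                  window = 2000) {
  linked <- function(ann) {
    vapply(ann$genes, function(g) {
      length(g) > 0 && any(expressed[g], na.rm = TRUE)
    }, logical(1))
  }
  focal <- dms_annotation
  bg <- bg_annotation
  if (dmr_restricted) {
    stopifnot(!is.null(dmrs))
    if (nrow(dmrs) == 0) {
      stop("focal set is empty: no DMRs supplied")
    }
    inside <- rep(FALSE, nrow(focal))
    for (i in seq_len(nrow(dmrs))) {
      inside <- inside | (focal$chrom == dmrs$chrom[i] &
                            focal$pos >= dmrs$start[i] &
                            focal$pos < dmrs$end[i])
    }
    focal <- focal[inside, , drop = FALSE]
    bg <- bg[.in_proximity(bg, window = window, min_sites = 3), ,
             drop = FALSE]
  }
  if (nrow(focal) == 0) stop("focal set is empty")
  f <- linked(focal)
  b <- linked(bg)
  enrichment_test(sum(f), sum(!f), sum(b), sum(!b),
                  label = if (dmr_restricted) "expressed genes (DMR sites)"
                  else "expressed genes")
}

#' Parse a Gene Ontology OBO file
#'
#' Minimal parser for the OBO flat-file format: `[Term]` stanzas with `id`,
#' `name`, `is_a` and `relationship: part_of` lines are retained; obsolete
#' terms are dropped. Only the fields needed for true-path propagation and
#' term naming are kept.
#'
#' @param path path to an `.obo` file.
#' @return object of class `go_ontology`: list with `terms` (data.frame id,
#'   name) and `parents` (named list of is_a/part_of parent ids).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  ids <- character(0)
  names_ <- character(0)
  parents <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      if (length(v)) sub(paste0("^", key, ": "), "", v[1]) else NA_character_
    }
    if (!is.na(get1("is_obsolete")) && get1("is_obsolete") == "true") next
    id <- get1("id")
    if (is.na(id)) next
    isa <- block[startsWith(block, "is_a: ")]
    isa <- sub("^is_a: ", "", isa)
    isa <- sub(" !.*$", "", isa)
    rel <- block[startsWith(block, "relationship: part_of ")]
    rel <- sub("^relationship: part_of ", "", rel)
    rel <- sub(" !.*$", "", rel)
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    parents[[id]] <- unique(c(isa, rel))
  }
  structure(list(terms = data.frame(id = ids, name = names_),
                 parents = parents),
            class = "go_ontology")
}

## all ancestors (transitive is_a/part_of closure) of a term, memoized
.go_ancestors <- function(id, ontology, cache) {
  if (!is.null(cache[[id]])) return(cache[[id]])
  seen <- character(0)
  frontier <- ontology$parents[[id]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
  }
  cache[[id]] <- seen
  seen
}

#' Propagate gene annotations to ancestor terms
#'
#' Applies the true-path rule: a gene annotated to a term is implicitly
#' annotated to every ancestor reachable through `is_a` or `part_of` edges.
#'
#' @param gene2go data.frame with columns `gene_id`, `term`.
#' @param ontology a `go_ontology` from [read_obo()].
#' @return named list: per gene, the character vector of all direct and
#'   ancestral term ids.
#' @export
propagate_annotations <- function(gene2go, ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  cache <- new.env(parent = emptyenv())
  per_gene <- split(gene2go$term, gene2go$gene_id)
  lapply(per_gene, function(terms) {
    terms <- intersect(unique(terms), names(ontology$parents))
    anc <- unlist(lapply(terms, .go_ancestors, ontology = ontology,
                         cache = cache), use.names = FALSE)
    sort(unique(c(terms, anc)))
  })
}

#' GO-term over-representation of DMR-linked genes
#'
#' One-sided hypergeometric upper-tail test per term with at least one
#' focal gene, with Benjamini-Hochberg correction across tested terms.
#' Annotations are first propagated to ancestors (true-path rule). By
#' default the background universe is every background gene with at least
#' one propagated annotation; `background = "all"` keeps unannotated genes
#' in the universe count.
#'
#' @param focal_genes character vector of focal gene ids (genes linked to
#'   DMSs inside DMRs via gene body, promoter or TSS).
#' @param gene2go data.frame with columns `gene_id`, `term`.
#' @param ontology a `go_ontology`.
#' @param background_genes character vector of background gene ids (default:
#'   all genes in `gene2go`).
#' @param fdr_threshold reported significance cutoff (default 0.05).
#' @param background `"annotated"` (default) or `"all"`.
#' @return data.frame (class `go_enrichment`) with term, name, k (focal
#'   genes annotated), K (background genes annotated), n (focal gene
#'   count), N (background gene count), p_value, fdr, significant; sorted
#'   by p-value. The number of focal genes without any annotation is
#'   attached as attribute `n_unannotated_focal`.
#' @export
go_enrichment <- function(focal_genes, gene2go, ontology,
                          background_genes = NULL, fdr_threshold = 0.05,
                          background = c("annotated", "all")) {
  background <- match.arg(background)
  if (is.null(background_genes)) {
    background_genes <- unique(gene2go$gene_id)
  }
  focal_genes <- unique(focal_genes)
  stopifnot(all(focal_genes %in% background_genes))
  ann <- propagate_annotations(
    gene2go[gene2go$gene_id %in% background_genes, , drop = FALSE],
    ontology)
  annotated <- names(ann)[lengths(ann) > 0]
  n_unann_focal <- sum(!(focal_genes %in% annotated))
  if (background == "annotated") {
    universe <- intersect(background_genes, annotated)
    focal_use <- intersect(focal_genes, universe)
  } else {
    universe <- background_genes
    focal_use <- focal_genes
  }
  N <- length(universe)
  n <- length(focal_use)
  term_genes <- list()
  for (g in intersect(universe, annotated)) {
    for (t in ann[[g]]) term_genes[[t]] <- c(term_genes[[t]], g)
  }
  focal_terms <- unique(unlist(ann[intersect(focal_use, annotated)],
                               use.names = FALSE))
  if (length(focal_terms) == 0) {
    out <- data.frame(term = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0))
    attr(out, "n_unannotated_focal") <- n_unann_focal
    class(out) <- c("go_enrichment", "data.frame")
    return(out)
  }
  k <- vapply(focal_terms, function(t) {
    length(intersect(term_genes[[t]], focal_use))
  }, integer(1))
  K <- vapply(focal_terms, function(t) length(term_genes[[t]]), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  nm <- ontology$terms$name[match(focal_terms, ontology$terms$id)]
  out <- data.frame(term = focal_terms, name = nm, k = k, K = K,
                    n = n, N = N, p_value = p, fdr = fdr,
                    significant = fdr < fdr_threshold)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated_focal") <- n_unann_focal
  class(out) <- c("go_enrichment", "data.frame")
  out
}

#' Read a two-column gene-to-term mapping
#'
#' @param path TSV with columns gene id and term id (no header).
#' @return data.frame with columns `gene_id`, `term`.
#' @export
read_gene2go <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("gene_id", "term"))
  df$gene_id <- as.character(df$gene_id)
  df$term <- as.character(df$term)
  df
}
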