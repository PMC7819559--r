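#' Pipeline run configuration
#'
#' Collects every analysis threshold in one validated object. Defaults are
#' the study settings: 10x minimum coverage capped at the per-sample 99.9th
#' percentile, a 25-percentage-point difference with q < 0.01 for DMS
#' calling, 2 kb windows with at least 3 sites for DMRs, 3 kb promoters,
#' -300/+50 bp TSS regions, 2 kb shores, the 10-or-more-reads-in-25%-of-
#' samples expressed-gene rule, and GO FDR 0.05.
#'
#' @param min_coverage,max_quantile coverage filters.
#' @param diff_threshold,q_threshold DMS thresholds.
#' @param dmr_window,dmr_min_sites DMR rule.
#' @param promoter_bp,tss_up,tss_down,shore_bp feature sizes (bp).
#' @param cgi_window,cgi_n_windows_avg,cgi_min_len,cgi_gc_min,cgi_obs_exp_min
#'   CpG-island detector parameters.
#' @param expressed_min_count,expressed_min_fraction expressed-gene rule.
#' @param relaxed_min_coverage,relaxed_min_samples background site rule.
#' @param go_fdr GO significance threshold.
#' @param perm_n_iter permutation iterations (0 disables the permutation
#'   stage).
#' @param seed integer seed for the permutation stage and any simulation.
#' @return object of class `run_config` (a validated list).
#' @export
run_config <- function(min_coverage = 10, max_quantile = 0.999,
                       diff_threshold = 25, q_threshold = 0.01,
                       dmr_window = 2000, dmr_min_sites = 3,
                       promoter_bp = 3000, tss_up = 300, tss_down = 50,
                       shore_bp = 2000,
                       cgi_window = 100, cgi_n_windows_avg = 10,
                       cgi_min_len = 200, cgi_gc_min = 0.5,
                       cgi_obs_exp_min = 0.6,
                       expressed_min_count = 10,
                       expressed_min_fraction = 0.25,
                       relaxed_min_coverage = 3, relaxed_min_samples = 1,
                       go_fdr = 0.05, perm_n_iter = 0, seed = 1L) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  stopifnot(all(num))
  stopifnot(cfg$min_coverage > 0, cfg$max_quantile > 0,
            cfg$max_quantile <= 1, cfg$diff_threshold > 0,
            cfg$q_threshold > 0, cfg$dmr_window > 0,
            cfg$dmr_min_sites > 0, cfg$promoter_bp > 0, cfg$tss_up > 0,
            cfg$tss_down > 0, cfg$shore_bp > 0, cfg$go_fdr > 0,
            cfg$perm_n_iter >= 0)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' The YAML round trip is lossless: `read_run_config(write_run_config(x))`
#' reproduces `x` exactly.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns the path invisibly;
#'   `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: strand merging and coverage filtering of the
#' per-sample coverage data, uniting into a methylation matrix, relaxed
#' background construction, feature-catalog building and site annotation,
#' DMS calling (with an optional permutation test), DMR calling, feature
#' and expressed-gene over-representation tests (site-level and
#' DMR-restricted), optional GO over-representation, and the
#' methylation-by-feature expression model. Stage failures abort with the
#' stage name; results computed so far are attached to the error condition.
#'
#' @param config a [run_config()].
#' @param study an `rrbs_study` from [simulate_study()], or `NULL` to pass
#'   file paths instead.
#' @param coverage_files named character vector of Bismark coverage paths
#'   (used when `study` is `NULL`).
#' @param metadata sample metadata data.frame (sample_id, habitat).
#' @param genome_fasta,genes_bed,expression_tsv input paths (when `study`
#'   is `NULL`).
#' @param gene2go,ontology optional GO inputs ([read_gene2go()] /
#'   [read_obo()] objects) enabling the GO stage.
#' @return object of class `pipeline_result`: list of per-stage outputs and
#'   a reproducibility `manifest` (seed, configuration digest, per-stage
#'   row counts, package version).
#' @export
run_pipeline <- function(config = run_config(), study = NULL,
                         coverage_files = NULL, metadata = NULL,
                         genome_fasta = NULL, genes_bed = NULL,
                         expression_tsv = NULL, gene2go = NULL,
                         ontology = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(study)) {
    stopifnot(inherits(study, "rrbs_study"))
    genome <- study$genome
    genes <- study$genes
    raw <- lapply(study$methylomes$samples, function(df) {
      data.frame(chrom = df$chrom, pos = df$start - 1L,
                 count_methylated = df$count_methylated,
                 count_total = df$count_methylated + df$count_unmethylated)
    })
    metadata <- study$methylomes$metadata
    counts <- study$expression$counts
  } else {
    stopifnot(!is.null(coverage_files), !is.null(metadata),
              !is.null(genome_fasta), !is.null(genes_bed))
    genome <- stage("read_genome", {
      g <- Biostrings::readDNAStringSet(genome_fasta)
      stats::setNames(as.character(g), sub("\\s.*$", "", names(g)))
    })
    genes <- stage("read_genes", read_genes_bed(genes_bed))
    raw <- stage("read_coverage",
                 lapply(coverage_files, read_coverage))
    counts <- if (!is.null(expression_tsv)) {
      stage("read_expression", {
        df <- utils::read.delim(expression_tsv, check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df[[1]]
        m
      })
    } else NULL
  }

  merged <- stage("merge_strands",
                  lapply(raw, merge_strands, genome = genome))
  filtered <- stage("filter_coverage", lapply(
    merged, filter_coverage,
    min_coverage = config$min_coverage,
    max_quantile = config$max_quantile))
  mm <- stage("unite", unite(filtered, metadata))
  background <- stage("relaxed_background", relaxed_background(
    merged, min_coverage = config$relaxed_min_coverage,
    min_samples = config$relaxed_min_samples))

  catalog <- stage("feature_catalog", build_feature_catalog(
    genome = genome, genes = genes,
    window = config$cgi_window,
    n_windows_avg = config$cgi_n_windows_avg,
    min_len = config$cgi_min_len, gc_min = config$cgi_gc_min,
    obs_exp_min = config$cgi_obs_exp_min, shore_bp = config$shore_bp))
  ann_sites <- stage("annotate_sites", annotate_sites(mm$sites, catalog))
  ann_bg <- stage("annotate_background",
                  annotate_sites(background, catalog))

  dms <- stage("call_dms", call_dms(
    mm, diff_threshold = config$diff_threshold,
    q_threshold = config$q_threshold))
  perm <- if (config$perm_n_iter >= 100) {
    stage("permutation_test", permutation_test(
      mm, n_iter = config$perm_n_iter, seed = config$seed,
      diff_threshold = config$diff_threshold,
      q_threshold = config$q_threshold))
  } else NULL
  dmrs <- stage("call_dmrs", call_dmrs(
    dms$dms, window = config$dmr_window,
    min_sites = config$dmr_min_sites))

  key_sites <- paste(ann_sites$chrom, ann_sites$pos)
  ann_dms <- ann_sites[match(paste(dms$dms$chrom, dms$dms$pos),
                             key_sites), , drop = FALSE]

  enrich <- stage("feature_enrichment", {
    classes <- c("regulatory", "promoter", "tss", "gene_body", "cgi",
                 "cgi_shore", "nonregulatory")
    out <- lapply(classes, function(cl) {
      tryCatch(feature_enrichment(ann_dms, ann_bg, cl),
               error = function(e) NULL)
    })
    stats::setNames(out, classes)
  })

  expr_enrich <- NULL
  expr_enrich_dmr <- NULL
  expr_fit <- NULL
  expressed <- NULL
  transformed <- NULL
  if (!is.null(counts)) {
    expressed <- stage("expressed_gene_flag", expressed_gene_flag(
      counts, min_count = config$expressed_min_count,
      min_fraction = config$expressed_min_fraction))
    expr_enrich <- stage("expression_enrichment", tryCatch(
      expression_enrichment(ann_dms, ann_bg, expressed),
      error = function(e) NULL))
    expr_enrich_dmr <- stage("expression_enrichment_dmr", tryCatch(
      expression_enrichment(ann_dms, ann_bg, expressed,
                            dmr_restricted = TRUE, dmrs = dmrs,
                            window = config$dmr_window),
      error = function(e) NULL))
    transformed <- stage("transform_counts", transform_counts(counts))
    ## the interaction model uses genes with usable expression levels:
    ## genes failing the expressed-gene rule carry counts too sparse for a
    ## meaningful log-scale response
    obs <- stage("build_observations",
                 build_observations(dms$dms, catalog, mm,
                                    transformed[expressed, , drop = FALSE]))
    expr_fit <- if (nrow(obs) > 0 &&
                      length(unique(obs$feature)) >= 2 &&
                      all(table(obs$feature) >= 3)) {
      stage("fit_meth_expr", fit_meth_expr(obs))
    } else NULL
  } else {
    obs <- NULL
  }

  go <- NULL
  if (!is.null(gene2go) && !is.null(ontology) && nrow(dmrs) > 0) {
    go <- stage("go_enrichment", {
      in_dmr <- rep(FALSE, nrow(ann_dms))
      for (i in seq_len(nrow(dmrs))) {
        in_dmr <- in_dmr | (ann_dms$chrom == dmrs$chrom[i] &
                              ann_dms$pos >= dmrs$start[i] &
                              ann_dms$pos < dmrs$end[i])
      }
      linked <- ann_dms[in_dmr & (ann_dms$promoter | ann_dms$tss |
                                    ann_dms$gene_body), , drop = FALSE]
      focal <- unique(unlist(linked$genes, use.names = FALSE))
      if (length(focal)) {
        go_enrichment(focal, gene2go, ontology,
                      background_genes = unique(genes$gene_id),
                      fdr_threshold = config$go_fdr)
      } else NULL
    })
  }

  cfg_yaml <- yaml::as.yaml(unclass(config))
  tmp <- tempfile()
  writeLines(cfg_yaml, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("urbanmeth")),
    seed = config$seed,
    config_digest = unname(tools::md5sum(tmp)),
    n_samples = nrow(metadata),
    n_sites_united = nrow(mm$sites),
    n_sites_background = nrow(background),
    n_dms = nrow(dms$dms),
    n_dmrs = nrow(dmrs),
    n_cgi = nrow(catalog$cgi),
    n_genes = if (!is.null(genes)) nrow(genes) else 0L,
    n_expressed = if (!is.null(expressed)) sum(expressed) else NA_integer_,
    n_obs_expression = if (!is.null(obs)) nrow(obs) else NA_integer_,
    pi0 = dms$pi0,
    permutation_p = if (!is.null(perm)) perm$p_value else NA_real_
  )
  unlink(tmp)

  structure(list(config = config, matrix = mm, background = background,
                 catalog = catalog, annotation_sites = ann_sites,
                 annotation_background = ann_bg, dms = dms,
                 permutation = perm, dmrs = dmrs,
                 feature_enrichment = enrich,
                 expression_enrichment = expr_enrich,
                 expression_enrichment_dmr = expr_enrich_dmr,
                 expressed = expressed, observations = obs,
                 expression_fit = expr_fit, go = go,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("pipeline_result\n")
  cat(sprintf("  %d united CpG units (background %d), %d samples\n",
              m$n_sites_united, m$n_sites_background, m$n_samples))
  cat(sprintf("  %d DMSs (pi0 = %.3f), %d DMRs, %d CpG islands\n",
              m$n_dms, m$pi0, m$n_dmrs, m$n_cgi))
  if (!is.na(m$permutation_p)) {
    cat(sprintf("  permutation p = %.4g\n", m$permutation_p))
  }
  if (!is.null(x$expression_fit)) {
    tssrow <- x$expression_fit$slopes$feature == "tss"
    if (any(tssrow)) {
      cat(sprintf("  TSS methylation-expression slope %+.4g\n",
                  x$expression_fit$slopes$slope[tssrow]))
    }
  }
  invisible(x)
}
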