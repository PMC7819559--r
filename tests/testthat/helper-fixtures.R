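# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# a small but complete simulated study used by several test files
small_study <- function() {
  if (is.null(.fixture_env$small_study)) {
    cfg <- sim_config(chrom_length = 2e5, n_cpg_sites = 1500,
                      n_true_dms = 30, n_tss_dms = 6, n_cgi = 4,
                      n_genes = 30, rng_seed = 42L)
    .fixture_env$small_study <- simulate_study(cfg)
  }
  .fixture_env$small_study
}

small_pipeline <- function() {
  if (is.null(.fixture_env$small_pipeline)) {
    .fixture_env$small_pipeline <-
      run_pipeline(run_config(), study = small_study())
  }
  .fixture_env$small_pipeline
}

# deterministic toy meth_matrix built from explicit per-site proportions
toy_matrix <- function(p_urban, p_forest, coverage = 30, n_per_group = 6,
                       seed = 7L, chrom = "chr1") {
  set.seed(seed)
  n <- length(p_urban)
  stopifnot(length(p_forest) == n)
  ids <- c(sprintf("u%02d", seq_len(n_per_group)),
           sprintf("f%02d", seq_len(n_per_group)))
  # variable per-cell coverage around the requested mean, as in real data
  Tt <- matrix(rpois(n * 2 * n_per_group, coverage - 5) + 5L,
               n, 2 * n_per_group, dimnames = list(NULL, ids))
  P <- cbind(matrix(p_urban, n, n_per_group),
             matrix(p_forest, n, n_per_group))
  M <- matrix(rbinom(length(Tt), as.vector(Tt), as.vector(P)),
              n, 2 * n_per_group, dimnames = list(NULL, ids))
  structure(list(
    sites = data.frame(chrom = chrom, pos = seq_len(n) * 50L),
    M = M, T = Tt,
    samples = data.frame(sample_id = ids,
                         habitat = rep(c("urban", "forest"),
                                       each = n_per_group))),
    class = "meth_matrix")
}

# write a minimal OBO ontology: a root, two mid terms, two leaves
#   leaf_a is_a mid_a is_a root; leaf_b part_of mid_b is_a root
write_toy_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: mid a",
    "is_a: GO:0000001 ! root process",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: mid b",
    "is_a: GO:0000001 ! root process",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: leaf a",
    "is_a: GO:0000002 ! mid a",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: leaf b",
    "relationship: part_of GO:0000003 ! mid b",
    "",
    "[Term]",
    "id: GO:0000006",
    "name: gone",
    "is_obsolete: true"
  ), path)
  path
}

# brute-force interval membership count for a set of point sites
brute_overlap_count <- function(sites, intervals) {
  vapply(seq_len(nrow(sites)), function(i) {
    sum(intervals$chrom == sites$chrom[i] &
          intervals$start <= sites$pos[i] &
          intervals$end > sites$pos[i])
  }, integer(1))
}

# exhaustive-window DMR oracle: enumerate candidate 2 kb windows anchored
# at every site, then deduplicate maximal clusters left to right, each site
# assigned at most once
dmr_oracle <- function(dms, window = 2000, min_sites = 3) {
  dms <- dms[order(dms$chrom, dms$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(dms$chrom)) {
    pos <- dms$pos[dms$chrom == ch]
    dirs <- dms$direction[dms$chrom == ch]
    unassigned <- rep(TRUE, length(pos))
    # all windows [s, s + window - 1] anchored at each site position
    wins <- lapply(pos, function(s) which(pos >= s & pos <= s + window - 1L))
    while (any(unassigned)) {
      i <- which(unassigned)[1]
      members <- intersect(wins[[i]], which(unassigned))
      unassigned[members] <- FALSE
      if (length(members) >= min_sites) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos[members[1]],
          end = pos[members[length(members)]] + 1L,
          n_sites = length(members),
          direction_class = classify_dmr(dirs[members]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      direction_class = character(0)))
  }
  do.call(rbind, out)
}

# exact upper-tail hypergeometric probability by exhaustive enumeration of
# all n-subsets of an N-element universe (feasible for N <= 12)
hyper_enum <- function(k, K, N, n) {
  subsets <- utils::combn(N, n)
  in_K <- colSums(subsets <= K)  # first K elements carry the property
  mean(in_K >= k)
}
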