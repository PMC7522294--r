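# Genomic summary statistics: mutation burden, shared/specific mutation
# partitioning, same-state CNV overlap, two-leaf phylogenies and Monte
# Carlo mutual-exclusivity testing.

#' Tumor mutation burden
#'
#' Somatic SNVs + indels per megabase of the interrogated coding region.
#' The denominator is an explicit parameter (e.g. the total target length
#' of the capture design); no exome size is hard-coded.
#'
#' @param catalog A [mutation_catalog()].
#' @param region_size_mb Size of the interrogated region in megabases (> 0).
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(catalog, region_size_mb) {
  if (!is.numeric(region_size_mb) || region_size_mb <= 0) {
    stop("region_size_mb must be positive")
  }
  nrow(catalog) / region_size_mb
}

#' Partition two catalogs into shared and specific mutations
#'
#' Mutations identical by `(chrom, pos, ref, alt)` in both components are
#' shared; the rest are specific to one component. `shared_pct` is
#' `100 * |shared| / |union|` (0, flagged, when both catalogs are empty).
#'
#' @param a,b [mutation_catalog()] objects.
#' @return A `partition_result`: list with `shared`, `specific_a`,
#'   `specific_b` (data.frames), `shared_pct` and `both_empty`.
#' @export
partition_mutations <- function(a, b) {
  ka <- mutation_keys(a)
  kb <- mutation_keys(b)
  shared_keys <- intersect(ka, kb)
  n_union <- length(union(ka, kb))
  both_empty <- n_union == 0L
  structure(list(
    shared = a[ka %in% shared_keys, , drop = FALSE],
    specific_a = a[!ka %in% shared_keys, , drop = FALSE],
    specific_b = b[!kb %in% shared_keys, , drop = FALSE],
    shared_pct = if (both_empty) 0 else 100 * length(shared_keys) / n_union,
    both_empty = both_empty),
    class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Shared %d / specific %d + %d mutations (%.1f%% shared)\n",
              nrow(x$shared), nrow(x$specific_a), nrow(x$specific_b),
              x$shared_pct))
  invisible(x)
}

state_ranges <- function(seg, st) {
  sel <- seg$state == st
  split(IRanges::IRanges(start = seg$start[sel] + 1L, end = seg$end[sel]),
        seg$chrom[sel])
}

#' Percentage of CNV length shared by two components
#'
#' Shared length is the number of bases covered by same-state segments
#' (gain with gain, loss with loss) in both samples; union length is the
#' number of bases covered by any CNV in either sample. Returns
#' `100 * shared / union` (0, flagged via attribute `both_empty`, when
#' neither sample has CNVs).
#'
#' @param a,b [segment_set()] objects.
#' @return Shared percentage in `[0, 100]`.
#' @export
cnv_shared_percentage <- function(a, b) {
  if (nrow(a) == 0L && nrow(b) == 0L) {
    return(structure(0, both_empty = TRUE))
  }
  shared <- 0
  for (st in c("gain", "loss")) {
    ra <- state_ranges(a, st)
    rb <- state_ranges(b, st)
    for (ch in intersect(names(ra), names(rb))) {
      shared <- shared +
        sum(IRanges::width(IRanges::intersect(IRanges::reduce(ra[[ch]]),
                                              IRanges::reduce(rb[[ch]]))))
    }
  }
  all_seg <- rbind(as.data.frame(a)[c("chrom", "start", "end")],
                   as.data.frame(b)[c("chrom", "start", "end")])
  union_len <- sum(vapply(split(all_seg, all_seg$chrom), function(s) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = s$start + 1L, end = s$end))))
  }, 0))
  100 * shared / union_len
}

#' Two-leaf phylogenetic tree from a mutation partition
#'
#' Builds the Newick string `"(E:bE,S:bS):t;"` in which the trunk length t
#' is the number of shared mutations of the given effect class and the
#' branch lengths are the components' specific counts. By default only
#' nonsynonymous mutations contribute.
#'
#' @param partition A `partition_result` from [partition_mutations()].
#' @param labels Two leaf labels, default `c("E", "S")` for the epithelial
#'   and sarcomatoid components.
#' @param restrict_to Effect class counted on trunk and branches.
#' @return A Newick string.
#' @export
build_phylogenetic_tree <- function(partition, labels = c("E", "S"),
                                    restrict_to = "nonsynonymous") {
  stopifnot(inherits(partition, "partition_result"), length(labels) == 2L)
  cnt <- function(df) sum(df$effect == restrict_to)
  sprintf("(%s:%d,%s:%d):%d;",
          labels[1L], cnt(partition$specific_a),
          labels[2L], cnt(partition$specific_b),
          cnt(partition$shared))
}

#' Monte Carlo test of mutual exclusivity of gene mutations
#'
#' The observed statistic is the number of samples carrying mutations in at
#' least two of the genes. The null distribution is generated by
#' independently permuting each gene's mutated-sample set (preserving each
#' gene's mutation count and the number of samples); small observed overlap
#' relative to the null indicates mutual exclusivity. The p-value uses the
#' add-one correction `p = (1 + #{overlap_perm <= overlap_obs}) /
#' (n_perm + 1)`, so it is never exactly 0.
#'
#' @param mat Binary genes x samples mutation indicator matrix (>= 2 genes).
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @param statistic `"overlap"` (default; samples with >= 2 mutated genes)
#'   or `"pairwise"` (sum over samples of the number of mutated gene pairs).
#' @return List with `observed_overlap`, `p`, `n_perm`, `statistic`.
#' @export
mutual_exclusivity_test <- function(mat, n_perm = 10000, seed = 1L,
                                    statistic = c("overlap", "pairwise")) {
  statistic <- match.arg(statistic)
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1))) stop("matrix entries must be 0/1")
  if (nrow(mat) < 2L) stop("mutual exclusivity needs >= 2 genes")
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  n_samples <- ncol(mat)
  counts <- rowSums(mat)
  stat <- function(hits_per_sample) {
    if (statistic == "overlap") sum(hits_per_sample >= 2L)
    else sum(choose(hits_per_sample, 2L))
  }
  observed <- stat(colSums(mat))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hits <- integer(n_samples)
      for (g in seq_along(counts)) {
        if (counts[g] > 0L) {
          sel <- sample.int(n_samples, counts[g])
          hits[sel] <- hits[sel] + 1L
        }
      }
      stat(hits)
    }, 0)
  })
  list(observed_overlap = observed,
       p = (1 + sum(null <= observed)) / (n_perm + 1),
       n_perm = n_perm, statistic = statistic)
}
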