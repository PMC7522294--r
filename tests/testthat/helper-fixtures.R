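# Fixture builders shared across test files. Everything is constructed in
# code; no data files.

# seeded draws that leave the session RNG untouched
runif_seeded <- function(n, min = 0, max = 1, seed = 1) {
  withr::with_seed(seed, stats::runif(n, min, max))
}
rnorm_seeded <- function(n, mean = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, stats::rnorm(n, mean, sd))
}

# catalog with one mutation per gene, unique positions from `offset`
toy_catalog <- function(genes, sample_id = "S", offset = 0L,
                        effect = "nonsynonymous") {
  n <- length(genes)
  mutation_catalog(data.frame(
    chrom = rep("chr1", n), pos = offset + seq_len(n),
    ref = rep("A", n), alt = rep("T", n), gene = genes,
    effect = rep(effect, length.out = n),
    stringsAsFactors = FALSE), sample_id)
}

# 76-gene EMT signature with epithelial/mesenchymal labels (synthetic
# stand-in for the published signature, which is an input file in practice)
emt_signature_fixture <- function() {
  data.frame(
    gene = c(sprintf("MES%02d", 1:38), "VIM", sprintf("EPI%02d", 1:36),
             "CDH1"),
    label = rep(c("mesenchymal", "epithelial"), c(39, 37)),
    stringsAsFactors = FALSE)
}

# single-subtype flat centroid covering the EMT signature plus background
flat_centroid_fixture <- function(signature, n_background = 20, level = 5) {
  genes <- c(signature$gene, sprintf("BG%02d", seq_len(n_background)))
  matrix(level, length(genes), 1L, dimnames = list(genes, "X"))
}

# brute-force Ward agglomeration: returns the list of merged index sets in
# merge order, computing the within-cluster ESS increase from scratch
ward_bruteforce <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# merge order of an hclust tree as sorted index sets
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (step in seq_len(nrow(hc$merge))) {
    members <- function(v) {
      if (v < 0) -v else sets[[v]]
    }
    sets[[step]] <- sort(c(members(hc$merge[step, 1L]),
                           members(hc$merge[step, 2L])))
  }
  sets
}
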