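test_that("tumor mutation burden is mutations per megabase", {
  expect_equal(compute_tmb(toy_catalog(character()), 30), 0)
  expect_equal(compute_tmb(toy_catalog(paste0("G", 1:100)), 50), 2)
  expect_equal(compute_tmb(toy_catalog(paste0("G", 1:142)), 20), 7.1)
  expect_error(compute_tmb(toy_catalog("A"), 0), "positive")
})

test_that("mutation partitioning is keyed on (chrom,pos,ref,alt) and symmetric", {
  a <- toy_catalog(paste0("G", 1:10), "A")
  expect_equal(partition_mutations(a, a)$shared_pct, 100)

  b_disjoint <- toy_catalog(paste0("G", 1:10), "B", offset = 100L)
  expect_equal(partition_mutations(a, b_disjoint)$shared_pct, 0)

  # shared 6, specific 2 + 2 => 60% of the union of 10
  a8 <- toy_catalog(paste0("G", 1:8), "A")              # positions 1..8
  b8 <- mutation_catalog(rbind(as.data.frame(a8)[1:6, ],
                               as.data.frame(toy_catalog(c("X", "Y"), "B",
                                                         offset = 50L))),
                         "B")
  part <- partition_mutations(a8, b8)
  expect_equal(part$shared_pct, 60)
  expect_equal(nrow(part$shared), 6)

  swapped <- partition_mutations(b8, a8)
  expect_equal(swapped$shared_pct, part$shared_pct)
  expect_identical(swapped$specific_a$gene, part$specific_b$gene)

  empty <- partition_mutations(toy_catalog(character()),
                               toy_catalog(character()))
  expect_equal(empty$shared_pct, 0)
  expect_true(empty$both_empty)
})

test_that("CNV shared percentage matches hand-computed interval arithmetic", {
  seg <- function(df, id = "s") segment_set(df, id)
  g <- function(start, end, state = "gain", chrom = "chr1") {
    data.frame(chrom = chrom, start = start, end = end, state = state)
  }

  cases <- list(
    # identical sets
    list(a = g(0, 100), b = g(0, 100), pct = 100),
    # state mismatch only: shared 0 over union 150
    list(a = g(0, 100, "gain"), b = g(50, 150, "loss"), pct = 0),
    # same-state partial overlap: 50 / 150
    list(a = g(0, 100), b = g(50, 150), pct = 100 * 50 / 150),
    # nested: 40 / 100
    list(a = g(0, 100), b = g(30, 70), pct = 40),
    # no overlap at all
    list(a = g(0, 100), b = g(200, 300), pct = 0),
    # different chromosomes never overlap
    list(a = g(0, 100, chrom = "chr1"), b = g(0, 100, chrom = "chr2"),
         pct = 0),
    # two chromosomes: chr1 shares 50, chr2 shares 0; union 150 + 100
    list(a = rbind(g(0, 100), g(0, 50, chrom = "chr2")),
         b = rbind(g(50, 150), g(50, 100, chrom = "chr2")),
         pct = 100 * 50 / 250),
    # mixed states in one sample: gain 50 shared, loss disjoint
    list(a = rbind(g(0, 100, "gain"), g(200, 250, "loss")),
         b = rbind(g(50, 150, "gain"), g(300, 350, "loss")),
         pct = 100 * 50 / 250),
    # one empty set
    list(a = g(0, 100), b = g(0, 0 + 1)[0, ], pct = 0),
    # touching but not overlapping (half-open): [0,100) vs [100,200)
    list(a = g(0, 100), b = g(100, 200), pct = 0)
  )
  for (cs in cases) {
    expect_equal(as.numeric(cnv_shared_percentage(seg(cs$a, "A"),
                                                  seg(cs$b, "B"))),
                 cs$pct, tolerance = 1e-12)
  }

  # split-segment invariance: [0,100) equals [0,60) + [60,100)
  whole <- seg(g(0, 100), "A")
  split2 <- seg(rbind(g(0, 60), g(60, 100)), "A")
  other <- seg(g(50, 150), "B")
  expect_equal(cnv_shared_percentage(whole, other),
               cnv_shared_percentage(split2, other))

  both_empty <- cnv_shared_percentage(seg(g(0, 1)[0, ], "A"),
                                      seg(g(0, 1)[0, ], "B"))
  expect_equal(as.numeric(both_empty), 0)
  expect_true(attr(both_empty, "both_empty"))
})

test_that("two-leaf trees encode shared/specific nonsynonymous counts", {
  a <- mutation_catalog(data.frame(
    chrom = "chr1", pos = 1:13, ref = "A", alt = "T",
    gene = paste0("G", 1:13),
    effect = c(rep("nonsynonymous", 13))), "E")
  b <- mutation_catalog(rbind(
    as.data.frame(a)[1:10, -1],
    data.frame(chrom = "chr1", pos = 101:105, ref = "A", alt = "T",
               gene = paste0("H", 1:5), effect = "nonsynonymous")), "S")
  part <- partition_mutations(a, b)
  expect_identical(build_phylogenetic_tree(part), "(E:3,S:5):10;")

  # synonymous mutations never contribute
  a_syn <- mutation_catalog(data.frame(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
    gene = paste0("G", 1:4),
    effect = c("nonsynonymous", "synonymous", "synonymous", "synonymous")),
    "E")
  b_syn <- mutation_catalog(as.data.frame(a_syn)[c(1, 2), -1], "S")
  tree_syn <- build_phylogenetic_tree(partition_mutations(a_syn, b_syn))
  expect_identical(tree_syn, "(E:0,S:0):1;")

  # zero shared => trunk 0
  disj <- partition_mutations(toy_catalog("A", "E"),
                              toy_catalog("B", "S", offset = 10L))
  expect_identical(build_phylogenetic_tree(disj), "(E:1,S:1):0;")
})

test_that("Newick output parses and round-trips branch lengths", {
  skip_if_not_installed("ape")
  part <- partition_mutations(
    toy_catalog(paste0("G", 1:12), "E"),
    mutation_catalog(as.data.frame(toy_catalog(paste0("G", 1:12), "E"))[1:7, -1],
                     "S"))
  nwk <- build_phylogenetic_tree(part)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("E", "S"))
  expect_equal(sort(tr$edge.length), sort(c(5, 0)))
  expect_equal(tr$root.edge, 7)
})

test_that("mutual exclusivity p-values agree with exhaustive enumeration", {
  m <- rbind(g1 = c(1, 0, 0, 0),
             g2 = c(0, 1, 0, 0),
             g3 = c(1, 1, 0, 0))
  mc <- mutual_exclusivity_test(m, n_perm = 10000, seed = 5)

  # enumerate all C(4,k) placements per gene and compute the exact p
  subsets <- function(k) utils::combn(4, k, simplify = FALSE)
  counts <- rowSums(m)
  total <- 0L
  le <- 0L
  for (s1 in subsets(counts[1])) for (s2 in subsets(counts[2])) {
    for (s3 in subsets(counts[3])) {
      hits <- tabulate(c(s1, s2, s3), 4)
      total <- total + 1L
      if (sum(hits >= 2) <= mc$observed_overlap) le <- le + 1L
    }
  }
  p_exact <- le / total
  mc_se <- sqrt(p_exact * (1 - p_exact) / mc$n_perm)
  expect_lt(abs(mc$p - p_exact), 3 * mc_se + 2 / (mc$n_perm + 1))
})

test_that("mutual exclusivity flags planted patterns and rejects bad input", {
  # perfectly exclusive: 6 genes, 10 distinct samples each, 60 samples
  excl <- matrix(0, 6, 60, dimnames = list(paste0("g", 1:6), NULL))
  for (g in 1:6) excl[g, (g - 1) * 10 + 1:10] <- 1
  res <- mutual_exclusivity_test(excl, n_perm = 10000, seed = 1)
  expect_equal(res$observed_overlap, 0)
  expect_lte(res$p, 0.01)

  # anti-exclusive extreme: all genes hit the same single sample
  anti <- matrix(0, 4, 20, dimnames = list(paste0("g", 1:4), NULL))
  anti[, 1] <- 1
  res_anti <- mutual_exclusivity_test(anti, n_perm = 2000, seed = 2)
  expect_equal(res_anti$observed_overlap, 1)
  expect_gt(res_anti$p, 0.9)

  expect_error(mutual_exclusivity_test(excl[1, , drop = FALSE], 2000),
               ">= 2 genes")
  expect_error(mutual_exclusivity_test(excl, n_perm = 10), ">= 1000")
  expect_error(mutual_exclusivity_test(matrix(2, 2, 2), 2000), "0/1")
})
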