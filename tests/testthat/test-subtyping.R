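tiny_beta <- function(beta, chrom = "chr1", is_cg = TRUE, has_snp = FALSE,
                      multimap = FALSE, detp = 0.001, bead = 10) {
  n <- nrow(beta)
  beta_matrix(
    beta,
    annotation = data.frame(probe = rownames(beta),
                            chrom = rep(chrom, length.out = n),
                            is_cg = rep(is_cg, length.out = n),
                            has_snp = rep(has_snp, length.out = n),
                            multimap = rep(multimap, length.out = n)),
    detection_p = matrix(rep(detp, length.out = n * ncol(beta)),
                         n, ncol(beta), dimnames = dimnames(beta)),
    beadcount = matrix(rep(bead, length.out = n * ncol(beta)),
                       n, ncol(beta), dimnames = dimnames(beta)))
}

test_that("probe filters remove each violation and report the first rule", {
  b <- matrix(0.5, 7, 20,
              dimnames = list(paste0("cg", 1:7), paste0("S", 1:20)))
  bm <- tiny_beta(b)
  bm$detection_p["cg1", 3] <- 0.02          # rule (i): one bad sample enough
  bm$beadcount["cg2", 1] <- 2               # 1/20 = 5% of samples
  bm$annotation$is_cg[3] <- FALSE
  bm$annotation$has_snp[4] <- TRUE
  bm$annotation$multimap[5] <- TRUE
  bm$annotation$chrom[6] <- "chrX"

  res <- filter_probes(bm)
  expect_identical(res$report$reason,
                   c("detection_p", "beadcount", "non_cg", "snp", "multimap",
                     "sex_chrom", "kept"))
  expect_identical(rownames(res$betas$beta), "cg7")

  # "chr"-less annotation dialect also triggers the sex-chromosome rule
  bm2 <- tiny_beta(b[1:2, ], chrom = c("Y", "12"))
  expect_identical(filter_probes(bm2)$report$reason, c("sex_chrom", "kept"))

  # first-violated-rule ordering: detection_p beats sex_chrom
  bm3 <- tiny_beta(b[1, , drop = FALSE], chrom = "chrX", detp = 0.5)
  expect_identical(filter_probes(bm3)$report$reason, "detection_p")

  # missing annotation errors name the blocked rule
  bm4 <- tiny_beta(b)
  bm4$annotation$is_cg <- NULL
  expect_error(filter_probes(bm4), "non_cg")
  bm5 <- tiny_beta(b)
  bm5$detection_p <- NULL
  expect_error(filter_probes(bm5), "detection_p")
})

test_that("probe filtering is idempotent", {
  sim <- generate_methylation_cohort(n_probes = 150, n_bad = 3, seed = 7)
  once <- filter_probes(sim$tumor)
  twice <- filter_probes(once$betas)
  expect_identical(rownames(twice$betas$beta), rownames(once$betas$beta))
  expect_true(all(twice$report$reason == "kept"))
  # every planted bad probe was removed
  expect_false(any(sim$truth$bad_probes %in% rownames(once$betas$beta)))
})

test_that("DMP calls enforce both the adjusted-p and median-delta thresholds", {
  n_p <- 1000
  base <- runif_seeded(n_p, 0.2, 0.45, seed = 5)
  noise <- function(seed) {
    matrix(rnorm_seeded(n_p * 10, 0, 0.05, seed = seed), n_p, 10)
  }
  a <- pmin(pmax(matrix(base, n_p, 10) + noise(1), 0), 1)
  b <- pmin(pmax(matrix(base, n_p, 10) + noise(2), 0), 1)
  b[1:30, ] <- pmin(b[1:30, ] + 0.35, 1)   # planted DMPs
  b[31:60, ] <- pmin(b[31:60, ] + 0.15, 1) # significant but small delta
  m <- cbind(a, b)
  rownames(m) <- sprintf("cg%04d", seq_len(n_p))
  colnames(m) <- c(paste0("A", 1:10), paste0("B", 1:10))

  res <- call_dmps(m, paste0("B", 1:10), paste0("A", 1:10))

  expect_true(all(res$is_dmp[1:30]))
  small <- res[31:60, ]
  expect_true(all(small$adj_p <= 0.05))      # significant...
  expect_false(any(small$is_dmp))            # ...but below |delta| 0.3

  # invariant: no emitted DMP violates either threshold
  dmps <- res[res$is_dmp, ]
  expect_true(all(dmps$adj_p <= 0.05 & abs(dmps$delta_beta) >= 0.3))

  # BH adjustment is monotone in p
  ord <- order(res$p)
  expect_true(all(diff(res$adj_p[ord]) >= -1e-15))

  expect_error(call_dmps(m, "B1", paste0("A", 1:10)), ">= 2 samples")
})

test_that("cancer-specific hypermethylation selection uses strict medians", {
  b <- function(vals, n = 5) {
    matrix(rep(vals, n), length(vals), n,
           dimnames = list(paste0("cg", seq_along(vals)), paste0("s", 1:n)))
  }
  tumor <- b(c(0.40, 0.90, 0.30, 0.35))
  normal <- b(c(0.15, 0.25, 0.10, 0.19))
  picked <- select_cancer_specific_hyper_probes(tumor, normal)
  # cg1: 0.15/0.40 in; cg2: normal 0.25 fails; cg3: tumor == 0.3 fails
  # (strict); cg4: in
  expect_identical(picked, c("cg1", "cg4"))
})

test_that("Ward clustering recovers planted blobs and matches brute force", {
  # planted 3-blob cohort: between-center distance >> within-cluster sd
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  labels <- rep(1:3, c(7, 5, 4))
  x <- centers[labels, ] + matrix(rnorm_seeded(32, 0, 0.5, seed = 6), 16, 2)
  rownames(x) <- paste0("s", 1:16)

  cl <- hierarchical_cluster(x, 3)
  expect_equal(length(unique(cl$assignment)), 3)
  tab <- table(cl$assignment, labels)
  expect_true(all(rowSums(tab > 0) == 1))  # pure clusters (up to renaming)
  expect_identical(unname(cl$assignment[1]), "C1")  # largest blob is C1

  # order invariance (same partition up to relabeling)
  perm <- c(16:1)
  cl2 <- hierarchical_cluster(x[perm, ], 3)
  expect_true(all(table(cl$assignment[rownames(x)[perm]],
                        cl2$assignment) %in%
                    c(0, table(cl2$assignment))))

  # identical samples, k = 1: all merge heights are 0
  same <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  cl_same <- hierarchical_cluster(same, 1)
  expect_equal(unique(unname(cl_same$assignment)), "C1")
  expect_equal(cl_same$hclust$height, rep(0, 3))

  # merge sequence equals brute-force Ward agglomeration on 6 points
  pts <- matrix(runif_seeded(12, 0, 10, seed = 11), 6, 2,
                dimnames = list(paste0("p", 1:6), NULL))
  hc <- hierarchical_cluster(pts, 2)$hclust
  expect_identical(hclust_merge_sets(hc), ward_bruteforce(pts))

  expect_error(hierarchical_cluster(x, 17), "exceeds")
  x_na <- x
  x_na[1, 2] <- NA
  expect_warning(hierarchical_cluster(x_na, 3), "missing")
})

test_that("co-methylation probe selection filters then ranks by MAD", {
  n_p <- 100
  probes <- sprintf("cg%03d", seq_len(n_p))
  base <- runif_seeded(n_p, 0.2, 0.4, seed = 3)
  normal <- matrix(base, n_p, 8, dimnames = list(probes, paste0("n", 1:8))) +
    matrix(rnorm_seeded(n_p * 8, 0, 0.01, seed = 4), n_p, 8)
  tumor <- matrix(base, n_p, 8, dimnames = list(probes, paste0("t", 1:8))) +
    matrix(rnorm_seeded(n_p * 8, 0, 0.01, seed = 5), n_p, 8)
  # 40 probes shifted by 0.3 (qualify); 10 shifted by 0.15 (below the 0.2
  # delta threshold however small their p-values)
  tumor[1:40, ] <- tumor[1:40, ] + 0.3
  tumor[41:50, ] <- tumor[41:50, ] + 0.15
  tumor <- pmin(pmax(tumor, 0), 1)
  normal <- pmin(pmax(normal, 0), 1)

  got <- select_comethylation_probes(tumor, normal, delta = 0.2, n_top = 20)
  expect_true(all(got %in% probes[1:40]))
  expect_length(got, 20)

  # MAD ranking oracle over the qualifying set
  mads <- apply(tumor[probes[1:40], ], 1, stats::mad)
  oracle <- probes[1:40][order(-mads, probes[1:40])][1:20]
  expect_identical(got, oracle)

  expect_warning(
    all40 <- select_comethylation_probes(tumor, normal, delta = 0.2,
                                         n_top = 90),
    "qualifying")
  expect_setequal(all40, probes[1:40])
})

test_that("nearest-centroid prediction recovers planted subtypes", {
  genes <- sprintf("g%03d", 1:200)
  centroids <- matrix(rnorm_seeded(200 * 4, 6, 1, seed = 2), 200, 4,
                      dimnames = list(genes, paste0("ST", 1:4)))

  # identity case: a sample equal to a centroid correlates at exactly 1
  expr_id <- 2^centroids - 1
  pred_id <- nearest_centroid_subtype(expr_id, centroids)
  expect_identical(pred_id$label, paste0("ST", 1:4))
  expect_equal(pred_id$cor_ST1[1], 1, tolerance = 1e-10)

  # anti-correlated sample goes to the other subtype of a 2-subtype predictor
  c2 <- cbind(ST1 = centroids[, 1], ST2 = 12 - centroids[, 1])  # reflection
  pred2 <- nearest_centroid_subtype(2^c2 - 1, c2)
  expect_identical(pred2$label, c("ST1", "ST2"))
  expect_equal(pred2$cor_ST1[2], -1, tolerance = 1e-10)

  # planted labels, 4 subtypes x 25 samples, noise 0.25 x centroid spread
  labels <- rep(paste0("ST", 1:4), each = 25)
  sim <- generate_expression_with_structure(centroids, labels,
                                            noise_sd = 0.25, seed = 3)
  pred <- nearest_centroid_subtype(sim$expr, centroids)
  expect_identical(pred$label, labels)
  cors <- as.matrix(pred[, grep("^cor_", names(pred))])
  expect_true(all(cors >= -1 & cors <= 1))

  # affine invariance: common scaling/offset of all log profiles
  aff <- 2^(2 * log2(sim$expr + 1) + 3) - 1
  expect_identical(nearest_centroid_subtype(aff, centroids)$label,
                   pred$label)

  expect_error(nearest_centroid_subtype(expr_id[1:5, ], centroids),
               "fewer than 10")

  flat <- matrix(7, 200, 1, dimnames = list(genes, "flat"))
  pf <- nearest_centroid_subtype(2^flat - 1, centroids)
  expect_true(is.na(pf$label))
  expect_true(pf$zero_variance)
})

test_that("methylation subtype similarity is a Euclidean nearest-profile rule", {
  probes <- paste0("cg", 1:300)
  profiles <- matrix(runif_seeded(300 * 3, 0.1, 0.9, seed = 4), 300, 3,
                     dimnames = list(probes, c("CIMP-low", "CIMP-int",
                                               "CIMP-high")))
  # a sample equal to a profile has distance 0 to it
  s0 <- profiles[, 2, drop = FALSE]
  colnames(s0) <- "s0"
  sim0 <- methylation_subtype_similarity(s0, profiles)
  expect_equal(sim0$distance["s0", "CIMP-int"], 0)
  expect_identical(unname(sim0$nearest["s0"]), "CIMP-int")

  # symmetry of the metric under swapping sample and profile roles
  s1 <- profiles[, 1, drop = FALSE]
  colnames(s1) <- "s1"
  d_ab <- methylation_subtype_similarity(s1, profiles[, 2, drop = FALSE])
  d_ba <- methylation_subtype_similarity(profiles[, 2, drop = FALSE],
                                         profiles[, 1, drop = FALSE])
  expect_equal(as.numeric(d_ab$distance), as.numeric(d_ba$distance))

  # planted mixtures are assigned to their source profile
  src <- rep(1:3, each = 20)
  samples <- pmin(pmax(
    profiles[, src] + matrix(rnorm_seeded(300 * 60, 0, 0.05, seed = 5),
                             300, 60), 0), 1)
  colnames(samples) <- paste0("s", 1:60)
  near <- methylation_subtype_similarity(samples, profiles)$nearest
  expect_gte(mean(near == colnames(profiles)[src]), 0.95)

  expect_error(methylation_subtype_similarity(
    matrix(0.5, 2, 1, dimnames = list(c("x1", "x2"), "s")), profiles),
    "common probes")
})
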