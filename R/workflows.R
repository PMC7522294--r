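# End-to-end workflows: wire stage outputs to stage inputs, centralize
# seeds and write a manifest of every output file with checksums. Outputs
# are deterministic given the global seed; stage sub-seeds are derived by
# derive_seed() and recorded in the manifest.

write_manifest <- function(out_dir, files, seed, sub_seeds) {
  manifest <- list(
    seed = seed,
    sub_seeds = sub_seeds,
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_error <- function(stage, msg) {
  stop("[stage: ", stage, "] ", msg, call. = FALSE)
}

#' Run the clonality workflow end to end
#'
#' Loads or simulates a reference cohort and a pair of tumor-component
#' catalogs, calibrates the clonality-index cutoff on the cohort, computes
#' the pair's partition, clonality index and clonal-relatedness call, and
#' writes the per-repeat calibration table, a per-pair JSON report, the
#' two-leaf Newick tree and a manifest with file checksums. Fully
#' deterministic given `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param simulate Simulate cohort and pair (`TRUE`) or read them from
#'   `cohort_path` / `pair_paths`.
#' @param cohort_path Multi-sample mutation TSV (when `simulate = FALSE`).
#' @param pair_paths Two mutation TSVs (when `simulate = FALSE`).
#' @param n_cohort Simulated cohort size.
#' @param pair_n_total,pair_shared_fraction Simulated pair parameters.
#' @param fractions,repeats Calibration parameters.
#' @return Invisibly, a list with the calibration, pair report and output
#'   paths.
#' @export
run_clonality_workflow <- function(out_dir, seed = 1L, simulate = TRUE,
                                   cohort_path = NULL, pair_paths = NULL,
                                   n_cohort = 30, pair_n_total = 100,
                                   pair_shared_fraction = 0.6,
                                   fractions = c(0.4, 0.6, 0.8),
                                   repeats = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub_seeds <- list(cohort = derive_seed(seed, "cohort"),
                    pair = derive_seed(seed, "pair"),
                    calibration = derive_seed(seed, "calibration"))
  config <- list(seed = seed, simulate = simulate, n_cohort = n_cohort,
                 pair_n_total = pair_n_total,
                 pair_shared_fraction = pair_shared_fraction,
                 fractions = fractions, repeats = repeats)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (simulate) {
    cohort <- generate_reference_cohort(n_cohort, seed = sub_seeds$cohort)
    pair <- generate_paired_components(pair_n_total, pair_shared_fraction,
                                       cohort, seed = sub_seeds$pair)
    write_mutation_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    write_mutation_tsv(list(pair$a, pair$b), file.path(out_dir, "pair.tsv"))
    write_ground_truth(pair$truth, file.path(out_dir, "ground_truth.json"))
    a <- pair$a; b <- pair$b
  } else {
    if (is.null(cohort_path) || !file.exists(cohort_path)) {
      stage_error("calibration", "cohort path missing or not found")
    }
    if (is.null(pair_paths) || length(pair_paths) != 2L ||
        !all(file.exists(pair_paths))) {
      stage_error("pair_input", "two existing pair mutation TSVs required")
    }
    cohort <- reference_cohort(read_mutation_tsv(cohort_path))
    a <- read_mutation_tsv(pair_paths[1L])[[1L]]
    b <- read_mutation_tsv(pair_paths[2L])[[1L]]
  }

  calib <- tryCatch(
    calibrate_cutoff(cohort, fractions = fractions, repeats = repeats,
                     seed = sub_seeds$calibration),
    error = function(e) stage_error("calibration", conditionMessage(e)))
  data.table::fwrite(
    data.frame(repeat_id = seq_along(calib$per_repeat_cutoffs),
               cutoff = calib$per_repeat_cutoffs),
    file.path(out_dir, "calibration.tsv"), sep = "\t", quote = FALSE)

  ci <- pair_clonality(a, b, cohort)
  call <- classify_relatedness(ci, calib)
  report <- list(sample_a = attr(a, "sample_id"),
                 sample_b = attr(b, "sample_id"),
                 M = ci$M, CI = ci$CI,
                 shared_pct = ci$partition$shared_pct,
                 cutoff_median = calib$cutoff_median,
                 ci95 = calib$ci95, call = call$call)
  jsonlite::write_json(report, file.path(out_dir, "pair_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  writeLines(build_phylogenetic_tree(ci$partition),
             file.path(out_dir, "tree.nwk"))
  data.table::fwrite(
    data.frame(class = c("shared", "specific_a", "specific_b"),
               n = c(nrow(ci$partition$shared), nrow(ci$partition$specific_a),
                     nrow(ci$partition$specific_b)),
               shared_pct = ci$partition$shared_pct),
    file.path(out_dir, "partition.tsv"), sep = "\t", quote = FALSE)

  files <- c("config.json", "calibration.tsv", "pair_report.json",
             "tree.nwk", "partition.tsv")
  if (simulate) files <- c(files, "cohort.tsv", "pair.tsv")
  write_manifest(out_dir, files, seed, sub_seeds)
  invisible(list(calibration = calib, report = report,
                 out_dir = out_dir, files = files))
}

#' Run the classification workflow end to end
#'
#' On simulated data (or user-supplied matrices), runs probe filtering,
#' cancer-specific hypermethylation probe selection, Ward/Euclidean
#' clustering into k molecular subgroups, leukocyte-fraction estimation per
#' tumor, EMT scoring, lymphocyte-infiltration ssGSEA scores and
#' nearest-centroid subtype prediction, writing one TSV per stage plus a
#' checksummed manifest.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param k Number of methylation clusters.
#' @param cluster_sizes Simulated samples per planted cluster.
#' @param n_probes Simulated probe count (passing filters).
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_classification_workflow <- function(out_dir, seed = 1L, k = 3,
                                        cluster_sizes = c(C1 = 8, C2 = 6,
                                                          C3 = 4),
                                        n_probes = 2000) {
  if (sum(cluster_sizes) == 0L) {
    stage_error("input", "empty sample set")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub_seeds <- list(methylation = derive_seed(seed, "methylation"),
                    lf_reference = derive_seed(seed, "lf_reference"),
                    expression = derive_seed(seed, "expression"))
  config <- list(seed = seed, k = k,
                 cluster_sizes = as.list(cluster_sizes),
                 n_probes = n_probes)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sim <- generate_methylation_cohort(n_probes = n_probes,
                                     cluster_sizes = cluster_sizes,
                                     seed = sub_seeds$methylation)

  filt <- filter_probes(sim$tumor)
  data.table::fwrite(filt$report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE)

  hyper <- select_cancer_specific_hyper_probes(filt$betas, sim$normal)
  writeLines(hyper, file.path(out_dir, "hyper_probes.txt"))

  clust <- hierarchical_cluster(t(filt$betas$beta[hyper, , drop = FALSE]), k)
  data.table::fwrite(
    data.frame(sample = names(clust$assignment),
               cluster = unname(clust$assignment)),
    file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE)

  # LF stage: simulate leukocyte/lung references and leukocyte-contaminated
  # tumor columns with known mixing fractions, then recover them
  lf_in <- with_seed(sub_seeds$lf_reference, {
    probes <- rownames(filt$betas$beta)
    n_ref <- length(probes)
    lung_profile <- stats::runif(n_ref, 0.05, 0.95)
    leuk_profile <- stats::runif(n_ref, 0.05, 0.95)
    rep_noise <- function(profile, prefix) {
      m <- clip01(matrix(profile, n_ref, 4) +
                    matrix(stats::rnorm(n_ref * 4, 0, 0.02), n_ref, 4))
      dimnames(m) <- list(probes, paste0(prefix, 1:4))
      m
    }
    n_tum <- ncol(filt$betas$beta)
    pi_true <- stats::runif(n_tum, 0.05, 0.6)
    mixed <- clip01(outer(leuk_profile, pi_true) +
                      sweep(filt$betas$beta, 2L, 1 - pi_true, `*`) +
                      matrix(stats::rnorm(n_ref * n_tum, 0, 0.01),
                             n_ref, n_tum))
    dimnames(mixed) <- dimnames(filt$betas$beta)
    list(lung = rep_noise(lung_profile, "L"),
         leuk = rep_noise(leuk_profile, "W"),
         mixed = mixed, pi_true = stats::setNames(pi_true, colnames(mixed)))
  })
  model <- select_lf_loci(lf_in$lung, lf_in$leuk,
                          n_per_direction = min(250, n_probes %/% 4))
  model <- estimate_pure_tumor_reference(lf_in$mixed, model)
  lf_tab <- do.call(rbind, lapply(colnames(lf_in$mixed), function(s) {
    est <- estimate_leukocyte_fraction(lf_in$mixed[, s], model)
    data.frame(sample = s, lf = est$lf, n_loci_used = est$n_loci_used)
  }))
  sim$truth$pi_true <- as.list(lf_in$pi_true)
  write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.json"))
  data.table::fwrite(lf_tab, file.path(out_dir, "leukocyte_fraction.tsv"),
                     sep = "\t", quote = FALSE)

  # Expression stage: planted subtypes + EMT + infiltration structure
  expr_sim <- with_seed(sub_seeds$expression, {
    n_genes <- 400
    genes <- c(sprintf("MES%02d", 1:38), sprintf("EPI%02d", 1:38),
               "VIM", "CDH1", sprintf("LI%02d", 1:18),
               sprintf("BG%03d", seq_len(n_genes - 96)))
    centroids <- matrix(stats::rnorm(length(genes) * k, 5, 1.5),
                        length(genes), k,
                        dimnames = list(genes, paste0("C", seq_len(k))))
    signature <- data.frame(
      gene = c(sprintf("MES%02d", 1:38), "VIM",
               sprintf("EPI%02d", 1:38), "CDH1"),
      label = rep(c("mesenchymal", "epithelial"), each = 39),
      stringsAsFactors = FALSE)
    labels <- unname(clust$assignment)
    generate_expression_with_structure(
      centroids, labels,
      emt_shift = 2, emt_positive = labels == "C1", signature = signature,
      infiltration_level = stats::runif(length(labels), 0, 2),
      infiltration_genes = sprintf("LI%02d", 1:18),
      noise_sd = 0.2,
      seed = derive_seed(seed, "expression_noise")) |>
      c(list(signature = signature, centroids = centroids))
  })
  colnames(expr_sim$expr) <- names(clust$assignment)
  emt <- emt_score(expr_sim$expr, expr_sim$signature)
  li <- liexpression_scores(expr_sim$expr, sprintf("LI%02d", 1:18))
  pred <- nearest_centroid_subtype(expr_sim$expr, expr_sim$centroids)
  data.table::fwrite(
    data.frame(sample = names(emt$scores), emt_score = unname(emt$scores)),
    file.path(out_dir, "emt_scores.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(li, file.path(out_dir, "liexpression.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(pred, file.path(out_dir, "subtype_prediction.tsv"),
                     sep = "\t", quote = FALSE)

  files <- c("config.json", "filter_report.tsv", "hyper_probes.txt",
             "clusters.tsv", "leukocyte_fraction.tsv", "emt_scores.tsv",
             "liexpression.tsv", "subtype_prediction.tsv")
  write_manifest(out_dir, files, seed, sub_seeds)
  invisible(list(clusters = clust, lf = lf_tab, emt = emt,
                 liexpression = li, prediction = pred,
                 truth = sim$truth, out_dir = out_dir, files = files))
}
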