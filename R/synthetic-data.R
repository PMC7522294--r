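# Seeded synthetic-data generators. Every generator plants a known ground
# truth (shared-mutation fraction, leukocyte fraction, subtype labels,
# differentially methylated probes, CNV overlap) that the matching analysis
# operation is expected to recover. Same seed + configuration gives
# bit-identical output; no generator touches global RNG state.

#' Default long-tailed per-gene mutation recurrence frequencies
#'
#' A few frequently mutated genes and many rare ones, the shape typical of
#' tumor-cohort mutation catalogs. This is generator configuration, not an
#' empirical claim about any cohort.
#'
#' @param n_genes Number of recurrently mutated genes to model.
#' @param max_freq Recurrence probability of the most frequent gene.
#' @return Named numeric vector of per-gene probabilities.
#' @export
default_gene_freq_spec <- function(n_genes = 200, max_freq = 0.5) {
  p <- max_freq / seq_len(n_genes)^0.8
  names(p) <- sprintf("G%03d", seq_len(n_genes))
  p
}

new_mutation_rows <- function(n, genes, pos_offset, effect_probs =
                                c(nonsynonymous = 0.7, synonymous = 0.2,
                                  other = 0.1)) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), effect = character(),
                      stringsAsFactors = FALSE))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = pos_offset + seq_len(n),
    ref = ref, alt = unname(alt), gene = genes,
    effect = sample(names(effect_probs), n, replace = TRUE,
                    prob = effect_probs),
    stringsAsFactors = FALSE)
}

#' Generate a reference cohort of unrelated mutation catalogs
#'
#' Each sample carries, independently, one mutation per gene with the
#' gene's recurrence probability, plus a Poisson number of private
#' passenger mutations in sample-specific genes. Every mutation receives a
#' globally unique position, so distinct catalogs never share an identical
#' variant: negative-control pairs built from such a cohort have clonality
#' index exactly 0.
#'
#' @param n_samples Number of catalogs (>= 2).
#' @param gene_freq_spec Named vector of per-gene recurrence probabilities
#'   in `[0, 1]`; see [default_gene_freq_spec()].
#' @param muts_per_sample Mean of the Poisson count of additional private
#'   passenger mutations per sample. The default of 100 reflects
#'   exome-scale catalogs of a high-burden carcinoma (several mutations per
#'   megabase over tens of megabases of coding sequence).
#' @param seed Integer seed.
#' @return A [reference_cohort()] with attribute `ground_truth`.
#' @export
generate_reference_cohort <- function(n_samples,
                                      gene_freq_spec = default_gene_freq_spec(),
                                      muts_per_sample = 100,
                                      seed = 1L) {
  stopifnot(is_count(n_samples), n_samples >= 2)
  if (any(gene_freq_spec < 0 | gene_freq_spec > 1) ||
      any(!is.finite(gene_freq_spec))) {
    stop("gene_freq_spec probabilities must lie in [0, 1]")
  }
  with_seed(seed, {
    pos_offset <- 0L
    catalogs <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      hit <- stats::runif(length(gene_freq_spec)) < gene_freq_spec
      driver_genes <- names(gene_freq_spec)[hit]
      n_pass <- stats::rpois(1L, muts_per_sample)
      pass_genes <- if (n_pass) sprintf("P%02d_%04d", i, seq_len(n_pass)) else character()
      genes <- c(driver_genes, pass_genes)
      rows <- new_mutation_rows(length(genes), genes, pos_offset)
      pos_offset <- pos_offset + length(genes)
      catalogs[[i]] <- mutation_catalog(rows, sprintf("S%03d", i))
    }
    cohort <- reference_cohort(catalogs)
    attr(cohort, "ground_truth") <- list(gene_freq_spec = as.list(gene_freq_spec),
                                         muts_per_sample = muts_per_sample,
                                         seed = seed)
    cohort
  })
}

#' Generate a pair of tumor-component catalogs with a planted shared fraction
#'
#' Builds a union of `n_total` mutations whose gene labels follow the
#' cohort's empirical gene frequencies, marks `round(shared_fraction *
#' n_total)` of them as shared (identical `(chrom,pos,ref,alt)` in both
#' components), and splits the remainder disjointly between the two
#' components. Positions are novel, outside the cohort's.
#'
#' @param n_total Size of the mutation union.
#' @param shared_fraction Planted fraction of shared mutations in `[0, 1]`.
#' @param cohort A [reference_cohort()] supplying gene frequencies.
#' @param seed Integer seed.
#' @return List with elements `a`, `b` (mutation catalogs) and `truth`.
#' @export
generate_paired_components <- function(n_total, shared_fraction, cohort,
                                       seed = 1L) {
  stopifnot(is_count(n_total), n_total >= 1)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  stopifnot(inherits(cohort, "reference_cohort"))
  gene_counts <- table(unlist(lapply(cohort$catalogs,
                                     function(cc) unique(cc$gene))))
  # weight by cohort recurrence so shared mutations carry informative p
  genes_pool <- names(gene_counts)
  with_seed(seed, {
    genes <- sample(genes_pool, n_total, replace = TRUE,
                    prob = as.numeric(gene_counts))
    rows <- new_mutation_rows(n_total, genes, pos_offset = 10^8)
    n_shared <- round(shared_fraction * n_total)
    idx <- sample.int(n_total)
    shared_idx <- idx[seq_len(n_shared)]
    rest <- idx[-seq_len(n_shared)]
    a_idx <- rest[seq_along(rest) %% 2L == 1L]
    b_idx <- setdiff(rest, a_idx)
    a <- mutation_catalog(rows[sort(c(shared_idx, a_idx)), , drop = FALSE],
                          "component_E")
    b <- mutation_catalog(rows[sort(c(shared_idx, b_idx)), , drop = FALSE],
                          "component_S")
    list(a = a, b = b,
         truth = list(shared_fraction = shared_fraction,
                      n_total = n_total, n_shared = n_shared, seed = seed))
  })
}

#' Generate one methylation mixture column with known leukocyte fraction
#'
#' Inverts the two-population mixture model: each locus' beta value is
#' `clip(beta_L * pi + beta_T * (1 - pi) + e, 0, 1)` with Gaussian noise
#' `e ~ N(0, noise_sd)`.
#'
#' @param n_loci Number of loci; must equal the profile lengths.
#' @param pi_true Planted leukocyte fraction in `[0, 1]`.
#' @param leukocyte_profile,tumor_profile Beta-value vectors in `[0, 1]`.
#' @param noise_sd Nonnegative noise standard deviation.
#' @param seed Integer seed.
#' @return Numeric vector of beta values (named like the profiles).
#' @export
generate_methylation_mixture <- function(n_loci, pi_true, leukocyte_profile,
                                         tumor_profile, noise_sd = 0,
                                         seed = 1L) {
  if (length(leukocyte_profile) != length(tumor_profile)) {
    stop("leukocyte and tumor profiles must have the same length")
  }
  stopifnot(n_loci == length(leukocyte_profile),
            pi_true >= 0, pi_true <= 1, noise_sd >= 0)
  with_seed(seed, {
    mix <- leukocyte_profile * pi_true + tumor_profile * (1 - pi_true)
    clip01(mix + stats::rnorm(n_loci, 0, noise_sd))
  })
}

#' Generate an expression matrix with planted subtype, EMT and infiltration structure
#'
#' Sample log2 profiles are their subtype centroid plus (i) an EMT shift
#' added to the mesenchymal signature genes of EMT-positive samples,
#' (ii) a per-sample infiltration level added to the infiltration-signature
#' genes, and (iii) additive Gaussian noise; linear-scale abundances
#' `2^x - 1` (floored at 0) are returned.
#'
#' @param centroids Genes x subtypes matrix on the log2 scale.
#' @param labels Character vector, one subtype per sample; must name
#'   centroid columns.
#' @param emt_shift Log2-units shift applied to mesenchymal genes of
#'   EMT-positive samples.
#' @param emt_positive Logical per sample; default all `FALSE`.
#' @param signature EMT signature data.frame (`gene`, `label`); required
#'   when `emt_shift != 0`.
#' @param infiltration_level Numeric per sample, added to
#'   `infiltration_genes`; default 0.
#' @param infiltration_genes Character vector of signature genes.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param seed Integer seed.
#' @return List with `expr` (genes x samples, linear scale) and `truth`.
#' @export
generate_expression_with_structure <- function(centroids, labels,
                                               emt_shift = 0,
                                               emt_positive = NULL,
                                               signature = NULL,
                                               infiltration_level = 0,
                                               infiltration_genes = character(),
                                               noise_sd = 0.1, seed = 1L) {
  centroids <- as.matrix(centroids)
  if (!all(labels %in% colnames(centroids))) {
    stop("unknown subtype label(s): ",
         paste(setdiff(labels, colnames(centroids)), collapse = ", "))
  }
  n <- length(labels)
  emt_positive <- emt_positive %||% rep(FALSE, n)
  infiltration_level <- rep(infiltration_level, length.out = n)
  mes_genes <- character()
  if (emt_shift != 0) {
    if (is.null(signature)) stop("signature required when emt_shift != 0")
    mes_genes <- intersect(signature$gene[signature$label == "mesenchymal"],
                           rownames(centroids))
  }
  inf_genes <- intersect(infiltration_genes, rownames(centroids))
  with_seed(seed, {
    logx <- centroids[, labels, drop = FALSE] +
      matrix(stats::rnorm(nrow(centroids) * n, 0, noise_sd),
             nrow(centroids), n)
    if (length(mes_genes)) {
      logx[mes_genes, emt_positive] <- logx[mes_genes, emt_positive] + emt_shift
    }
    if (length(inf_genes)) {
      logx[inf_genes, ] <- logx[inf_genes, ] +
        matrix(infiltration_level, length(inf_genes), n, byrow = TRUE)
    }
    expr <- pmax(2^logx - 1, 0)
    colnames(expr) <- sprintf("T%03d", seq_len(n))
    list(expr = expr,
         truth = list(labels = stats::setNames(labels, colnames(expr)),
                      emt_positive = stats::setNames(emt_positive, colnames(expr)),
                      infiltration_level = stats::setNames(infiltration_level,
                                                           colnames(expr)),
                      emt_shift = emt_shift, seed = seed))
  })
}

#' Generate a pair of CNV segment sets with a planted shared percentage
#'
#' The genome is tiled into equal slots, one candidate segment per slot;
#' `round(target_shared_pct / 100 * n_segments)` segments are present in
#' both samples with the same state, and the remainder alternate between
#' the two samples, so the recovered same-state shared/union length
#' percentage equals the target up to the slot granularity (within 2
#' percentage points for the default 100 slots).
#'
#' @param genome_length Total genome length in bases.
#' @param target_shared_pct Target shared percentage in `[0, 100]`.
#' @param seed Integer seed.
#' @param n_segments Number of candidate segments (granularity of the
#'   planted percentage).
#' @param cnv_fraction Fraction of the genome covered by the CNV union.
#' @return List with `a`, `b` ([segment_set()]s) and `truth`.
#' @export
generate_cnv_pair <- function(genome_length = 3e6, target_shared_pct = 50,
                              seed = 1L, n_segments = 100,
                              cnv_fraction = 0.3) {
  if (target_shared_pct < 0 || target_shared_pct > 100) {
    stop("target_shared_pct must lie in [0, 100]")
  }
  stopifnot(is_count(n_segments), n_segments >= 1)
  slot <- floor(genome_length / n_segments)
  width <- max(1L, floor(slot * cnv_fraction))
  with_seed(seed, {
    offset <- floor(stats::runif(n_segments, 0, slot - width))
    start <- (seq_len(n_segments) - 1L) * slot + offset
    state <- sample(c("gain", "loss"), n_segments, replace = TRUE)
    n_shared <- round(target_shared_pct / 100 * n_segments)
    role <- rep(c("a", "b"), length.out = n_segments - n_shared)
    role <- c(rep("shared", n_shared), role)[sample.int(n_segments)]
    seg <- data.frame(chrom = "chr1", start = start, end = start + width,
                      state = state, stringsAsFactors = FALSE)
    a <- segment_set(seg[role != "b", , drop = FALSE], "component_E")
    b <- segment_set(seg[role != "a", , drop = FALSE], "component_S")
    list(a = a, b = b,
         truth = list(target_shared_pct = target_shared_pct,
                      n_segments = n_segments, n_shared = n_shared,
                      seed = seed))
  })
}

#' Generate a methylation cohort with planted clusters and probe artefacts
#'
#' Produces an annotated tumor beta matrix whose samples fall into planted
#' clusters (distinct mean methylation profiles over a set of informative
#' probes), a matched normal matrix, and annotation/detection/beadcount
#' fields that deliberately include probes violating each of the six probe
#' filters, plus a planted set of differentially methylated probes between
#' the first two clusters.
#'
#' @param n_probes Number of probes passing the filters.
#' @param cluster_sizes Named integer vector, samples per planted cluster.
#' @param n_informative Probes carrying cluster-specific methylation.
#' @param n_bad Probes planted to violate each filter rule (total added
#'   probes = 6 * n_bad).
#' @param noise_sd Gaussian noise sd on beta values.
#' @param seed Integer seed.
#' @return List with `tumor` (annotated [beta_matrix()]), `normal`
#'   (beta_matrix), and `truth` (cluster labels, informative/bad probes).
#' @export
generate_methylation_cohort <- function(n_probes = 2000,
                                        cluster_sizes = c(C1 = 8, C2 = 6, C3 = 4),
                                        n_informative = round(0.15 * n_probes),
                                        n_bad = 5,
                                        noise_sd = 0.05,
                                        seed = 1L) {
  stopifnot(n_informative <= n_probes)
  k <- length(cluster_sizes)
  n <- sum(cluster_sizes)
  labels <- rep(names(cluster_sizes), cluster_sizes)
  with_seed(seed, {
    probes <- sprintf("cg%06d", seq_len(n_probes))
    # normals (and uninformative tumor probes) are unmethylated; informative
    # probes are cancer-specifically hypermethylated, at a level drawn
    # independently per cluster so the clusters are separable on them
    base <- stats::runif(n_probes, 0.05, 0.18)
    centers <- matrix(rep(base, k), n_probes, k,
                      dimnames = list(probes, names(cluster_sizes)))
    info <- sort(sample.int(n_probes, n_informative))
    centers[info, ] <- stats::runif(n_informative * k, 0.4, 0.9)
    beta <- centers[, match(labels, names(cluster_sizes)), drop = FALSE] +
      matrix(stats::rnorm(n_probes * n, 0, noise_sd), n_probes, n)
    beta <- clip01(beta)
    rownames(beta) <- probes
    colnames(beta) <- sprintf("T%03d", seq_len(n))
    # normals: uniformly low methylation
    n_norm <- max(4L, ceiling(n / 2))
    normal <- clip01(matrix(rep(base, n_norm), n_probes, n_norm) +
                       stats::rnorm(n_probes * n_norm, 0, noise_sd))
    rownames(normal) <- probes
    colnames(normal) <- sprintf("N%03d", seq_len(n_norm))
    # add probes violating each filter rule
    bad_reasons <- c("detection_p", "beadcount", "non_cg", "snp",
                     "multimap", "sex_chrom")
    n_extra <- n_bad * length(bad_reasons)
    extra_probes <- sprintf("bad%04d", seq_len(n_extra))
    extra_beta <- clip01(matrix(stats::runif(n_extra * n, 0.2, 0.8),
                                n_extra, n,
                                dimnames = list(extra_probes, colnames(beta))))
    all_beta <- rbind(beta, extra_beta)
    n_all <- n_probes + n_extra
    ann <- data.frame(
      probe = rownames(all_beta),
      chrom = paste0("chr", sample(1:22, n_all, replace = TRUE)),
      is_cg = TRUE, has_snp = FALSE, multimap = FALSE,
      stringsAsFactors = FALSE)
    detp <- matrix(0.001, n_all, n, dimnames = dimnames(all_beta))
    bead <- matrix(10, n_all, n, dimnames = dimnames(all_beta))
    reason_of <- rep(bad_reasons, each = n_bad)
    for (i in seq_len(n_extra)) {
      row <- n_probes + i
      switch(reason_of[i],
             detection_p = { detp[row, sample.int(n, 1L)] <- 0.05 },
             beadcount = { bead[row, ] <- 2 },
             non_cg = { ann$is_cg[row] <- FALSE },
             snp = { ann$has_snp[row] <- TRUE },
             multimap = { ann$multimap[row] <- TRUE },
             sex_chrom = { ann$chrom[row] <- sample(c("chrX", "chrY"), 1L) })
    }
    tumor <- beta_matrix(all_beta, annotation = ann, detection_p = detp,
                         beadcount = bead)
    truth <- list(labels = stats::setNames(labels, colnames(beta)),
                  informative_probes = probes[info],
                  cluster_centers = centers[info, , drop = FALSE],
                  bad_probes = extra_probes,
                  seed = seed)
    list(tumor = tumor, normal = beta_matrix(normal), truth = truth)
  })
}
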