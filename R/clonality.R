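# Clonality-index testing of common origin between two tumor components.
#
# For the M mutations shared by two components, each mutation's chance of
# appearing in both samples independently is P(X) = C(n,k) p^k (1-p)^(n-k)
# with n = k = 2, i.e. p^2, where p is the mutation's background
# probability in a reference cohort of unrelated tumors. The clonality
# index CI = -log10 prod_m P(X)_m grows as shared mutations become less
# explicable by chance; CI above a resampling-calibrated cutoff calls the
# pair clonally related.

cohort_index <- function(cohort) {
  stopifnot(inherits(cohort, "reference_cohort"))
  key_sets <- lapply(cohort$catalogs, function(cc) unique(mutation_keys(cc)))
  gene_sets <- lapply(cohort$catalogs, function(cc) unique(cc$gene))
  list(key_counts = table(unlist(key_sets)),
       gene_counts = table(unlist(gene_sets)),
       N = cohort$N)
}

#' Estimate the background probability of a mutation
#'
#' The background probability p is the add-one-smoothed fraction of
#' reference-cohort samples carrying the mutation: `p = (c + 1) / (N + 1)`.
#' The count c is hotspot-level (samples with the exact
#' `(chrom,pos,ref,alt)` variant) when the identical variant recurs in the
#' cohort, and gene-level (samples with any mutation in the same gene)
#' otherwise. Smoothing keeps p > 0 for private mutations.
#'
#' @param mutation One-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt` and `gene`.
#' @param cohort A [reference_cohort()].
#' @return List with `p`, the count `c`, and `level` (`"hotspot"` or
#'   `"gene"`).
#' @export
estimate_background_probability <- function(mutation, cohort) {
  idx <- if (inherits(cohort, "reference_cohort")) cohort_index(cohort) else cohort
  key <- paste(mutation$chrom, mutation$pos, mutation$ref, mutation$alt,
               sep = ":")
  c_hot <- idx$key_counts[key]
  if (!is.na(c_hot) && c_hot >= 1L) {
    cc <- as.integer(c_hot)
    level <- "hotspot"
  } else {
    gene <- mutation$gene
    if (is.null(gene) || is.na(gene) || !nzchar(gene)) {
      stop("mutation lacks a gene annotation needed for gene-level fallback")
    }
    cg <- idx$gene_counts[gene]
    cc <- if (is.na(cg)) 0L else as.integer(cg)
    level <- "gene"
  }
  list(p = (cc + 1) / (idx$N + 1), c = cc, level = level)
}

background_probabilities <- function(mutations, idx) {
  # vectorized equivalent of estimate_background_probability() per row
  if (nrow(mutations) == 0L) return(numeric())
  keys <- mutation_keys(mutations)
  c_hot <- as.integer(idx$key_counts[keys])
  gene_fallback <- is.na(c_hot)
  cc <- c_hot
  if (any(gene_fallback)) {
    genes <- mutations$gene[gene_fallback]
    if (any(is.na(genes) | !nzchar(genes))) {
      stop("mutation lacks a gene annotation needed for gene-level fallback")
    }
    cg <- as.integer(idx$gene_counts[genes])
    cg[is.na(cg)] <- 0L
    cc[gene_fallback] <- cg
  }
  (cc + 1) / (idx$N + 1)
}

#' Compute the clonality index from shared-mutation background probabilities
#'
#' `CI = -log10 prod_m P(X)_m` with `P(X) = p^2` (binomial probability of
#' observing the mutation in both of two samples). The product is evaluated
#' in log space, so there is no underflow even for thousands of shared
#' mutations with small p. An empty shared set gives CI = 0.
#'
#' @param p Numeric vector of background probabilities in `(0, 1]`, one per
#'   shared mutation.
#' @return A `clonality_result`: list with `M`, `per_mutation_P` (the
#'   `P(X)` values) and `CI`.
#' @export
compute_clonality_index <- function(p) {
  p <- as.numeric(p)
  if (length(p) && (any(!is.finite(p)) || any(p <= 0) || any(p > 1))) {
    stop("background probabilities must lie in (0, 1]")
  }
  ci <- if (length(p)) -2 * sum(log10(p)) else 0
  structure(list(M = length(p), per_mutation_P = p^2, CI = ci),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat(sprintf("Clonality index: CI = %.3f over M = %d shared mutations\n",
              x$CI, x$M))
  invisible(x)
}

#' Clonality index of a pair of catalogs against a reference cohort
#'
#' Partitions the two catalogs into shared and specific mutations, looks up
#' each shared mutation's background probability in the cohort, and applies
#' [compute_clonality_index()]. Symmetric in the order of the catalogs.
#'
#' @param a,b [mutation_catalog()] objects.
#' @param cohort A [reference_cohort()] (or a prebuilt internal index).
#' @return A `clonality_result` with an added `partition` element.
#' @export
pair_clonality <- function(a, b, cohort) {
  idx <- if (inherits(cohort, "reference_cohort")) cohort_index(cohort) else cohort
  part <- partition_mutations(a, b)
  p <- background_probabilities(part$shared, idx)
  res <- compute_clonality_index(p)
  res$partition <- part
  res
}

#' Build a positive-control pair from one catalog
#'
#' Draws two independent uniform subsets, each of size
#' `round(fraction * |catalog|)`, from the same catalog; the pair's shared
#' mutations are the subsets' intersection. Such a pair is known clonal by
#' construction.
#'
#' @param catalog A nonempty [mutation_catalog()].
#' @param fraction Subset fraction (the calibration uses 0.4, 0.6, 0.8).
#' @param seed Integer seed.
#' @return List of two catalogs.
#' @export
make_positive_control_pair <- function(catalog, fraction, seed = 1L) {
  n <- nrow(catalog)
  if (n == 0L) stop("cannot subsample an empty catalog")
  size <- round(fraction * n)
  sid <- attr(catalog, "sample_id")
  with_seed(seed, {
    i1 <- sort(sample.int(n, size))
    i2 <- sort(sample.int(n, size))
    list(mutation_catalog(catalog[i1, , drop = FALSE], paste0(sid, "_r1")),
         mutation_catalog(catalog[i2, , drop = FALSE], paste0(sid, "_r2")))
  })
}

#' Sample negative-control pairs of unrelated cohort samples
#'
#' Distinct unordered pairs of different cohort samples, sampled without
#' replacement among all `C(N, 2)` pairs.
#'
#' @param cohort A [reference_cohort()].
#' @param n_pairs Number of pairs; at most `C(N, 2)`.
#' @param seed Integer seed.
#' @return List of catalog pairs.
#' @export
make_negative_control_pairs <- function(cohort, n_pairs, seed = 1L) {
  stopifnot(inherits(cohort, "reference_cohort"))
  all_pairs <- utils::combn(cohort$N, 2L)
  if (n_pairs > ncol(all_pairs)) {
    stop("n_pairs exceeds the number of distinct pairs C(N, 2) = ",
         ncol(all_pairs))
  }
  with_seed(seed, {
    take <- sample.int(ncol(all_pairs), n_pairs)
    lapply(take, function(j) {
      list(cohort$catalogs[[all_pairs[1L, j]]],
           cohort$catalogs[[all_pairs[2L, j]]])
    })
  })
}

youden_optimal_cutoff <- function(pos, neg) {
  vals <- sort(unique(c(pos, neg)))
  if (length(vals) < 2L) {
    stop("all clonality indices are identical; cutoff undefined")
  }
  candidates <- (vals[-1L] + vals[-length(vals)]) / 2
  j <- vapply(candidates, function(cut) {
    mean(pos > cut) + mean(neg <= cut) - 1
  }, 0)
  best <- max(j)
  # ties broken toward the larger threshold (favoring specificity)
  cut <- max(candidates[j >= best - 1e-12])
  structure(cut, sensitivity = mean(pos > cut), specificity = mean(neg <= cut),
            J = best)
}

#' Calibrate the clonality-index cutoff by resampling
#'
#' Per repeat: positive-control pairs are built from every cohort sample at
#' every fraction (two independent subsets each), an equal number of
#' negative-control pairs are drawn from unrelated cohort samples, all
#' pairs' clonality indices are computed, and the cutoff maximizing
#' Youden's J (sensitivity + specificity - 1, candidate thresholds at
#' midpoints of the sorted pooled CI values, ties toward the larger
#' threshold) is recorded. The repeats' median and 2.5/97.5 percentiles
#' summarize the cutoff.
#'
#' @param cohort A [reference_cohort()].
#' @param fractions Positive-control subset fractions.
#' @param repeats Number of calibration repeats.
#' @param seed Integer seed; repeat r uses a derived sub-seed.
#' @return A `cutoff_calibration`: list with `per_repeat_cutoffs`,
#'   `cutoff_median`, `ci95`, `fractions`, `repeats`.
#' @export
calibrate_cutoff <- function(cohort, fractions = c(0.4, 0.6, 0.8),
                             repeats = 100, seed = 1L) {
  stopifnot(inherits(cohort, "reference_cohort"))
  idx <- cohort_index(cohort)
  n_pos <- cohort$N * length(fractions)
  if (n_pos > choose(cohort$N, 2L)) {
    stop("cohort too small to draw ", n_pos, " negative pairs")
  }
  cutoffs <- vapply(seq_len(repeats), function(r) {
    seed_r <- derive_seed(seed, paste0("calibration_repeat_", r))
    pos_ci <- unlist(lapply(seq_len(cohort$N), function(i) {
      vapply(seq_along(fractions), function(fi) {
        pr <- make_positive_control_pair(
          cohort$catalogs[[i]], fractions[fi],
          seed = derive_seed(seed_r, paste0("pos_", i, "_", fi)))
        pair_clonality(pr[[1L]], pr[[2L]], idx)$CI
      }, 0)
    }))
    negs <- make_negative_control_pairs(cohort, n_pos,
                                        seed = derive_seed(seed_r, "neg"))
    neg_ci <- vapply(negs, function(pr) pair_clonality(pr[[1L]], pr[[2L]],
                                                       idx)$CI, 0)
    as.numeric(youden_optimal_cutoff(pos_ci, neg_ci))
  }, 0)
  structure(list(per_repeat_cutoffs = cutoffs,
                 cutoff_median = stats::median(cutoffs),
                 ci95 = stats::quantile(cutoffs, c(0.025, 0.975),
                                        names = FALSE),
                 fractions = fractions, repeats = repeats, seed = seed),
            class = "cutoff_calibration")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf(
    "CI cutoff calibration: median %.3f (95%% interval %.3f-%.3f) over %d repeats\n",
    x$cutoff_median, x$ci95[1], x$ci95[2], x$repeats))
  invisible(x)
}

#' Classify clonal relatedness of a pair
#'
#' A pair is called `"clonal"` iff its clonality index strictly exceeds the
#' calibrated cutoff median; the comparison against the cutoff's 95%
#' interval bounds is reported alongside.
#'
#' @param ci A `clonality_result` or a single CI value.
#' @param calibration A `cutoff_calibration`.
#' @return List with `call`, `CI`, `cutoff_median`, `ci95`,
#'   `above_ci95_upper`, `below_ci95_lower`.
#' @export
classify_relatedness <- function(ci, calibration) {
  stopifnot(inherits(calibration, "cutoff_calibration"))
  ci_val <- if (inherits(ci, "clonality_result")) ci$CI else as.numeric(ci)
  list(call = if (ci_val > calibration$cutoff_median) "clonal" else "not_clonal",
       CI = ci_val,
       cutoff_median = calibration$cutoff_median,
       ci95 = calibration$ci95,
       above_ci95_upper = ci_val > calibration$ci95[2],
       below_ci95_lower = ci_val < calibration$ci95[1])
}
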