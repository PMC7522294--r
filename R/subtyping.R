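# Methylation-based molecular classification and transcriptional subtype
# prediction: probe filtering, differential methylation calling,
# cancer-specific probe selection, Ward/Euclidean hierarchical clustering,
# nearest-centroid prediction and methylation-subtype similarity.

#' Filter methylation probes by the six standard quality rules
#'
#' A probe is removed if, in this order: (i) its detection p-value exceeds
#' 0.01 in at least one sample; (ii) its beadcount is below 3 in at least
#' 5% of samples; (iii) it is a non-CpG probe; (iv) it carries a SNP;
#' (v) it aligns to multiple genomic sites; (vi) it lies on the X or Y
#' chromosome. The report records each probe's first violated rule (the
#' kept set is order-independent). Filtering is idempotent.
#'
#' @param betas An annotated [beta_matrix()] with `detection_p` and
#'   `beadcount`.
#' @return List with `betas` (filtered `beta_matrix`) and `report`
#'   (data.frame `probe`, `reason`; reason `"kept"` for surviving probes).
#' @export
filter_probes <- function(betas) {
  stopifnot(inherits(betas, "beta_matrix"))
  ann <- betas$annotation
  need <- function(ok, rule, what) {
    if (!ok) stop("missing annotation '", what, "' required by the ",
                  rule, " rule")
  }
  need(!is.null(betas$detection_p), "detection_p", "detection_p matrix")
  need(!is.null(betas$beadcount), "beadcount", "beadcount matrix")
  need(!is.null(ann) && "is_cg" %in% names(ann), "non_cg", "is_cg")
  need("has_snp" %in% names(ann), "snp", "has_snp")
  need("multimap" %in% names(ann), "multimap", "multimap")
  need("chrom" %in% names(ann), "sex_chrom", "chrom")
  sexual <- sub("^chr", "", ann$chrom) %in% c("X", "Y")
  rules <- cbind(
    detection_p = apply(betas$detection_p > 0.01, 1L, any),
    beadcount = rowMeans(betas$beadcount < 3) >= 0.05,
    non_cg = !ann$is_cg,
    snp = ann$has_snp,
    multimap = ann$multimap,
    sex_chrom = sexual)
  first_violation <- apply(rules, 1L, function(v) {
    hit <- which(v)
    if (length(hit)) colnames(rules)[hit[1L]] else "kept"
  })
  keep <- first_violation == "kept"
  filtered <- beta_matrix(
    betas$beta[keep, , drop = FALSE],
    annotation = ann[keep, , drop = FALSE],
    detection_p = betas$detection_p[keep, , drop = FALSE],
    beadcount = betas$beadcount[keep, , drop = FALSE])
  list(betas = filtered,
       report = data.frame(probe = rownames(betas$beta),
                           reason = first_violation,
                           stringsAsFactors = FALSE))
}

moderated_fit <- function(beta, groups) {
  design <- cbind(intercept = 1, group = groups)
  fit <- limma::lmFit(beta, design)
  zero_var <- all(fit$sigma < 1e-12, na.rm = TRUE)
  if (zero_var) {
    warning("zero residual variance at all probes; ",
            "falling back to an ordinary t-test")
    m1 <- rowMeans(beta[, groups == 1, drop = FALSE])
    m0 <- rowMeans(beta[, groups == 0, drop = FALSE])
    n1 <- sum(groups == 1); n0 <- sum(groups == 0)
    s2 <- (apply(beta[, groups == 1, drop = FALSE], 1, stats::var) * (n1 - 1) +
             apply(beta[, groups == 0, drop = FALSE], 1, stats::var) * (n0 - 1)) /
      (n1 + n0 - 2)
    tt <- (m1 - m0) / sqrt(pmax(s2, .Machine$double.eps) * (1 / n1 + 1 / n0))
    return(list(p = 2 * stats::pt(-abs(tt), n1 + n0 - 2), mean_diff = m1 - m0))
  }
  eb <- limma::eBayes(fit)
  list(p = eb$p.value[, "group"], mean_diff = fit$coefficients[, "group"])
}

#' Call differentially methylated probes (DMPs)
#'
#' Per probe, a moderated t-test (empirical-Bayes variance shrinkage across
#' probes) compares the two groups on beta values; p-values are
#' Benjamini-Hochberg adjusted across the tested probes. A probe is a DMP
#' iff its adjusted p is <= 0.05 and the absolute difference of group
#' median beta values is >= 0.3. The effect size follows the group medians
#' while the test statistic follows the group means; both are reported.
#'
#' @param betas A [beta_matrix()] (ideally filtered) or plain matrix.
#' @param group_a,group_b Character vectors of sample ids (>= 2 each).
#' @param p_threshold Adjusted-p cutoff.
#' @param delta_threshold Minimum absolute difference of group medians.
#' @return Data.frame with per-probe `delta_beta` (median a - median b),
#'   `mean_diff`, `p`, `adj_p`, `is_dmp`.
#' @export
call_dmps <- function(betas, group_a, group_b, p_threshold = 0.05,
                      delta_threshold = 0.3) {
  beta <- as_beta(betas)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 samples")
  }
  stopifnot(all(c(group_a, group_b) %in% colnames(beta)))
  sub <- beta[, c(group_a, group_b), drop = FALSE]
  groups <- rep(c(1, 0), c(length(group_a), length(group_b)))
  fit <- moderated_fit(sub, groups)
  med_a <- apply(beta[, group_a, drop = FALSE], 1L, stats::median)
  med_b <- apply(beta[, group_b, drop = FALSE], 1L, stats::median)
  adj_p <- stats::p.adjust(fit$p, method = "BH")
  delta <- med_a - med_b
  data.frame(probe = rownames(beta),
             delta_beta = delta,
             mean_diff = fit$mean_diff,
             p = fit$p, adj_p = adj_p,
             is_dmp = adj_p <= p_threshold & abs(delta) >= delta_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select cancer-specific hypermethylation probes
#'
#' Probes unmethylated in the normal samples (median beta < 0.2) and
#' methylated in the tumor samples (median beta > 0.3); both inequalities
#' strict.
#'
#' @param tumor,normal [beta_matrix()] objects (or matrices) sharing a
#'   probe universe.
#' @param normal_max,tumor_min The two median thresholds.
#' @return Character vector of probe ids.
#' @export
select_cancer_specific_hyper_probes <- function(tumor, normal,
                                                normal_max = 0.2,
                                                tumor_min = 0.3) {
  tm <- as_beta(tumor)
  nm <- as_beta(normal)
  common <- intersect(rownames(tm), rownames(nm))
  med_t <- apply(tm[common, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
  med_n <- apply(nm[common, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
  common[med_n < normal_max & med_t > tumor_min]
}

#' Hierarchical clustering with Euclidean distance and Ward linkage
#'
#' Agglomerative clustering under the Ward minimum-variance criterion on
#' Euclidean distances (`stats::hclust` method `"ward.D2"`, the classical
#' Ward criterion on unsquared distances); the tree is cut at `k` clusters
#' and labels `C1, C2, ...` are assigned by decreasing cluster size. The
#' labels carry no biological meaning by themselves.
#'
#' @param x Samples x features numeric matrix; features containing missing
#'   values are dropped with a warning.
#' @param k Number of clusters (<= number of samples).
#' @return A `cluster_assignment`: list with `assignment` (named character
#'   vector), `hclust`, `k`, `linkage`.
#' @export
hierarchical_cluster <- function(x, k) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of samples")
  bad <- colSums(is.na(x)) > 0L
  if (any(bad)) {
    warning("dropping ", sum(bad), " features with missing values")
    x <- x[, !bad, drop = FALSE]
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(paste0("C", seq_len(k)), names(sizes))
  structure(list(assignment = stats::setNames(relabel[as.character(raw)],
                                              rownames(x)),
                 hclust = hc, k = k,
                 linkage = "ward.D2 on Euclidean distance"),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, "), k = ", x$k, ":\n", sep = "")
  print(table(x$assignment))
  invisible(x)
}

#' Select co-methylation probes for cross-cohort clustering
#'
#' Probes significantly differentially methylated between tumor and normal
#' samples (moderated t, BH-adjusted p <= 0.05) with an absolute difference
#' of group mean beta values >= `delta`, reduced to the `n_top` most
#' variable across tumors by median absolute deviation. If fewer probes
#' qualify, all are returned with a warning.
#'
#' @param tumor,normal [beta_matrix()] objects (or matrices) sharing a
#'   probe universe.
#' @param delta Minimum absolute mean difference.
#' @param n_top Number of probes to keep.
#' @return Character vector of probe ids.
#' @export
select_comethylation_probes <- function(tumor, normal, delta = 0.2,
                                        n_top = 3000) {
  tm <- as_beta(tumor)
  nm <- as_beta(normal)
  common <- intersect(rownames(tm), rownames(nm))
  tm <- tm[common, , drop = FALSE]
  nm <- nm[common, , drop = FALSE]
  fit <- moderated_fit(cbind(tm, nm), rep(c(1, 0), c(ncol(tm), ncol(nm))))
  adj_p <- stats::p.adjust(fit$p, method = "BH")
  qualify <- common[adj_p <= 0.05 & abs(fit$mean_diff) >= delta]
  if (length(qualify) < n_top) {
    warning("only ", length(qualify), " qualifying probes (< ", n_top,
            "); returning all")
    n_top <- length(qualify)
  }
  mads <- apply(tm[qualify, , drop = FALSE], 1L, stats::mad)
  ord <- order(-mads, qualify)
  qualify[ord][seq_len(n_top)]
}

#' Nearest-centroid transcriptional subtype prediction
#'
#' Each sample's log2(x+1) profile, centered by the cohort gene medians, is
#' Pearson-correlated with every subtype centroid over their common genes;
#' the predicted subtype is the centroid with the maximum correlation. The
#' centroid matrix is likewise centered by its own gene medians, placing
#' both vectors on the centered scale that published predictor centroids
#' assume (a no-op for pre-centered centroids).
#' Ties resolve to the earliest centroid column and are flagged; samples
#' with zero variance over the common genes get no label and are flagged.
#'
#' @param expr Genes x samples expression matrix, linear scale.
#' @param centroids Genes x subtypes centroid matrix (log-scale predictor
#'   values); >= 10 genes must be common with `expr`.
#' @return Data.frame with `sample`, `label`, `tie`, `zero_variance` and
#'   one `cor_<subtype>` column per centroid.
#' @export
nearest_centroid_subtype <- function(expr, centroids) {
  centroids <- as.matrix(centroids)
  common <- intersect(rownames(expr), rownames(centroids))
  if (length(common) < 10L) {
    stop("fewer than 10 genes common to the matrix and the centroids (",
         length(common), ")")
  }
  x <- log2(expr[common, , drop = FALSE] + 1)
  x <- x - apply(x, 1L, stats::median)
  cm <- centroids[common, , drop = FALSE]
  cm <- cm - apply(cm, 1L, stats::median)
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::sd(v) < 1e-12) {
      return(list(label = NA_character_, tie = FALSE, zero_variance = TRUE,
                  cors = rep(NA_real_, ncol(cm))))
    }
    cors <- apply(cm, 2L, stats::cor, y = v)
    best <- max(cors)
    hits <- which(cors >= best - 1e-12)
    list(label = colnames(cm)[hits[1L]], tie = length(hits) > 1L,
         zero_variance = FALSE, cors = cors)
  })
  out <- data.frame(sample = colnames(expr),
                    label = vapply(res, `[[`, "", "label"),
                    tie = vapply(res, `[[`, FALSE, "tie"),
                    zero_variance = vapply(res, `[[`, FALSE, "zero_variance"),
                    stringsAsFactors = FALSE)
  cors <- t(vapply(res, `[[`, numeric(ncol(cm)), "cors"))
  colnames(cors) <- paste0("cor_", colnames(cm))
  cbind(out, cors)
}

#' Euclidean similarity of methylation profiles to subtype references
#'
#' Computes the Euclidean distance between each sample's beta vector and
#' each subtype's mean beta profile over the common probes; smaller
#' distances mean greater similarity, and the nearest subtype is reported.
#'
#' @param samples [beta_matrix()] (or matrix) of samples.
#' @param subtype_profiles Probes x subtypes matrix of mean beta values.
#' @return List with `distance` (samples x subtypes matrix) and `nearest`
#'   (named character vector).
#' @export
methylation_subtype_similarity <- function(samples, subtype_profiles) {
  sm <- as_beta(samples)
  sp <- as.matrix(subtype_profiles)
  common <- intersect(rownames(sm), rownames(sp))
  if (!length(common)) stop("no common probes with the subtype profiles")
  sm <- sm[common, , drop = FALSE]
  sp <- sp[common, , drop = FALSE]
  d <- t(vapply(seq_len(ncol(sm)), function(j) {
    sqrt(colSums((sp - sm[, j])^2))
  }, numeric(ncol(sp))))
  dimnames(d) <- list(colnames(sm), colnames(sp))
  list(distance = d,
       nearest = stats::setNames(colnames(sp)[apply(d, 1L, which.min)],
                                 colnames(sm)))
}
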