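# Leukocyte-fraction deconvolution from DNA methylation and ssGSEA-based
# lymphocyte-infiltration scoring.
#
# The leukocyte fraction (LF) model assumes each tumor beta value is a
# two-population mixture, beta_i = beta_iL * pi + beta_iT * (1 - pi), over
# loci chosen to discriminate leukocyte from normal lung methylation. Per
# locus pi is solved directly; the sample's LF is the mode of a Gaussian
# kernel density estimate of the per-locus solutions.

as_beta <- function(x) {
  if (inherits(x, "beta_matrix")) x$beta else as.matrix(x)
}

#' Select leukocyte-discriminating methylation loci
#'
#' Probes are ranked by the difference of group mean beta values
#' (leukocyte - normal lung); the strongest `n_per_direction` positive
#' differences become `leukocyte_high` loci and the strongest negative
#' differences `leukocyte_low` loci (1000 each by default, 2000 loci
#' total). If fewer discriminating probes exist in a direction, the
#' available ones are used with a warning.
#'
#' @param normal_lung,leukocyte [beta_matrix()] objects (or plain matrices)
#'   sharing a probe universe.
#' @param n_per_direction Target loci per direction.
#' @return An `lf_model`: list with `loci`, `direction`, `beta_L` (mean
#'   leukocyte beta per locus) and `beta_T = NULL` until
#'   [estimate_pure_tumor_reference()] is applied.
#' @export
select_lf_loci <- function(normal_lung, leukocyte, n_per_direction = 1000) {
  lung <- as_beta(normal_lung)
  leuk <- as_beta(leukocyte)
  common <- intersect(rownames(lung), rownames(leuk))
  if (!length(common)) stop("no common probes between matrices")
  d <- rowMeans(leuk[common, , drop = FALSE]) -
    rowMeans(lung[common, , drop = FALSE])
  pick <- function(dir) {
    dd <- if (dir == "leukocyte_high") d[d > 0] else -d[d < 0]
    if (!length(dd)) return(character())
    names(sort(dd, decreasing = TRUE))[seq_len(min(n_per_direction, length(dd)))]
  }
  hi <- pick("leukocyte_high")
  lo <- pick("leukocyte_low")
  if (!length(hi) && !length(lo)) {
    stop("no discriminating loci between leukocyte and normal lung")
  }
  if (length(hi) < n_per_direction || length(lo) < n_per_direction) {
    warning("fewer than ", n_per_direction,
            " discriminating loci in at least one direction; using ",
            length(hi), " high / ", length(lo), " low")
  }
  loci <- c(hi, lo)
  structure(list(loci = loci,
                 direction = stats::setNames(
                   rep(c("leukocyte_high", "leukocyte_low"),
                       c(length(hi), length(lo))), loci),
                 beta_L = rowMeans(leuk[loci, , drop = FALSE]),
                 beta_T = NULL),
            class = "lf_model")
}

#' Estimate the pure-tumor reference profile
#'
#' The tumor with the least evidence of leukocyte methylation serves as the
#' pure-tumor surrogate, operationalized per locus: at `leukocyte_high`
#' loci the minimum beta over tumors, at `leukocyte_low` loci the maximum
#' (the extreme in the anti-leukocyte direction). Loci missing in all
#' tumors are dropped from the model. A whole-sample alternative (single
#' tumor most distant from the leukocyte profile) is available via
#' `per_locus = FALSE`.
#'
#' @param tumors [beta_matrix()] (or matrix) of tumor samples.
#' @param model An `lf_model` from [select_lf_loci()].
#' @param per_locus Use the per-locus extremum (default) or one whole
#'   sample.
#' @return The `lf_model` with `beta_T` filled in.
#' @export
estimate_pure_tumor_reference <- function(tumors, model, per_locus = TRUE) {
  stopifnot(inherits(model, "lf_model"))
  tm <- as_beta(tumors)
  loci <- intersect(model$loci, rownames(tm))
  if (!length(loci)) stop("tumor matrix shares no loci with the model")
  tm <- tm[loci, , drop = FALSE]
  keep <- rowSums(!is.na(tm)) > 0L
  loci <- loci[keep]
  tm <- tm[keep, , drop = FALSE]
  hi <- model$direction[loci] == "leukocyte_high"
  if (per_locus) {
    bt <- numeric(length(loci))
    bt[hi] <- apply(tm[hi, , drop = FALSE], 1L, min, na.rm = TRUE)
    bt[!hi] <- apply(tm[!hi, , drop = FALSE], 1L, max, na.rm = TRUE)
  } else {
    # whole-sample surrogate: tumor farthest from the leukocyte profile
    dist_to_leuk <- colMeans(abs(tm - model$beta_L[loci]), na.rm = TRUE)
    bt <- tm[, which.max(dist_to_leuk)]
  }
  model$loci <- loci
  model$direction <- model$direction[loci]
  model$beta_L <- model$beta_L[loci]
  model$beta_T <- stats::setNames(bt, loci)
  model
}

#' Estimate the leukocyte fraction of one sample
#'
#' Per locus, `pi = (beta_i - beta_iT) / (beta_iL - beta_iT)` clipped to
#' `[0, 1]`; loci whose reference spread `|beta_iL - beta_iT|` is below
#' `spread_threshold` are excluded (the division would be unstable). The
#' sample's LF is the mode of a Gaussian kernel density estimate
#' (Silverman's rule bandwidth) of the per-locus pi values, taken as the
#' argmax over the grid `0, 0.001, ..., 1`; ties resolve to the smallest
#' pi.
#'
#' @param sample_beta Named beta vector (names = probe ids) or one-column
#'   matrix.
#' @param model A fitted `lf_model` (with `beta_T`).
#' @param spread_threshold Minimum reference spread per locus.
#' @param min_loci Minimum usable loci (error below this).
#' @return An `lf_estimate`: list with `lf`, `per_locus_pi`, `n_loci_used`.
#' @export
estimate_leukocyte_fraction <- function(sample_beta, model,
                                        spread_threshold = 0.05,
                                        min_loci = 50) {
  stopifnot(inherits(model, "lf_model"))
  if (is.null(model$beta_T)) {
    stop("model lacks beta_T; run estimate_pure_tumor_reference() first")
  }
  if (is.matrix(sample_beta)) {
    sample_beta <- stats::setNames(sample_beta[, 1L], rownames(sample_beta))
  }
  loci <- intersect(model$loci, names(sample_beta))
  spread <- model$beta_L[loci] - model$beta_T[loci]
  usable <- loci[!is.na(sample_beta[loci]) & abs(spread) >= spread_threshold]
  if (length(usable) < min_loci) {
    stop("only ", length(usable), " usable loci (< ", min_loci, ")")
  }
  pi_hat <- clip01((sample_beta[usable] - model$beta_T[usable]) /
                     (model$beta_L[usable] - model$beta_T[usable]))
  h <- stats::bw.nrd0(pi_hat)
  grid <- seq(0, 1, by = 0.001)
  if (h <= 0 || !is.finite(h)) {
    lf <- grid[which.min(abs(grid - stats::median(pi_hat)))]
  } else {
    dens <- rowSums(stats::dnorm(outer(grid, pi_hat, "-") / h)) /
      (length(pi_hat) * h)
    lf <- grid[which.max(dens)]  # which.max returns the first (smallest) mode
  }
  structure(list(lf = lf, per_locus_pi = pi_hat,
                 n_loci_used = length(usable)),
            class = "lf_estimate")
}

#' @export
print.lf_estimate <- function(x, ...) {
  cat(sprintf("Leukocyte fraction %.3f (from %d loci)\n", x$lf,
              x$n_loci_used))
  invisible(x)
}

#' Single-sample gene set enrichment score (ssGSEA)
#'
#' Genes are ranked by expression (descending; tied expression receives
#' average ranks, and tied order is broken by gene name so the score is
#' independent of input gene order). Walking down the ranking, the score
#' accumulates the difference between the weighted in-set empirical CDF
#' (weights `rank^alpha`) and the unweighted out-of-set CDF; a gene set
#' concentrated at the top of the ranking scores high. Being rank-based,
#' the score is invariant under strictly increasing transforms of the
#' expression values. No cross-sample normalization is applied.
#'
#' @param expr Named numeric vector of one sample's expression values.
#' @param gene_set Character vector of gene symbols (>= 1 present in
#'   `expr`).
#' @param alpha Rank-weighting exponent (the method's conventional 0.75).
#' @return A single enrichment score.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.75) {
  if (is.null(names(expr))) stop("expr must be a named vector")
  if (any(!is.finite(expr))) stop("expression values must be finite")
  in_set_genes <- intersect(names(expr), gene_set)
  if (!length(in_set_genes)) stop("gene set shares no genes with expr")
  n <- length(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(-expr, names(expr))
  in_set <- names(expr)[ord] %in% in_set_genes
  w <- (r[ord]^alpha) * in_set
  p_in <- cumsum(w) / sum(w)
  n_out <- n - length(in_set_genes)
  p_out <- if (n_out > 0L) cumsum(!in_set) / n_out else rep(0, n)
  sum(p_in - p_out)
}

#' Lymphocyte-infiltration expression scores for a cohort
#'
#' Applies [ssgsea_score()] with the predefined infiltration signature
#' (e.g. an 18-gene overall lymphocyte infiltration set) to every sample
#' column.
#'
#' @param expr Genes x samples expression matrix (linear scale).
#' @param signature Character vector of signature genes, or a data.frame
#'   with a `gene` column.
#' @param alpha Rank-weighting exponent.
#' @return Data.frame with columns `sample` and `LIexpression`.
#' @export
liexpression_scores <- function(expr, signature, alpha = 0.75) {
  genes <- if (is.data.frame(signature)) signature$gene else signature
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ssgsea_score(stats::setNames(expr[, j], rownames(expr)), genes, alpha)
  }, 0)
  data.frame(sample = colnames(expr), LIexpression = scores,
             stringsAsFactors = FALSE)
}
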