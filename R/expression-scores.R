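# Expression-based scoring: EMT score as signature PC1, Cyber-T style
# Bayesian-regularized differential expression, and MAD-based variable
# gene selection. All computations operate on log2(x + 1) values; fold
# changes are reported on the linear scale.

#' EMT score from the first principal component of a signature
#'
#' Restricts the expression matrix to the EMT signature genes, log2(x+1)
#' transforms, centers each gene, and takes the first principal component
#' across samples as the per-sample EMT score. The sign is oriented so that
#' a mesenchymal anchor gene (default `VIM`; the mean mesenchymal loading
#' if the anchor is absent) has nonnegative loading, making higher scores
#' more mesenchymal.
#'
#' @param expr Genes x samples expression matrix, linear scale, >= 3
#'   samples.
#' @param signature Data.frame with columns `gene` and `label`
#'   (`epithelial`/`mesenchymal`); >= 50% of its genes must be present.
#' @param anchor Mesenchymal orientation anchor gene.
#' @return An `emt_score_result`: list with `scores` (centered, one per
#'   sample), `loadings`, `explained_variance_pc1`, `orientation_anchor`.
#' @export
emt_score <- function(expr, signature, anchor = "VIM") {
  stopifnot(is.data.frame(signature), all(c("gene", "label") %in%
                                            names(signature)))
  if (ncol(expr) < 3L) stop("EMT scoring needs >= 3 samples")
  present <- intersect(signature$gene, rownames(expr))
  if (length(present) < 0.5 * nrow(signature)) {
    stop("fewer than 50% of signature genes present in the matrix (",
         length(present), "/", nrow(signature), ")")
  }
  x <- log2(expr[present, , drop = FALSE] + 1)
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12)) stop("constant expression matrix; PC1 undefined")
  pca <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  scores <- pca$x[, 1L]
  loadings <- pca$rotation[, 1L]
  orient_val <- if (anchor %in% present) {
    loadings[anchor]
  } else {
    mes <- intersect(signature$gene[signature$label == "mesenchymal"], present)
    mean(loadings[mes])
  }
  if (is.na(orient_val)) orient_val <- 1
  if (orient_val < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pc1 = pca$sdev[1L]^2 / sum(pca$sdev^2),
                 orientation_anchor = anchor),
            class = "emt_score_result")
}

#' @export
print.emt_score_result <- function(x, ...) {
  cat(sprintf("EMT scores for %d samples; PC1 explains %.1f%% of variance\n",
              length(x$scores), 100 * x$explained_variance_pc1))
  invisible(x)
}

running_window_mean <- function(x, window) {
  # mean of the `window` values nearest each position in an ordered vector
  n <- length(x)
  w <- min(window, n)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, pmin(seq_len(n) - half, n - w + 1L))
  (cs[lo + w] - cs[lo]) / w
}

#' Differential expression with Bayesian-regularized variance (Cyber-T)
#'
#' Per gene and group, the variance on log2(x+1) values is shrunk toward a
#' local background `s0^2` (the mean variance of the `window` genes nearest
#' in average log expression within the group):
#' `s~^2 = (prior_df * s0^2 + (n - 1) * s^2) / (prior_df + n - 2)`. The
#' test statistic is a Welch t on the regularized variances, with
#' per-group degrees of freedom augmented to `prior_df + n - 2` and
#' combined by Welch-Satterthwaite; p-values are two-sided. A gene is
#' called differentially expressed iff its linear-scale fold change is >= 2
#' in magnitude (ratio >= 2 or <= 0.5) and p < 0.05.
#'
#' @param group_a,group_b Genes x samples matrices (same genes, >= 2
#'   samples each), linear scale.
#' @param prior_df Prior degrees of freedom of the background variance.
#' @param window Number of genes in the local background window (clamped
#'   with a warning if larger than the gene count).
#' @param fc_threshold Fold-change call threshold.
#' @param p_threshold P-value call threshold.
#' @return Data.frame with per-gene `fold_change` (ratio of linear group
#'   means a/b), `log2_diff`, `t`, `df`, `p`, `called`.
#' @export
cybert_deg <- function(group_a, group_b, prior_df = 10, window = 101,
                       fc_threshold = 2, p_threshold = 0.05) {
  if (ncol(group_a) < 2L || ncol(group_b) < 2L) {
    stop("each group needs >= 2 samples")
  }
  if (!identical(rownames(group_a), rownames(group_b))) {
    stop("groups must share the same genes in the same order")
  }
  n_genes <- nrow(group_a)
  if (window > n_genes) {
    warning("window (", window, ") larger than gene count (", n_genes,
            "); clamped")
    window <- n_genes
  }
  la <- log2(group_a + 1)
  lb <- log2(group_b + 1)
  reg_var <- function(lx) {
    n <- ncol(lx)
    m <- rowMeans(lx)
    s2 <- apply(lx, 1L, stats::var)
    ord <- order(m)
    s0 <- numeric(n_genes)
    s0[ord] <- running_window_mean(s2[ord], window)
    list(m = m, n = n,
         v = (prior_df * s0 + (n - 1) * s2) / (prior_df + n - 2),
         df = prior_df + n - 2)
  }
  a <- reg_var(la)
  b <- reg_var(lb)
  se2 <- a$v / a$n + b$v / b$n
  t_stat <- (a$m - b$m) / sqrt(se2)
  df <- se2^2 / ((a$v / a$n)^2 / a$df + (b$v / b$n)^2 / b$df)
  p <- 2 * stats::pt(-abs(t_stat), df)
  fc <- rowMeans(group_a) / rowMeans(group_b)
  data.frame(gene = rownames(group_a),
             fold_change = fc,
             log2_diff = a$m - b$m,
             t = t_stat, df = df, p = p,
             called = (fc >= fc_threshold | fc <= 1 / fc_threshold) &
               p < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Most variably expressed genes by median absolute deviation
#'
#' Genes are ranked by the MAD of their log2(x+1) values across samples;
#' the top `n` are returned. Ties are broken by gene id in lexicographic
#' order, so the selection is deterministic.
#'
#' @param expr Genes x samples expression matrix, linear scale.
#' @param n Number of genes to return (<= gene count).
#' @return Character vector of gene ids.
#' @export
top_variable_genes <- function(expr, n = 2000) {
  if (n > nrow(expr)) stop("n exceeds the gene count")
  m <- apply(log2(expr + 1), 1L, stats::mad)
  ord <- order(-m, rownames(expr))
  rownames(expr)[ord][seq_len(n)]
}
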