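# Core data containers: mutation catalogs, reference cohorts, beta-value
# matrices and copy-number segment sets. All are lightweight S3 wrappers
# around data.frames/matrices so they print and subset naturally.

#' Construct a mutation catalog
#'
#' A mutation catalog is the per-sample set of somatic mutations underlying
#' clonality and mutation-burden analysis. Mutation identity is the key
#' `(chrom, pos, ref, alt)`; the gene symbol and effect class are
#' annotations, not part of the identity.
#'
#' @param x A data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gene`, and `effect` (one of `"nonsynonymous"`, `"synonymous"`,
#'   `"other"`).
#' @param sample_id Sample identifier; defaults to the `sample` column if
#'   present.
#' @return A `mutation_catalog`, a data.frame with attribute `sample_id`.
#' @export
mutation_catalog <- function(x, sample_id = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "gene", "effect")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("mutation catalog is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(sample_id)) {
    sample_id <- if ("sample" %in% names(x) && nrow(x)) x$sample[1] else "sample"
  }
  if (nrow(x)) {
    if (any(x$pos < 1)) stop("mutation positions must be >= 1")
    if (any(x$ref == x$alt)) stop("ref and alt alleles must differ")
    keys <- mutation_keys(x)
    if (anyDuplicated(keys)) {
      stop("duplicate mutation keys (chrom,pos,ref,alt) within catalog '",
           sample_id, "'")
    }
  }
  x$sample <- rep(sample_id, length.out = nrow(x))
  structure(x[, c("sample", needed)],
            sample_id = sample_id,
            class = c("mutation_catalog", "data.frame"))
}

mutation_keys <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Construct a reference cohort of unrelated mutation catalogs
#'
#' The cohort supplies background mutation probabilities for the clonality
#' index and the raw material for positive/negative control pairs during
#' cutoff calibration.
#'
#' @param catalogs A list of [mutation_catalog()] objects with unique
#'   sample ids (at least two).
#' @return A `reference_cohort`: list with elements `catalogs` and `N`.
#' @export
reference_cohort <- function(catalogs) {
  stopifnot(is.list(catalogs))
  if (length(catalogs) < 2L) stop("a reference cohort needs >= 2 catalogs")
  catalogs <- lapply(catalogs, function(cc) {
    if (!inherits(cc, "mutation_catalog")) mutation_catalog(cc) else cc
  })
  ids <- vapply(catalogs, attr, "", which = "sample_id")
  if (anyDuplicated(ids)) stop("cohort sample ids must be unique")
  names(catalogs) <- ids
  structure(list(catalogs = catalogs, N = length(catalogs)),
            class = "reference_cohort")
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat("Reference cohort of", x$N, "mutation catalogs;",
      sum(vapply(x$catalogs, nrow, 0L)), "mutations total\n")
  invisible(x)
}

#' Construct a beta-value matrix with probe annotation
#'
#' Container for DNA methylation beta values (probes x samples, values in
#' `[0, 1]`) plus the per-probe annotation required by the six probe
#' filters: chromosome, CpG flag, SNP flag, multi-mapping flag, and
#' per-sample detection p-values and beadcounts.
#'
#' @param beta Numeric matrix, probes x samples, rownames = probe ids.
#' @param annotation Optional data.frame with columns `probe`, `chrom`,
#'   `is_cg`, `has_snp`, `multimap` (one row per probe).
#' @param detection_p,beadcount Optional probes x samples matrices aligned
#'   with `beta`.
#' @return A `beta_matrix` object.
#' @export
beta_matrix <- function(beta, annotation = NULL, detection_p = NULL,
                        beadcount = NULL) {
  beta <- as.matrix(beta)
  if (nrow(beta) > 0L) {
    if (is.null(rownames(beta))) stop("beta matrix needs probe rownames")
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  }
  if (is.null(colnames(beta))) {
    colnames(beta) <- paste0("S", seq_len(ncol(beta)))
  }
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
    if (!"probe" %in% names(annotation)) stop("annotation needs a 'probe' column")
    if (!setequal(annotation$probe, rownames(beta))) {
      stop("annotation probes must match beta rownames")
    }
    annotation <- annotation[match(rownames(beta), annotation$probe), ,
                             drop = FALSE]
    rownames(annotation) <- NULL
  }
  for (m in list(detection_p = detection_p, beadcount = beadcount)) {
    if (!is.null(m) && !identical(dim(as.matrix(m)), dim(beta))) {
      stop("detection_p/beadcount must have the same dimensions as beta")
    }
  }
  structure(list(beta = beta, annotation = annotation,
                 detection_p = detection_p, beadcount = beadcount),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("Beta matrix:", nrow(x$beta), "probes x", ncol(x$beta), "samples",
      if (!is.null(x$annotation)) "(annotated)" else "", "\n")
  invisible(x)
}

#' Construct a copy-number segment set
#'
#' Segments use BED-style 0-based half-open coordinates. Overlapping or
#' adjacent same-state segments on a chromosome are merged on construction,
#' so the stored representation is canonical.
#'
#' @param x Data.frame with columns `chrom`, `start`, `end`, `state`
#'   (`"gain"` or `"loss"`).
#' @param sample_id Sample identifier.
#' @return A `segment_set` data.frame with attribute `sample_id`.
#' @export
segment_set <- function(x, sample_id = "sample") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "state")
  if (!all(needed %in% names(x))) {
    stop("segment set needs columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(x$start >= x$end)) stop("segments must satisfy start < end")
    if (!all(x$state %in% c("gain", "loss"))) {
      stop("segment state must be 'gain' or 'loss'")
    }
    merged <- list()
    for (ch in unique(x$chrom)) {
      for (st in unique(x$state[x$chrom == ch])) {
        sel <- x$chrom == ch & x$state == st
        ir <- IRanges::reduce(IRanges::IRanges(start = x$start[sel] + 1L,
                                               end = x$end[sel]))
        merged[[paste(ch, st)]] <- data.frame(
          chrom = ch, start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir), state = st,
          stringsAsFactors = FALSE)
      }
    }
    x <- do.call(rbind, merged)
    x <- x[order(x$chrom, x$start, x$state), , drop = FALSE]
    rownames(x) <- NULL
  }
  structure(x[, needed, drop = FALSE], sample_id = sample_id,
            class = c("segment_set", "data.frame"))
}
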