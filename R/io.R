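# Plain-text I/O for the package's standard exchange formats. All tables
# are tab-separated, UTF-8, '.' decimal, NA for missing. Point mutations
# use 1-based positions (MAF/VCF convention); segments use 0-based
# half-open coordinates (BED convention).

#' Write / read a MAF-like mutation table
#'
#' Multi-sample tables carry a `sample` column; [read_mutation_tsv()]
#' returns one [mutation_catalog()] per sample.
#'
#' @param x A `mutation_catalog`, a list of them, or a `reference_cohort`.
#' @param path Output file path.
#' @return `write_mutation_tsv()` returns `path` invisibly;
#'   `read_mutation_tsv()` returns a named list of catalogs.
#' @export
write_mutation_tsv <- function(x, path) {
  if (inherits(x, "reference_cohort")) x <- x$catalogs
  if (inherits(x, "mutation_catalog")) x <- list(x)
  tab <- data.table::rbindlist(lapply(x, as.data.frame))
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_mutation_tsv
#' @export
read_mutation_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"sample" %in% names(tab)) tab$sample <- "sample"
  out <- lapply(split(tab, tab$sample), mutation_catalog)
  out[unique(tab$sample)]
}

#' Write / read a beta-value matrix with optional probe annotation
#'
#' The matrix file has a `probe` id column followed by one column per
#' sample; the annotation file carries the probe filter fields plus, when
#' available, wide `detp_<sample>` and `bead_<sample>` columns.
#'
#' @param x A [beta_matrix()].
#' @param path Matrix file path.
#' @param annotation_path Optional annotation file path.
#' @return `write_beta_tsv()` returns `path` invisibly; `read_beta_tsv()`
#'   a `beta_matrix`.
#' @export
write_beta_tsv <- function(x, path, annotation_path = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  tab <- data.frame(probe = rownames(x$beta), x$beta, check.names = FALSE)
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(annotation_path) && !is.null(x$annotation)) {
    ann <- x$annotation
    if (!is.null(x$detection_p)) {
      dp <- as.data.frame(x$detection_p)
      names(dp) <- paste0("detp_", colnames(x$beta))
      ann <- cbind(ann, dp)
    }
    if (!is.null(x$beadcount)) {
      bc <- as.data.frame(x$beadcount)
      names(bc) <- paste0("bead_", colnames(x$beta))
      ann <- cbind(ann, bc)
    }
    data.table::fwrite(ann, annotation_path, sep = "\t", na = "NA",
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path, annotation_path = NULL) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  beta <- as.matrix(tab[, -1, drop = FALSE])
  rownames(beta) <- tab$probe
  ann <- det <- bead <- NULL
  if (!is.null(annotation_path)) {
    ann <- as.data.frame(data.table::fread(annotation_path, sep = "\t"))
    dcols <- grep("^detp_", names(ann), value = TRUE)
    bcols <- grep("^bead_", names(ann), value = TRUE)
    ord <- match(rownames(beta), ann$probe)
    if (length(dcols)) {
      det <- as.matrix(ann[ord, dcols, drop = FALSE])
      dimnames(det) <- dimnames(beta)
    }
    if (length(bcols)) {
      bead <- as.matrix(ann[ord, bcols, drop = FALSE])
      dimnames(bead) <- dimnames(beta)
    }
    ann <- ann[, setdiff(names(ann), c(dcols, bcols)), drop = FALSE]
  }
  beta_matrix(beta, annotation = ann, detection_p = det, beadcount = bead)
}

#' Write / read a genes-by-samples expression matrix
#'
#' @param x Numeric matrix (genes x samples) with gene rownames; values are
#'   nonnegative linear-scale abundances.
#' @param path File path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_expression_tsv <- function(x, path) {
  tab <- data.frame(gene = rownames(x), x, check.names = FALSE)
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  m
}

#' Write / read a BED-like copy-number segment table
#'
#' Columns: `chrom`, `start`, `end`, `state` (0-based half-open), plus a
#' `sample` column when writing multiple sets.
#'
#' @param x A [segment_set()] or list of them.
#' @param path File path.
#' @export
write_segments_tsv <- function(x, path) {
  if (inherits(x, "segment_set")) x <- list(x)
  tab <- data.table::rbindlist(lapply(x, function(s) {
    cbind(sample = attr(s, "sample_id"), as.data.frame(s))
  }))
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"sample" %in% names(tab)) tab$sample <- "sample"
  out <- lapply(split(tab, tab$sample), function(s) {
    segment_set(s[, c("chrom", "start", "end", "state")], s$sample[1])
  })
  out[unique(tab$sample)]
}

#' Read a gene signature file
#'
#' Accepts either one symbol per line or a two-column TSV `gene<TAB>label`
#' (labels `epithelial`/`mesenchymal` for the EMT signature).
#'
#' @param path File path.
#' @return Data.frame with columns `gene` and `label` (label `NA` for
#'   unlabeled sets).
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[`, "", 1L),
    label = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Write a ground-truth sidecar file
#'
#' Planted parameters from the synthetic-data generators are written as a
#' JSON sidecar, never embedded in the data files, so downstream stages
#' cannot read them by accident.
#'
#' @param truth Named list of planted parameters.
#' @param path Output path (JSON).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
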