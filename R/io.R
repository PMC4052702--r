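#' Read a probes x samples log2 expression matrix from TSV
#'
#' The expected dialect is tab-separated UTF-8 text with a header row of
#' sample identifiers (the first header cell may be empty or any label such
#' as `probe_id`) and one row per probe, first column the probe identifier.
#' Values are log2-scale, already normalized intensities; normalization
#' itself (e.g. RMA on probe-level CEL data) is outside this package's scope.
#'
#' @param path path to a TSV file
#' @param impute if `TRUE`, missing values are replaced by the per-probe
#'   mean (with a message); if `FALSE` (default) any non-finite value is an
#'   error with its row/column coordinates.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a single
#'   assay `"exprs"`, probe identifiers as rownames and sample identifiers
#'   as colnames, in file order.
#' @export
readExpressionMatrix <- function(path, impute = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "",
                   na.strings = c("NA", "NaN", ""))
  if (ncol(df) < 2L) stop("expression file must have a probe-id column and at least one sample column")
  probes <- df[[1L]]
  samples <- colnames(df)[-1L]
  dupP <- unique(probes[duplicated(probes)])
  if (length(dupP)) stop("duplicate probe id(s): ", paste(dupP, collapse = ", "))
  dupS <- unique(samples[duplicated(samples)])
  if (length(dupS)) stop("duplicate sample id(s): ", paste(dupS, collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], probes[bad[1, 1]], samples[bad[1, 2]]))
  }
  dimnames(num) <- list(probes, samples)
  if (any(!is.finite(num))) {
    if (!impute) {
      miss <- which(!is.finite(num), arr.ind = TRUE)
      stop(sprintf("missing/non-finite value at probe '%s', sample '%s' (use impute = TRUE for per-probe mean imputation)",
                   probes[miss[1, 1]], samples[miss[1, 2]]))
    }
    nImp <- sum(!is.finite(num))
    for (i in which(rowSums(!is.finite(num)) > 0L)) {
      row <- num[i, ]
      if (!any(is.finite(row))) stop("probe '", probes[i], "' has no finite values; cannot impute")
      row[!is.finite(row)] <- mean(row[is.finite(row)])
      num[i, ] <- row
    }
    message("imputed ", nImp, " missing value(s) by per-probe mean")
  }
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = num))
}

#' Write an expression matrix to TSV
#'
#' Writes the canonical dialect read by [readExpressionMatrix()]: tab
#' separators, `.` decimal mark, header `probe_id` then sample ids.
#'
#' @param se a SummarizedExperiment (assay `"exprs"`) or numeric matrix with
#'   dimnames
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- if (is(se, "SummarizedExperiment")) SummarizedExperiment::assay(se, "exprs") else se
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read two-class sample labels from TSV
#'
#' The file has two columns, sample id and group string, with exactly two
#' distinct group strings. The mapping of group string to the 0/1 disease
#' coding is explicit (`positiveClass` names the class coded 1, e.g. the
#' patients) and never inferred alphabetically.
#'
#' @param path path to a two-column TSV with header
#' @param positiveClass the group string coded as 1 (patients)
#' @return a data.frame with columns `sample_id`, `group`, `status` (integer
#'   0/1)
#' @export
readSampleLabels <- function(path, positiveClass) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("labels file must have sample-id and group columns")
  out <- data.frame(sample_id = df[[1L]], group = df[[2L]], stringsAsFactors = FALSE)
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup)) stop("duplicate sample id(s) in labels: ", paste(dup, collapse = ", "))
  grp <- unique(out$group)
  if (length(grp) != 2L)
    stop("labels must contain exactly two classes; found: ", paste(grp, collapse = ", "))
  if (!positiveClass %in% grp)
    stop("positiveClass '", positiveClass, "' not among group labels: ", paste(grp, collapse = ", "))
  out$status <- as.integer(out$group == positiveClass)
  if (sum(out$status) < 2L || sum(1L - out$status) < 2L)
    stop("each class needs at least 2 samples")
  out
}

#' Align an expression matrix with sample labels
#'
#' Matches labels to matrix columns by sample id (order-independent). Matrix
#' samples without a label are dropped with a warning; label sample ids not
#' present in the matrix are an error, as is an empty intersection.
#'
#' @param se SummarizedExperiment from [readExpressionMatrix()]
#' @param labels data.frame from [readSampleLabels()]
#' @return the SummarizedExperiment restricted/reordered to labeled samples,
#'   with `group` and `status` in its `colData`
#' @export
alignSamples <- function(se, labels) {
  m <- colnames(se)
  common <- intersect(labels$sample_id, m)
  if (length(common) == 0L) stop("no overlap between label and matrix sample ids")
  missingLab <- setdiff(labels$sample_id, m)
  if (length(missingLab))
    stop("label sample id(s) absent from matrix: ", paste(missingLab, collapse = ", "))
  dropped <- setdiff(m, labels$sample_id)
  if (length(dropped))
    warning("dropping ", length(dropped), " unlabeled matrix sample(s): ",
            paste(dropped, collapse = ", "))
  ord <- labels$sample_id
  out <- se[, ord]
  cd <- labels[match(ord, labels$sample_id), ]
  SummarizedExperiment::colData(out)$group <- cd$group
  SummarizedExperiment::colData(out)$status <- cd$status
  if (sum(cd$status) < 2L || sum(1L - cd$status) < 2L)
    stop("each class needs at least 2 samples after alignment")
  out
}

#' Read a gene-to-term annotation table
#'
#' Flat (gene, term) pairs with term metadata; no ontology-graph semantics
#' (no ancestor propagation) are applied — annotations are used as given.
#'
#' @param path TSV with header and columns gene_id, term_id, term_name,
#'   term_class
#' @return data.frame with those four columns, duplicate (gene, term) pairs
#'   collapsed
#' @export
readAnnotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character", quote = "")
  need <- c("gene_id", "term_id", "term_name", "term_class")
  if (!all(need %in% colnames(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df <- df[!duplicated(df[, c("gene_id", "term_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an undirected interaction edge list
#'
#' Interaction extracts in the wild are directional and duplicated; each
#' pair is canonicalized (sorted endpoints) before removing duplicates and
#' self-loops.
#'
#' @param path two-column TSV with header (gene_a, gene_b)
#' @return data.frame with columns `gene_a`, `gene_b`; canonical order,
#'   no self-loops, no duplicates
#' @export
readEdgeList <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("edge file must have two columns")
  cleanEdgeList(data.frame(gene_a = df[[1L]], gene_b = df[[2L]], stringsAsFactors = FALSE))
}

# canonicalize an edge data.frame: sorted endpoints, drop loops + duplicates
cleanEdgeList <- function(edges) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b
  df <- unique(data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}
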