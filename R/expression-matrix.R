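#' Gene-by-sample expression matrix with a declared unit
#'
#' A light container for a numeric gene-by-sample matrix that carries the
#' normalization unit it is expressed in (`counts`, `RPKM`, `TPM` or
#' `logTPM`), optional per-gene lengths (required to compute RPKM) and
#' optional per-sample metadata (cell type, lot, passage). Unit transitions
#' happen only through [compute_rpkm()], [rpkm_to_tpm()] and
#' [log_transform()], so downstream code can refuse inputs on the wrong
#' scale instead of silently correlating counts.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene identifiers),
#'   samples as columns (colnames = sample identifiers).
#' @param unit One of `"counts"`, `"RPKM"`, `"TPM"`, `"logTPM"`.
#' @param gene_lengths Optional named numeric vector of gene lengths in
#'   bases; names must cover the matrix rownames when present.
#' @param metadata Optional `data.frame` of per-sample annotations with a
#'   `sample_id` column (or rownames) matching the matrix columns. Typical
#'   columns: `cell_type`, `role`, `lot`, `passage`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `unit`, `gene_lengths`, `metadata`.
#' @examples
#' m <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- expression_matrix(m, "counts", gene_lengths = setNames(rep(1000, 4), rownames(m)))
#' em
#' @export
expression_matrix <- function(values,
                              unit = c("counts", "RPKM", "TPM", "logTPM"),
                              gene_lengths = NULL,
                              metadata = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in matrix rows", call. = FALSE)
  if (unit != "logTPM" && any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed in a ", unit, " matrix", call. = FALSE)
  if (unit == "TPM") {
    cs <- colSums(values)
    bad <- abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad))
      stop("TPM columns must sum to 1e6 (off: ",
           paste(colnames(values)[bad], collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)))
      stop("'gene_lengths' must be a named vector", call. = FALSE)
    missing_len <- setdiff(rownames(values), names(gene_lengths))
    if (length(missing_len))
      stop("gene lengths missing for: ",
           paste(utils::head(missing_len, 5), collapse = ", "), call. = FALSE)
    gene_lengths <- gene_lengths[rownames(values)]
    if (any(gene_lengths <= 0))
      stop("gene lengths must be positive", call. = FALSE)
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) {
      if (is.null(rownames(metadata)))
        stop("'metadata' needs a sample_id column or rownames", call. = FALSE)
      metadata$sample_id <- rownames(metadata)
    }
    absent <- setdiff(colnames(values), metadata$sample_id)
    if (length(absent))
      stop("metadata missing for samples: ", paste(absent, collapse = ", "),
           call. = FALSE)
    metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(
    list(values = values, unit = unit, gene_lengths = gene_lengths,
         metadata = metadata),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (!is.null(x$gene_lengths)) cat("  gene lengths: present\n")
  if (!is.null(x$metadata))
    cat("  metadata:", paste(setdiff(names(x$metadata), "sample_id"),
                             collapse = ", "), "\n")
  iv <- attr(x, "impute_value")
  if (!is.null(iv)) cat(sprintf("  imputed zeros at TPM %.4g before log\n", iv))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression table from TSV
#'
#' Expects genes as rows with the identifier in the first column and one
#' column per sample. `#`-prefixed lines are treated as comments.
#'
#' @param path Path to a tab-separated table.
#' @param unit Unit the stored values are in (see [expression_matrix()]).
#' @param gene_lengths,metadata Passed on to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, unit = "counts", gene_lengths = NULL,
                            metadata = NULL) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expression table needs an id column plus at least one sample",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  expression_matrix(m, unit, gene_lengths = gene_lengths, metadata = metadata)
}

#' Write an expression matrix to TSV
#'
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @param id_column Name for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, id_column = "gene_id") {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(rownames(em$values), em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene lengths from a two-column TSV
#'
#' @param path Path to a tab-separated table: gene identifier, length in bases.
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("gene-length table needs two columns", call. = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
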