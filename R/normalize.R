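#' Convert raw counts to RPKM
#'
#' Reads per kilobase per million mapped reads:
#' `RPKM_gs = counts_gs / (length_g / 1e3) / (libsize_s / 1e6)`.
#'
#' @param counts An `expression_matrix` in `counts` unit.
#' @param gene_lengths Optional named length vector; defaults to the lengths
#'   stored in `counts`.
#' @return An `expression_matrix` in `RPKM` unit.
#' @export
compute_rpkm <- function(counts, gene_lengths = NULL) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "counts")
    stop("compute_rpkm expects a counts matrix, got ", counts$unit,
         call. = FALSE)
  if (is.null(gene_lengths)) gene_lengths <- counts$gene_lengths
  if (is.null(gene_lengths))
    stop("gene lengths are required to compute RPKM", call. = FALSE)
  missing_len <- setdiff(rownames(counts$values), names(gene_lengths))
  if (length(missing_len))
    stop("no length for gene(s): ",
         paste(utils::head(missing_len, 5), collapse = ", "), call. = FALSE)
  len <- gene_lengths[rownames(counts$values)]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  lib <- colSums(counts$values)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts$values)[lib == 0], collapse = ", "),
         call. = FALSE)
  v <- counts$values / (len / 1e3)
  v <- sweep(v, 2, lib / 1e6, "/")
  expression_matrix(v, "RPKM", gene_lengths = gene_lengths,
                    metadata = counts$metadata)
}

#' Convert RPKM to TPM
#'
#' Transcripts per million are the RPKM values rescaled so every sample
#' sums to one million: `TPM_gs = RPKM_gs / sum_g(RPKM_gs) * 1e6`. This
#' removes the residual library-composition dependence of RPKM and makes
#' samples directly comparable.
#'
#' @param rpkm An `expression_matrix` in `RPKM` unit.
#' @return An `expression_matrix` in `TPM` unit (columns sum to 1e6).
#' @export
rpkm_to_tpm <- function(rpkm) {
  stopifnot(inherits(rpkm, "expression_matrix"))
  if (rpkm$unit != "RPKM")
    stop("rpkm_to_tpm expects an RPKM matrix, got ", rpkm$unit, call. = FALSE)
  cs <- colSums(rpkm$values)
  if (any(cs <= 0))
    stop("all-zero RPKM column in sample(s): ",
         paste(colnames(rpkm$values)[cs <= 0], collapse = ", "), call. = FALSE)
  v <- sweep(rpkm$values, 2, cs, "/") * 1e6
  expression_matrix(v, "TPM", gene_lengths = rpkm$gene_lengths,
                    metadata = rpkm$metadata)
}

#' Log-transform TPM with below-minimum imputation of zeros
#'
#' Zeros (dropouts / undetected genes) are replaced by half the smallest
#' positive TPM observed anywhere in the matrix before taking `log2`, so a
#' lack of expression stays *below* every measured value instead of being
#' dropped — absent expression is itself informative for identity QC. The
#' imputation value used is recorded in the `"impute_value"` attribute of
#' the result.
#'
#' @param tpm An `expression_matrix` in `TPM` unit.
#' @return An `expression_matrix` in `logTPM` unit (base-2 logs).
#' @export
log_transform <- function(tpm) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (tpm$unit != "TPM")
    stop("log_transform expects a TPM matrix, got ", tpm$unit, call. = FALSE)
  v <- tpm$values
  pos <- v[v > 0]
  if (length(pos) == 0)
    stop("matrix is entirely zero; nothing to log-transform", call. = FALSE)
  impute <- min(pos) / 2
  v[v == 0 | is.na(v)] <- impute
  out <- expression_matrix(log2(v), "logTPM", gene_lengths = tpm$gene_lengths,
                           metadata = tpm$metadata)
  attr(out, "impute_value") <- impute
  out
}

#' Counts to log2 TPM in one step
#'
#' Convenience chain [compute_rpkm()] -> [rpkm_to_tpm()] ->
#' [log_transform()].
#'
#' @param counts An `expression_matrix` in `counts` unit with gene lengths.
#' @param gene_lengths Optional named length vector.
#' @return An `expression_matrix` in `logTPM` unit.
#' @export
counts_to_logtpm <- function(counts, gene_lengths = NULL) {
  log_transform(rpkm_to_tpm(compute_rpkm(counts, gene_lengths)))
}
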