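#' Coefficient of determination between two expression profiles
#'
#' The identity statistic of the QC method: R-squared between two samples'
#' log-TPM vectors over a gene set. The default estimator is the squared
#' Pearson correlation, which is symmetric in its arguments and invariant
#' to the log base used upstream. `mode = "identity_line"` instead measures
#' agreement about the y = x line (1 - SSE/SST with the total sum of
#' squares pooled over both vectors about their grand mean), which
#' penalizes systematic offsets that squared correlation ignores.
#'
#' @param x,y Numeric vectors of equal length (>= 3), typically log-TPM.
#' @param mode `"pearson_sq"` (default) or `"identity_line"`.
#' @return R-squared in `[0, 1]`.
#' @examples
#' r_squared(c(0, 1, 2, 3), c(0, 1, 1, 2))  # 0.9
#' @export
r_squared <- function(x, y, mode = c("pearson_sq", "identity_line")) {
  mode <- match.arg(mode)
  if (length(x) != length(y))
    stop("profiles differ in length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least 3 genes to correlate", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values in expression profiles", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant expression profile: zero variance", call. = FALSE)
  if (mode == "pearson_sq") {
    r <- stats::cor(x, y)
    if (r < 0)
      warning("negative slope: profiles are anticorrelated (r = ",
              signif(r, 3), ")", call. = FALSE)
    r^2
  } else {
    m <- mean(c(x, y))
    sse <- sum((x - y)^2)
    sst <- sum((x - m)^2) + sum((y - m)^2)
    max(0, 1 - sse / sst)
  }
}

#' Median reference profile of a set of lots
#'
#' The per-gene median log-TPM across the constituent samples (lots) of a
#' cell type, used as the comparison anchor for R-squared scoring.
#'
#' @param samples An `expression_matrix` in `logTPM` unit containing the
#'   constituent lots (columns).
#' @param name Profile name, e.g. the cell type.
#' @return An object of class `reference_profile`: `name`, `values` (named
#'   per-gene vector), `n_lots`.
#' @export
reference_profile <- function(samples, name) {
  stopifnot(inherits(samples, "expression_matrix"))
  if (samples$unit != "logTPM")
    stop("reference profiles are built from logTPM, got ", samples$unit,
         call. = FALSE)
  if (ncol(samples$values) < 1) stop("no samples", call. = FALSE)
  vals <- apply(samples$values, 1, stats::median)
  structure(list(name = name, values = vals,
                 n_lots = ncol(samples$values)),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile '%s': %d genes, median of %d lot(s)\n",
              x$name, length(x$values), x$n_lots))
  invisible(x)
}

#' Panel-restricted correlation records for samples against references
#'
#' Computes one R-squared record per (sample, reference) pair — and per
#' unordered sample pair when `sample_pairs = TRUE` — over the genes of
#' `panel` present in the matrix.
#'
#' @param matrix An `expression_matrix` in `logTPM` unit.
#' @param panel A `gene_panel`, or `NULL` to use all genes.
#' @param references List of `reference_profile` objects (may be empty).
#' @param sample_pairs Also record all unordered sample-sample pairs.
#' @param mode Estimator passed to [r_squared()].
#' @return A `data.frame` with columns `sample_id`, `reference_id`,
#'   `gene_set_name`, `n_genes`, `r_squared`.
#' @export
correlation_table <- function(matrix, panel = NULL, references = list(),
                              sample_pairs = FALSE,
                              mode = c("pearson_sq", "identity_line")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$unit != "logTPM")
    stop("correlation_table expects logTPM, got ", matrix$unit, call. = FALSE)
  if (inherits(references, "reference_profile")) references <- list(references)
  sub <- if (is.null(panel)) matrix else subset_matrix(matrix, panel)
  set_name <- if (is.null(panel)) "all_genes" else panel$name
  v <- sub$values
  rows <- list()
  for (ref in references) {
    shared <- intersect(rownames(v), names(ref$values))
    if (length(shared) < 3)
      stop("fewer than 3 shared genes between matrix and reference '",
           ref$name, "'", call. = FALSE)
    rv <- ref$values[shared]
    for (s in colnames(v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, reference_id = ref$name, gene_set_name = set_name,
        n_genes = length(shared),
        r_squared = r_squared(v[shared, s], rv, mode = mode),
        stringsAsFactors = FALSE)
    }
  }
  if (sample_pairs && ncol(v) >= 2) {
    cn <- colnames(v)
    for (i in seq_len(ncol(v) - 1)) for (j in seq(i + 1, ncol(v))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cn[i], reference_id = cn[j], gene_set_name = set_name,
        n_genes = nrow(v),
        r_squared = r_squared(v[, i], v[, j], mode = mode),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sample_id = character(), reference_id = character(),
                      gene_set_name = character(), n_genes = integer(),
                      r_squared = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discrimination statistic: percent deviation of an R-squared from self
#'
#' `%CV = |(r2_self - r2_other) / r2_self| * 100`. Large values mean the
#' compared population is easily told apart from the reference; reports
#' conventionally round to the nearest integer percent, the returned value
#' is unrounded.
#'
#' @param r2_self R-squared of the reference population against its own
#'   median profile (must be positive).
#' @param r2_other R-squared of the compared population against the same
#'   profile. Vectorized.
#' @return Percent deviation(s), unrounded.
#' @examples
#' round(cv_percent(0.949, 0.100))  # 89
#' @export
cv_percent <- function(r2_self, r2_other) {
  if (any(r2_self <= 0))
    stop("r2_self must be positive", call. = FALSE)
  abs((r2_self - r2_other) / r2_self) * 100
}

#' Detection power of one gene set over another
#'
#' The ratio of the discrimination statistics obtained with two gene sets
#' for the same population comparison: `cv(a) / cv(b)`, where `a` is the
#' curated panel and `b` a comparator (random gene set or whole
#' transcriptome). Values above 1 mean the panel separates the populations
#' better than the comparator. Computed from unrounded R-squared values;
#' reports conventionally show 2 decimals.
#'
#' @param r2_self_a,r2_other_a Self/other R-squared under gene set `a`.
#' @param r2_self_b,r2_other_b Self/other R-squared under gene set `b`.
#' @return Power ratio(s), unrounded.
#' @examples
#' round(detection_power(0.949, 0.462, 0.977, 0.803), 2)  # 2.88
#' @export
detection_power <- function(r2_self_a, r2_other_a, r2_self_b, r2_other_b) {
  cv_b <- cv_percent(r2_self_b, r2_other_b)
  if (any(cv_b == 0))
    stop("comparator CV is zero; power undefined", call. = FALSE)
  cv_percent(r2_self_a, r2_other_a) / cv_b
}

#' Benchmark a curated panel against comparator gene sets
#'
#' Reproduces the detection-power table layout: one query sample is scored
#' against the per-type median profile of every cell type, once per gene
#' set, and per-type CV and power ratios (panel vs. each comparator) are
#' derived. The self comparison is the query against its own type's median
#' profile.
#'
#' @param matrix An `expression_matrix` in `logTPM` with `cell_type` in its
#'   metadata.
#' @param panel The curated `gene_panel`.
#' @param query_sample Sample id of the query lot.
#' @param target_type Cell type of the query (the reference population).
#' @param comparators Named list of comparator `gene_panel`s; use `NULL`
#'   entries for the all-genes set.
#' @param mode Estimator passed to [r_squared()].
#' @return `data.frame`: one row per cell type with `r2_<set>` and
#'   `cv_<set>` columns per gene set and `power_vs_<comparator>` columns
#'   (NA on the target type's own row).
#' @export
benchmark_gene_sets <- function(matrix, panel, query_sample, target_type,
                                comparators = list(),
                                mode = c("pearson_sq", "identity_line")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "expression_matrix"))
  md <- matrix$metadata
  if (is.null(md) || !"cell_type" %in% names(md))
    stop("matrix metadata with a cell_type column is required", call. = FALSE)
  if (!query_sample %in% colnames(matrix$values))
    stop("query sample '", query_sample, "' not in matrix", call. = FALSE)
  sets <- c(stats::setNames(list(panel), panel$name), comparators)
  types <- unique(md$cell_type)
  res <- data.frame(cell_type = types, stringsAsFactors = FALSE)
  for (k in seq_along(sets)) {
    set_name <- names(sets)[k]
    sub <- if (is.null(sets[[k]])) matrix else subset_matrix(matrix, sets[[k]])
    r2 <- vapply(types, function(tp) {
      cols <- md$sample_id[md$cell_type == tp]
      prof <- reference_profile(
        expression_matrix(sub$values[, cols, drop = FALSE], "logTPM",
                          metadata = md[md$cell_type == tp, , drop = FALSE]),
        tp)
      r_squared(sub$values[, query_sample], prof$values[rownames(sub$values)],
                mode = mode)
    }, 0)
    self <- r2[types == target_type]
    res[[paste0("r2_", set_name)]] <- unname(r2)
    res[[paste0("cv_", set_name)]] <- unname(cv_percent(self, r2))
  }
  for (comp in setdiff(names(sets), panel$name)) {
    pw <- res[[paste0("cv_", panel$name)]] / res[[paste0("cv_", comp)]]
    pw[res$cell_type == target_type] <- NA_real_
    res[[paste0("power_vs_", comp)]] <- pw
  }
  res
}
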