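#' Run the full panel-correlation identity QC on a labelled dataset
#'
#' Ties the modules together for a dataset whose metadata assigns each
#' sample a `cell_type` and a `role` (`target`, `other_msc`, `non_msc`):
#' counts are normalized to log2 TPM, a median reference profile is built
#' from the target-type lots over the panel genes, thresholds are derived
#' from the other-MSC and non-MSC type comparisons (per-type median
#' profiles against the target reference), and every sample is classified
#' against the target reference.
#'
#' @param data An `expression_matrix` in `counts` or `logTPM` unit with
#'   `cell_type` and `role` metadata columns.
#' @param panel A `gene_panel`.
#' @param sd_multiplier Multiplier for the same-type bound in
#'   [derive_thresholds()].
#' @param mode Estimator passed to [r_squared()].
#' @return List of class `panel_qc`: `logtpm`, `reference` (the target
#'   median profile), `type_r2` (per-type R-squared of the type median
#'   profile vs. the reference), `thresholds`, `decisions` (per-sample
#'   classification), `panel_genes_used`.
#' @export
run_panel_qc <- function(data, panel, sd_multiplier = 1,
                         mode = c("pearson_sq", "identity_line")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "expression_matrix"))
  md <- data$metadata
  if (is.null(md) || !all(c("cell_type", "role") %in% names(md)))
    stop("metadata with cell_type and role columns is required", call. = FALSE)
  logtpm <- switch(data$unit,
                   counts = counts_to_logtpm(data),
                   logTPM = data,
                   stop("expected counts or logTPM input, got ", data$unit,
                        call. = FALSE))
  sub <- subset_matrix(logtpm, panel)
  target_type <- unique(md$cell_type[md$role == "target"])
  if (length(target_type) != 1)
    stop("metadata must define exactly one target cell type", call. = FALSE)
  type_profile <- function(tp) {
    cols <- md$sample_id[md$cell_type == tp]
    apply(sub$values[, cols, drop = FALSE], 1, stats::median)
  }
  ref <- structure(list(name = target_type, values = type_profile(target_type),
                        n_lots = sum(md$cell_type == target_type)),
                   class = "reference_profile")
  types <- unique(md$cell_type)
  type_r2 <- vapply(types, function(tp)
    r_squared(type_profile(tp), ref$values, mode = mode), 0)
  role_of <- md$role[match(types, md$cell_type)]
  thresholds <- derive_thresholds(type_r2[role_of == "other_msc"],
                                  type_r2[role_of == "non_msc"],
                                  sd_multiplier = sd_multiplier)
  sample_r2 <- vapply(colnames(sub$values), function(s)
    r_squared(sub$values[, s], ref$values, mode = mode), 0)
  decisions <- classify_sample(unname(sample_r2), thresholds,
                               sample_id = colnames(sub$values),
                               gene_set_name = panel$name)
  decisions$cell_type <- md$cell_type
  decisions$role <- md$role
  structure(list(logtpm = logtpm, reference = ref,
                 type_r2 = data.frame(cell_type = types, role = role_of,
                                      r_squared = unname(type_r2),
                                      stringsAsFactors = FALSE),
                 thresholds = thresholds, decisions = decisions,
                 panel_genes_used = nrow(sub$values)),
            class = "panel_qc")
}

#' @export
print.panel_qc <- function(x, ...) {
  cat(sprintf("panel_qc on %d panel genes, target '%s' (median of %d lots)\n",
              x$panel_genes_used, x$reference$name, x$reference$n_lots))
  print(x$thresholds)
  tab <- table(x$decisions$role, x$decisions$label)
  cat("decisions by role:\n")
  print(tab)
  invisible(x)
}
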