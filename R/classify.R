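#' Derive identity-QC decision thresholds from reference comparisons
#'
#' Two boundaries are extracted from observed R-squared values. The
#' same-type lower bound is `mean + multiplier * SD` of the other-tissue
#' MSC comparisons (sample SD, n-1 denominator), with mean and SD first
#' rounded to 3 decimals — the reporting precision at which the rule is
#' stated and applied (e.g. 0.809 + 0.020 = 0.829). The non-MSC upper
#' bound is the maximum R-squared observed among non-MSC populations, i.e.
#' the top of their observed range.
#'
#' @param other_msc_r2 R-squared values of other-tissue MSC populations
#'   against the target reference (>= 2 values).
#' @param non_msc_r2 R-squared values of non-MSC populations (>= 1 value).
#' @param sd_multiplier Multiplier on the SD for the same-type bound.
#' @return An object of class `threshold_set`: `same_type_lower`,
#'   `non_msc_upper`, `other_msc_mean`, `other_msc_sd`, `sd_multiplier`,
#'   and `provenance` (the input values).
#' @examples
#' derive_thresholds(c(0.821, 0.786, 0.821),
#'                   c(0.699, 0.720, 0.462, 0.132, 0.100))
#' @export
derive_thresholds <- function(other_msc_r2, non_msc_r2, sd_multiplier = 1) {
  other_msc_r2 <- as.numeric(other_msc_r2)
  non_msc_r2 <- as.numeric(non_msc_r2)
  if (length(other_msc_r2) < 2)
    stop("need at least 2 other-MSC R-squared values (SD undefined)",
         call. = FALSE)
  if (length(non_msc_r2) < 1)
    stop("need at least 1 non-MSC R-squared value", call. = FALSE)
  if (any(c(other_msc_r2, non_msc_r2) < 0 | c(other_msc_r2, non_msc_r2) > 1))
    stop("R-squared values must lie in [0, 1]", call. = FALSE)
  m <- round(mean(other_msc_r2), 3)
  s <- round(stats::sd(other_msc_r2), 3)
  lower <- round(m + sd_multiplier * s, 3)
  # round the upper bound up so the defining observation stays inside its zone
  upper <- ceiling(round(max(non_msc_r2) * 1000, 6)) / 1000
  if (upper >= lower)
    warning("non-MSC upper bound (", upper, ") is not below the same-type ",
            "lower bound (", lower, "); zones overlap", call. = FALSE)
  structure(list(same_type_lower = lower, non_msc_upper = upper,
                 other_msc_mean = m, other_msc_sd = s,
                 sd_multiplier = sd_multiplier,
                 provenance = list(other_msc_r2 = other_msc_r2,
                                   non_msc_r2 = non_msc_r2)),
            class = "threshold_set")
}

#' Construct a threshold_set from known boundaries
#'
#' For applying published boundaries without re-deriving them.
#'
#' @param same_type_lower,non_msc_upper The two decision boundaries.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(same_type_lower, non_msc_upper) {
  if (!(non_msc_upper < same_type_lower))
    stop("need non_msc_upper < same_type_lower", call. = FALSE)
  if (same_type_lower >= 1 || non_msc_upper <= 0)
    stop("bounds must satisfy 0 < non_msc_upper < same_type_lower < 1",
         call. = FALSE)
  structure(list(same_type_lower = same_type_lower,
                 non_msc_upper = non_msc_upper,
                 other_msc_mean = NA_real_, other_msc_sd = NA_real_,
                 sd_multiplier = NA_real_, provenance = list()),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set: target MSC at R^2 >= %.3f, non-MSC at <= %.3f\n",
              x$same_type_lower, x$non_msc_upper))
  if (!is.na(x$other_msc_mean))
    cat(sprintf("  other-MSC mean %.3f, SD %.3f (x%g)\n",
                x$other_msc_mean, x$other_msc_sd, x$sd_multiplier))
  invisible(x)
}

qc_labels <- c("non_msc_like", "other_msc_zone", "target_msc")

#' Classify a sample by its R-squared against the target reference
#'
#' A monotone three-way decision: `r2 >= same_type_lower` labels the sample
#' `target_msc`; `r2 <= non_msc_upper` labels it `non_msc_like`; values in
#' between fall in the `other_msc_zone` — territory of MSCs from other
#' tissues, not a failure. Both boundaries are inclusive toward their
#' labels.
#'
#' @param r2 R-squared value(s) in `[0, 1]` (vectorized).
#' @param thresholds A `threshold_set`.
#' @param sample_id Optional sample identifier(s) for the report.
#' @param gene_set_name Optional gene-set name for the report.
#' @return `data.frame` with `sample_id`, `r_squared`, `label` (ordered
#'   factor `non_msc_like < other_msc_zone < target_msc`), threshold
#'   columns and `gene_set_name`.
#' @examples
#' th <- threshold_set(0.829, 0.720)
#' classify_sample(c(0.847, 0.780, 0.700), th)
#' @export
classify_sample <- function(r2, thresholds, sample_id = NULL,
                            gene_set_name = NA_character_) {
  stopifnot(inherits(thresholds, "threshold_set"))
  r2 <- as.numeric(r2)
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1))
    stop("R-squared must lie in [0, 1]", call. = FALSE)
  lab <- ifelse(r2 >= thresholds$same_type_lower, "target_msc",
                ifelse(r2 <= thresholds$non_msc_upper, "non_msc_like",
                       "other_msc_zone"))
  if (is.null(sample_id)) sample_id <- paste0("sample", seq_along(r2))
  data.frame(sample_id = sample_id, r_squared = r2,
             label = factor(lab, levels = qc_labels, ordered = TRUE),
             same_type_lower = thresholds$same_type_lower,
             non_msc_upper = thresholds$non_msc_upper,
             gene_set_name = gene_set_name,
             stringsAsFactors = FALSE)
}

#' Monitor a lot's identity across culture passages
#'
#' Classifies each passage's R-squared, reports the first passage (if any)
#' at which the label degrades relative to the previous passage, the
#' per-passage signed change in R-squared, and the least-squares slope of
#' R-squared over passage index (NA for a single passage).
#'
#' @param passages Character/numeric passage labels, ordered by passage.
#' @param r2 R-squared per passage against the target reference.
#' @param thresholds A `threshold_set`.
#' @return List of class `passage_report`: `decisions` (per-passage
#'   classification with `delta_r2`), `first_degradation` (passage label or
#'   `NA`), `slope`.
#' @export
monitor_passages <- function(passages, r2, thresholds) {
  if (length(passages) == 0) stop("empty passage series", call. = FALSE)
  if (length(passages) != length(r2))
    stop("passages and r2 differ in length", call. = FALSE)
  dec <- classify_sample(r2, thresholds, sample_id = as.character(passages))
  names(dec)[names(dec) == "sample_id"] <- "passage"
  dec$delta_r2 <- c(NA_real_, diff(r2))
  ord <- as.integer(dec$label)
  worse <- which(diff(ord) < 0) + 1L
  first_deg <- if (length(worse)) as.character(passages[worse[1]]) else NA_character_
  slope <- if (length(r2) >= 2)
    unname(stats::coef(stats::lm(r2 ~ seq_along(r2)))[2]) else NA_real_
  structure(list(decisions = dec, first_degradation = first_deg,
                 slope = slope),
            class = "passage_report")
}

#' @export
print.passage_report <- function(x, ...) {
  cat("passage_report:\n")
  print(x$decisions[, c("passage", "r_squared", "label", "delta_r2")])
  if (is.na(x$first_degradation)) cat("  no degradation across passages\n")
  else cat("  first degradation at passage", x$first_degradation, "\n")
  if (!is.na(x$slope))
    cat(sprintf("  R^2 trend slope per passage: %+.4f\n", x$slope))
  invisible(x)
}

#' Write a QC report (thresholds, decisions, optional passage trend) as JSON
#'
#' @param thresholds A `threshold_set`.
#' @param decisions A decision `data.frame` from [classify_sample()].
#' @param path Output path.
#' @param passage_report Optional `passage_report`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(thresholds, decisions, path,
                            passage_report = NULL) {
  decisions$label <- as.character(decisions$label)
  rep <- list(
    thresholds = list(
      same_type_lower = thresholds$same_type_lower,
      non_msc_upper = thresholds$non_msc_upper,
      other_msc_mean = thresholds$other_msc_mean,
      other_msc_sd = thresholds$other_msc_sd,
      sd_multiplier = thresholds$sd_multiplier,
      provenance = thresholds$provenance),
    decisions = decisions)
  if (!is.null(passage_report)) {
    pr <- passage_report
    pr$decisions$label <- as.character(pr$decisions$label)
    rep$passage_trend <- list(decisions = pr$decisions,
                              first_degradation = pr$first_degradation,
                              slope = pr$slope)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
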