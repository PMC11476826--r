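#' Curated gene panels
#'
#' A `gene_panel` holds an ordered table of candidate genes with their
#' functional-category labels and two exclusion flags used during panel
#' construction: genes expressed so highly that they would dominate
#' amplicon sequencing, and genes for which PCR primers are not readily
#' available. The included panel is what remains after dropping flagged
#' entries.
#'
#' @param entries `data.frame` with columns `symbol`, `gene_id`,
#'   `categories` (list-column of character vectors, or a `;`-separated
#'   character column), `excluded_high_expression`, `excluded_no_primer`
#'   (logical).
#' @param name Panel name.
#' @param universe_size Size of the gene universe the panel was drawn from
#'   (`NA` if unknown).
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(entries, name = "panel", universe_size = NA_integer_) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  for (col in c("symbol", "gene_id")) {
    if (!col %in% names(entries)) entries[[col]] <- NA_character_
    entries[[col]] <- as.character(entries[[col]])
  }
  if (!"categories" %in% names(entries)) {
    entries$categories <- replicate(nrow(entries), character(0),
                                    simplify = FALSE)
  } else if (!is.list(entries$categories)) {
    entries$categories <- lapply(as.character(entries$categories), function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else unique(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
    })
  }
  for (col in c("excluded_high_expression", "excluded_no_primer")) {
    if (!col %in% names(entries)) entries[[col]] <- FALSE
    entries[[col]] <- parse_flag(entries[[col]])
  }
  blank_sym <- is.na(entries$symbol) | !nzchar(entries$symbol)
  if (any(blank_sym))
    stop("every panel entry needs a non-empty gene symbol (rows ",
         paste(utils::head(which(blank_sym), 5), collapse = ", "), ")",
         call. = FALSE)
  no_id <- is.na(entries$gene_id) | !nzchar(entries$gene_id)
  entries$gene_id[no_id] <- entries$symbol[no_id]
  key <- tolower(entries$gene_id)
  if (anyDuplicated(key)) entries <- collapse_duplicates(entries, key)
  rownames(entries) <- NULL
  structure(list(name = name, entries = entries,
                 universe_size = universe_size),
            class = "gene_panel")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- tolower(trimws(as.character(x)))
  !is.na(x) & x %in% c("1", "true", "t", "yes", "y")
}

# union categories, OR flags, keep first occurrence's position and ids
collapse_duplicates <- function(entries, key) {
  idx <- split(seq_len(nrow(entries)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    r <- entries[i[1], , drop = FALSE]
    r$categories <- list(unique(unlist(entries$categories[i])))
    r$excluded_high_expression <- any(entries$excluded_high_expression[i])
    r$excluded_no_primer <- any(entries$excluded_no_primer[i])
    r
  })
  do.call(rbind, rows)
}

#' @export
print.gene_panel <- function(x, ...) {
  inc <- panel_included(x)
  cat(sprintf("gene_panel '%s': %d candidates, %d included (%d excluded)\n",
              x$name, nrow(x$entries), length(inc),
              nrow(x$entries) - length(inc)))
  if (!is.na(x$universe_size))
    cat("  universe size:", x$universe_size, "\n")
  invisible(x)
}

#' @export
length.gene_panel <- function(x) nrow(x$entries)

#' Gene identifiers of the included (non-excluded) panel entries
#'
#' @param panel A `gene_panel`.
#' @return Character vector of gene identifiers, in panel order.
#' @export
panel_included <- function(panel) {
  stopifnot(inherits(panel, "gene_panel"))
  keep <- !(panel$entries$excluded_high_expression |
              panel$entries$excluded_no_primer)
  panel$entries$gene_id[keep]
}

#' Load a gene panel from a delimited table
#'
#' The panel dialect is tab-separated, UTF-8, with `#` comment lines and a
#' header containing at least `symbol`, `gene_id`, `categories`,
#' `excluded_high_expression` and `excluded_no_primer`. `categories` is
#' multi-valued, `;`-separated. Duplicate gene ids are collapsed into one
#' entry whose categories are the union of the duplicates'.
#'
#' @param path Path to the panel table.
#' @param name Panel name (defaults to the file name).
#' @return A `gene_panel` preserving input order.
#' @export
load_panel <- function(path, name = NULL) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse panel table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0)
    stop("panel table '", path, "' is empty", call. = FALSE)
  required <- c("symbol", "gene_id", "categories",
                "excluded_high_expression", "excluded_no_primer")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("panel table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_panel(df, name = name)
}

#' Write a gene panel back to the TSV dialect read by [load_panel()]
#'
#' @param panel A `gene_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  e <- panel$entries
  out <- data.frame(
    symbol = e$symbol,
    gene_id = e$gene_id,
    categories = vapply(e$categories, paste, "", collapse = ";"),
    excluded_high_expression = as.integer(e$excluded_high_expression),
    excluded_no_primer = as.integer(e$excluded_no_primer),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the included panel from a candidate table
#'
#' Drops candidates carrying the requested exclusion flags, mirroring how a
#' curated amplicon panel is finalized: overly highly expressed genes would
#' swamp the sequencing library and genes without available PCR primers
#' cannot be amplified. A gene flagged for both reasons is removed once,
#' with a warning, so the included count stays
#' `candidates - high_expression_flagged - no_primer_flagged` only when the
#' flags are disjoint.
#'
#' @param candidates A deduplicated `gene_panel` of candidates.
#' @param drop_high_expression,drop_no_primer Which exclusion flags to apply.
#' @return A `gene_panel` containing only the retained entries (all flags
#'   cleared), with `universe_size` carried over.
#' @examples
#' tab <- data.frame(symbol = c("IDO1", "ACTB", "XYZ1"),
#'                   gene_id = c("3620", "60", "999"),
#'                   excluded_high_expression = c(FALSE, TRUE, FALSE),
#'                   excluded_no_primer = c(FALSE, FALSE, TRUE))
#' build_panel(gene_panel(tab))
#' @export
build_panel <- function(candidates, drop_high_expression = TRUE,
                        drop_no_primer = TRUE) {
  stopifnot(inherits(candidates, "gene_panel"))
  e <- candidates$entries
  both <- e$excluded_high_expression & e$excluded_no_primer
  if (any(both))
    warning(sum(both), " gene(s) flagged for both exclusion reasons; ",
            "removed once", call. = FALSE)
  drop <- rep(FALSE, nrow(e))
  if (drop_high_expression) drop <- drop | e$excluded_high_expression
  if (drop_no_primer) drop <- drop | e$excluded_no_primer
  kept <- e[!drop, , drop = FALSE]
  if (nrow(kept) == 0)
    warning("all candidates excluded; panel is empty", call. = FALSE)
  kept$excluded_high_expression <- rep(FALSE, nrow(kept))
  kept$excluded_no_primer <- rep(FALSE, nrow(kept))
  gene_panel(kept, name = candidates$name,
             universe_size = candidates$universe_size)
}

#' Draw a seeded random gene panel from a universe
#'
#' Uniform sampling without replacement from the *sorted* universe, so the
#' result depends only on the universe membership, the size and the seed —
#' not on input file order. This is the "random-human" comparator used to
#' benchmark a curated panel's discrimination power.
#'
#' @param universe Character vector of gene identifiers.
#' @param size Number of genes to draw.
#' @param seed Integer seed; identical `(universe, size, seed)` give an
#'   identical panel.
#' @param name Panel name.
#' @return A `gene_panel` of `size` entries.
#' @export
sample_random_panel <- function(universe, size, seed, name = "random") {
  universe <- sort(unique(as.character(universe)))
  if (size > length(universe))
    stop("cannot draw ", size, " genes from a universe of ",
         length(universe), call. = FALSE)
  ids <- with_seed(seed, sample(universe, size))
  gene_panel(data.frame(symbol = ids, gene_id = ids,
                        stringsAsFactors = FALSE),
             name = name, universe_size = length(universe))
}

# run code under a fixed RNG state, restoring the caller's afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Restrict an expression matrix to a panel's included genes
#'
#' Genes are resolved by `gene_id` against the matrix rownames, falling back
#' to a case-insensitive symbol match. Output rows follow panel order.
#' The number of panel genes not found in the matrix is recorded in the
#' `"n_absent"` attribute.
#'
#' @param matrix An `expression_matrix`.
#' @param panel A `gene_panel`.
#' @return An `expression_matrix` restricted to the panel genes present.
#' @export
subset_matrix <- function(matrix, panel) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(panel, "gene_panel"))
  keep <- !(panel$entries$excluded_high_expression |
              panel$entries$excluded_no_primer)
  ids <- panel$entries$gene_id[keep]
  syms <- panel$entries$symbol[keep]
  rows <- rownames(matrix$values)
  hit <- match(ids, rows)
  miss <- is.na(hit)
  hit[miss] <- match(tolower(syms[miss]), tolower(rows))
  n_absent <- sum(is.na(hit))
  hit <- hit[!is.na(hit)]
  hit <- hit[!duplicated(hit)]
  if (length(hit) == 0)
    stop("no panel gene found in the matrix; identifier mismatch between ",
         "panel '", panel$name, "' and matrix rows", call. = FALSE)
  out <- expression_matrix(matrix$values[hit, , drop = FALSE], matrix$unit,
                           gene_lengths = matrix$gene_lengths[rownames(matrix$values)[hit]],
                           metadata = matrix$metadata)
  attr(out, "impute_value") <- attr(matrix, "impute_value")
  attr(out, "n_absent") <- n_absent
  out
}
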