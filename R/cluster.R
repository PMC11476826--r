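#' Correlation distance between samples on a gene panel
#'
#' `d(a, b) = 1 - Pearson r(a, b)` over the panel genes, so duplicate
#' samples are at distance 0 and perfectly anticorrelated samples at 2.
#' Unlike the R-squared identity statistic, the distance keeps the sign of
#' the correlation: anticorrelated samples stay maximally distant instead
#' of being conflated with identical ones.
#'
#' @param matrix An `expression_matrix` in `logTPM` unit with >= 2 samples.
#' @param panel Optional `gene_panel` restriction (`NULL` = all genes).
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
distance_matrix <- function(matrix, panel = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$unit != "logTPM")
    stop("distance_matrix expects logTPM, got ", matrix$unit, call. = FALSE)
  sub <- if (is.null(panel)) matrix else subset_matrix(matrix, panel)
  v <- sub$values
  if (ncol(v) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression vector in sample(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering on a sample-sample distance matrix. Average
#' linkage (UPGMA) is used by default; it produces monotone non-decreasing
#' merge heights on any proper distance matrix.
#'
#' @param dist Symmetric distance matrix (e.g. from [distance_matrix()]),
#'   or a `dist` object.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An `hclust` merge tree (leaf count = sample count).
#' @export
hierarchical_cluster <- function(dist, linkage = "average") {
  if (inherits(dist, "dist")) {
    d <- dist
  } else {
    if (!is.matrix(dist) || nrow(dist) != ncol(dist))
      stop("distance must be a square matrix or dist object", call. = FALSE)
    if (max(abs(dist - t(dist))) > 1e-8)
      stop("distance matrix is not symmetric", call. = FALSE)
    d <- stats::as.dist(dist)
  }
  stats::hclust(d, method = linkage)
}

#' Write a merge tree as a Newick string
#'
#' Branch lengths are half the merge-height differences, so two leaves
#' merging at height `h` are written `(A:h/2,B:h/2);` and the tree is
#' ultrametric. Labels containing characters outside `[A-Za-z0-9_.|-]` are
#' single-quoted per the Newick dialect rules.
#'
#' @param dendrogram An `hclust` object.
#' @param path Output path, or `NULL` to return the string.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  labels <- dendrogram$labels
  if (is.null(labels)) labels <- as.character(seq_along(dendrogram$order))
  quote_label <- function(x) {
    if (grepl("[^A-Za-z0-9_.|-]", x))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  h <- dendrogram$height
  m <- dendrogram$merge
  node_str <- function(i) {
    # i < 0: leaf -i; i > 0: internal merge i
    if (i < 0) list(str = quote_label(labels[-i]), height = 0)
    else {
      a <- node_str(m[i, 1]); b <- node_str(m[i, 2])
      list(str = sprintf("(%s:%.12g,%s:%.12g)",
                         a$str, (h[i] - a$height) / 2,
                         b$str, (h[i] - b$height) / 2),
           height = h[i])
    }
  }
  nwk <- if (length(h) == 0) paste0(quote_label(labels[1]), ";")
  else paste0(node_str(length(h))$str, ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Cluster samples on a panel and export distances, tree and heatmap data
#'
#' Convenience wrapper tying [distance_matrix()], [hierarchical_cluster()]
#' and [write_newick()] together.
#'
#' @param matrix An `expression_matrix` in `logTPM` unit.
#' @param panel Optional `gene_panel`.
#' @param newick_path,distance_path,heatmap_json_path Optional output paths
#'   for the Newick tree, the TSV distance matrix, and a JSON bundle of
#'   values plus leaf order for external heatmap rendering.
#' @return List: `distances`, `tree` (`hclust`), `newick`.
#' @export
cluster_samples <- function(matrix, panel = NULL, newick_path = NULL,
                            distance_path = NULL, heatmap_json_path = NULL) {
  d <- distance_matrix(matrix, panel)
  tree <- hierarchical_cluster(d)
  nwk <- write_newick(tree, newick_path)
  if (!is.null(distance_path)) {
    df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
    utils::write.table(df, distance_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(heatmap_json_path)) {
    sub <- if (is.null(panel)) matrix else subset_matrix(matrix, panel)
    jsonlite::write_json(
      list(genes = rownames(sub$values), samples = colnames(sub$values),
           values = sub$values, sample_order = tree$labels[tree$order]),
      heatmap_json_path, digits = NA, auto_unbox = TRUE)
  }
  list(distances = d, tree = tree, newick = nwk)
}
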