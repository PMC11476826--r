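# fixtures are built in code; nothing is read from disk except package extdata

# independent clamped-prefix-sum oracle for read trimming: computes the sums
# with Reduce/accumulate and applies the interval definition directly
oracle_trim <- function(q, limit = 0.05) {
  d <- limit - 10^(-q / 10)
  s <- Reduce(function(acc, di) max(0, acc + di), d, 0, accumulate = TRUE)[-1]
  if (!any(s > 0)) return(c(start = 0L, end = 0L))
  c(start = which(s > 0)[1] - 1L, end = which(s == max(s))[1])
}

# brute-force squared Pearson correlation from raw sum formulas
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num^2 / den
}

# small counts matrix with lengths and two-type metadata
make_counts_em <- function(n_genes = 30, seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- c("A_L1", "A_L2", "B_L1", "B_L2")
  m <- matrix(rpois(n_genes * 4, lambda = 60), n_genes, 4,
              dimnames = list(genes, samples))
  lengths <- setNames(sample(500:3000, n_genes), genes)
  md <- data.frame(sample_id = samples,
                   cell_type = c("A", "A", "B", "B"),
                   role = c("target", "target", "non_msc", "non_msc"),
                   lot = c(1, 2, 1, 2))
  expression_matrix(m, "counts", gene_lengths = lengths, metadata = md)
}

# random logTPM matrix: shared gene profile + per-sample noise, so samples
# are positively correlated as real log-TPM replicates are
make_logtpm_em <- function(n_genes = 20, samples = c("s1", "s2", "s3"),
                           seed = 7) {
  set.seed(seed)
  profile <- rnorm(n_genes, 5, 2)
  m <- profile + matrix(rnorm(n_genes * length(samples), 0, 0.5), n_genes)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)), samples)
  expression_matrix(m, "logTPM")
}

# candidate panel table emulating a curated-panel construction run:
# n_total deduplicated candidates, n_high + n_noprimer flagged (disjoint)
write_candidate_table <- function(path, n_total = 1199, n_high = 18,
                                  n_noprimer = 38) {
  sym <- sprintf("GENE%04d", seq_len(n_total))
  high <- rep(0L, n_total); high[seq_len(n_high)] <- 1L
  nop <- rep(0L, n_total)
  nop[seq(n_high + 1, n_high + n_noprimer)] <- 1L
  df <- data.frame(symbol = sym, gene_id = paste0("id", seq_len(n_total)),
                   categories = "msc", excluded_high_expression = high,
                   excluded_no_primer = nop)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# FASTQ writer for trim tests (Phred+33)
write_fastq <- function(path, ids, seqs, quals) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  out <- character(0)
  for (i in seq_along(ids)) {
    q <- intToUtf8(quals[[i]] + 33L)
    out <- c(out, paste0("@", ids[i]), seqs[i], "+", q)
  }
  writeLines(out, path)
  path
}

# published benchmark R^2 table shipped with the package
reference_r2 <- function() {
  utils::read.delim(system.file("extdata", "reference_r2_table.tsv",
                                package = "panelqc"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
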