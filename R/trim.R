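#' Convert a Phred quality score to a base-call error probability
#'
#' A Phred score is minus ten times the log10 error probability, so the
#' inverse map is `10^(-q/10)`.
#'
#' @param q Non-negative Phred score(s).
#' @return Error probability in `(0, 1]`, vectorized over `q`.
#' @examples
#' phred_to_error_prob(c(0, 10, 40))
#' @export
phred_to_error_prob <- function(q) {
  if (!is.numeric(q) || any(is.na(q)) || any(q < 0))
    stop("Phred scores must be non-negative numbers", call. = FALSE)
  10^(-q / 10)
}

#' Quality-trim one read by the clamped cumulative-sum rule
#'
#' Each base contributes the difference between the error-probability limit
#' and its own error probability, `d_i = limit - 10^(-q_i/10)`. A running
#' sum is accumulated with clamping at zero (`s_i = max(0, s_{i-1} + d_i)`).
#' The retained interval starts at the first position where the sum becomes
#' positive and ends at the (first) position where the sum is maximal; a
#' read whose sum never becomes positive is discarded entirely.
#'
#' Intervals are 0-based, half-open `[start, end)`, so `kept_length =
#' end - start` and a discarded read is encoded as `start = end = 0`.
#'
#' @param qualities Integer/numeric vector of per-base Phred scores.
#' @param limit Error-probability limit; bases with error probability below
#'   it push the sum up. Default 0.05 (Phred 13).
#' @return A list of class `trim_result`: `start`, `end`, `kept_length`.
#' @examples
#' trim_read(rep(40, 10))            # whole read kept
#' trim_read(rep(2, 10))             # discarded
#' trim_read(c(2, 2, 40, 40, 40, 2, 40, 2, 2))  # [2, 5)
#' @export
trim_read <- function(qualities, limit = 0.05) {
  if (length(qualities) == 0)
    stop("empty quality sequence", call. = FALSE)
  d <- limit - phred_to_error_prob(qualities)
  s <- numeric(length(d))
  acc <- 0
  for (i in seq_along(d)) {
    acc <- max(0, acc + d[i])
    s[i] <- acc
  }
  if (all(s <= 0)) {
    res <- list(start = 0L, end = 0L, kept_length = 0L)
  } else {
    start <- which(s > 0)[1] - 1L
    end <- which.max(s)            # first occurrence of the maximum
    res <- list(start = start, end = as.integer(end),
                kept_length = as.integer(end) - start)
  }
  class(res) <- "trim_result"
  res
}

#' @export
print.trim_result <- function(x, ...) {
  if (x$kept_length == 0) cat("trim_result: read discarded\n")
  else cat(sprintf("trim_result: keep [%d, %d), %d bases\n",
                   x$start, x$end, x$kept_length))
  invisible(x)
}

#' Quality-trim a FASTQ file
#'
#' Applies [trim_read()] to every read of a Phred+33 FASTQ file (gzip
#' accepted), writing the retained intervals to `out` in input order.
#' Fully discarded reads are omitted from the output.
#'
#' @param infile Input FASTQ path (Phred+33).
#' @param outfile Output FASTQ path.
#' @param limit Error-probability limit passed to [trim_read()].
#' @return A list summary: `reads_in`, `reads_kept`, `reads_discarded`,
#'   `bases_in`, `bases_kept`, `bases_removed`.
#' @export
trim_fastq <- function(infile, outfile, limit = 0.05) {
  parsed <- tryCatch({
    reads <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(infile,
                                                quality.scoring = "phred"))
    # decoding the qualities here forces full validation of the records
    list(reads = reads,
         quals = as(Biostrings::quality(reads), "IntegerList"))
  }, error = function(e) stop("malformed FASTQ '", infile, "': ",
                              conditionMessage(e), call. = FALSE))
  reads <- parsed$reads
  quals <- parsed$quals
  bad <- which(lengths(quals) != Biostrings::width(reads))
  if (length(bad))
    stop("malformed FASTQ '", infile, "': read/quality length mismatch at ",
         "record ", bad[1], call. = FALSE)
  n <- length(reads)
  if (n == 0) {
    file.create(outfile)
    return(list(reads_in = 0L, reads_kept = 0L, reads_discarded = 0L,
                bases_in = 0L, bases_kept = 0L, bases_removed = 0L))
  }
  ivs <- lapply(seq_len(n), function(i) trim_read(quals[[i]], limit))
  starts <- vapply(ivs, `[[`, 0L, "start")
  ends <- vapply(ivs, `[[`, 0L, "end")
  keep <- ends > starts
  bases_in <- sum(lengths(quals))
  bases_kept <- sum(ends[keep] - starts[keep])
  if (any(keep)) {
    trimmed <- suppressWarnings(
      Biostrings::subseq(reads[keep], start = starts[keep] + 1L,
                         end = ends[keep]))
    Biostrings::writeQualityScaledXStringSet(trimmed, outfile)
  } else {
    file.create(outfile)
  }
  list(reads_in = n, reads_kept = sum(keep),
       reads_discarded = n - sum(keep),
       bases_in = as.integer(bases_in),
       bases_kept = as.integer(bases_kept),
       bases_removed = as.integer(bases_in - bases_kept))
}
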