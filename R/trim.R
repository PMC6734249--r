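#' Trim short 3' adapter overhangs left behind by template trimmers
#'
#' Template-based trimmers cannot recognise adapter matches shorter than
#' about 7 bp, yet CUT&RUN inserts are frequently shorter than the read, so
#' 1-6 bp of adapter read-through routinely survives the first trimming
#' pass. This second pass removes the longest read suffix of length
#' `k in [1, max_overhang]` that exactly equals the first `k` bases of the
#' adapter (longest match wins; one trim per read; no mismatches -- short
#' exact matching is all that is safe at these lengths).
#'
#' @param seq character vector of read sequences
#' @param qual character vector of quality strings (same lengths), or NULL
#' @param adapter adapter sequence (only its first `max_overhang` bases are
#'   used)
#' @param max_overhang maximum overhang length to remove (default 6)
#' @return list with `seq`, `qual` (trimmed in lockstep) and `n_trimmed`
#'   (integer vector, 0 when no suffix matched)
#' @export
trim_overhang <- function(seq, qual = NULL, adapter, max_overhang = 6L) {
  if (missing(adapter) || is.null(adapter) || !nzchar(adapter)) {
    stopf("adapter must be a non-empty nucleotide string")
  }
  if (max_overhang > nchar(adapter)) {
    stopf("max_overhang (%d) exceeds adapter length (%d)",
          max_overhang, nchar(adapter))
  }
  if (!is.null(qual) && any(nchar(qual) != nchar(seq))) {
    stopf("quality strings must match sequence lengths")
  }
  if (length(seq) == 0L) {
    return(list(seq = character(), qual = if (is.null(qual)) NULL else
      character(), n_trimmed = integer()))
  }
  n <- nchar(seq)
  n_trimmed <- integer(length(seq))
  for (k in seq(min(max_overhang, max(n, 1L)), 1L)) {
    prefix <- substr(adapter, 1L, k)
    hit <- n_trimmed == 0L & n >= k &
      substr(seq, n - k + 1L, n) == prefix
    n_trimmed[hit] <- k
  }
  keep_to <- n - n_trimmed
  list(seq = substr(seq, 1L, keep_to),
       qual = if (is.null(qual)) NULL else substr(qual, 1L, keep_to),
       n_trimmed = n_trimmed)
}

#' Minimum-length filter for trimmed read pairs
#'
#' Reads shorter than `min_len` are hard to align accurately; the whole pair
#' is dropped when either mate fails, because paired alignment needs both
#' mates. The boundary is inclusive: a 25-bp mate is kept at the default.
#'
#' @param seq1,seq2 character vectors of mate sequences
#' @param min_len minimum kept read length in bp (default 25)
#' @return logical vector, TRUE where the pair is kept
#' @export
filter_min_length <- function(seq1, seq2, min_len = 25L) {
  nchar(seq1) >= min_len & nchar(seq2) >= min_len
}

#' Trim paired FASTQ files and apply the minimum-length filter
#'
#' Runs [trim_overhang()] on both mates of every pair and drops pairs
#' failing [filter_min_length()]. Counters feed the QC adapter-content
#' metric.
#'
#' @param in1,in2 input FASTQ paths (gzip accepted)
#' @param out1,out2 output FASTQ paths (gzip when ending in .gz)
#' @param adapter adapter sequence
#' @param max_overhang maximum overhang length (default 6)
#' @param min_len minimum read length (default 25)
#' @return counters list: pairs_in, pairs_out, pairs_dropped,
#'   reads_trimmed, bases_trimmed
#' @export
trim_fastq_pair <- function(in1, in2, out1, out2,
                            adapter = "AGATCGGAAGAGC",
                            max_overhang = 6L, min_len = 25L) {
  r1 <- read_fastq(in1)
  r2 <- read_fastq(in2)
  if (nrow(r1) != nrow(r2)) stopf("mate files differ in read count")
  t1 <- trim_overhang(r1$seq, r1$qual, adapter, max_overhang)
  t2 <- trim_overhang(r2$seq, r2$qual, adapter, max_overhang)
  keep <- filter_min_length(t1$seq, t2$seq, min_len)
  write_fastq(data.frame(name = r1$name[keep], seq = t1$seq[keep],
                         qual = t1$qual[keep], stringsAsFactors = FALSE), out1)
  write_fastq(data.frame(name = r2$name[keep], seq = t2$seq[keep],
                         qual = t2$qual[keep], stringsAsFactors = FALSE), out2)
  list(pairs_in = nrow(r1), pairs_out = sum(keep),
       pairs_dropped = sum(!keep),
       reads_trimmed = sum(t1$n_trimmed > 0) + sum(t2$n_trimmed > 0),
       bases_trimmed = sum(t1$n_trimmed) + sum(t2$n_trimmed),
       n_trimmed1 = t1$n_trimmed, n_trimmed2 = t2$n_trimmed)
}
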