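#' Load paired-end fragments from BAM or fragment BED
#'
#' Produces one record per properly paired primary alignment pair. Each
#' fragment carries, besides its 0-based half-open interval, the two
#' nuclease cut boundaries: `s1`, the 5' boundary of mate R1, and `e2`, the
#' 5' boundary of mate R2 (for a proper FR pair these are the two outer
#' fragment boundaries, matching `bedtools bamtobed` fragment ends). All
#' coordinates are inter-base boundary indices, so downstream cut-matrix
#' columns need no strand-dependent 1-bp correction.
#'
#' @param path BAM file (paired-end) or 6-column fragment BED; a data.frame
#'   with the fragment columns is passed through after validation
#' @param min_mapq drop pairs with either mate below this MAPQ (default 0 =
#'   no filter; the field convention is no MAPQ filtering by default)
#' @return data.frame with chrom, start, end, name, score, strand (of R1),
#'   s1, e2; attribute `n_skipped` counts pairs/reads dropped on loading
#' @export
load_fragments <- function(path, min_mapq = 0L) {
  if (is.data.frame(path)) {
    return(validate_fragments(path))
  }
  stopifnot(is.character(path), length(path) == 1L)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    load_fragments_bam(path, min_mapq)
  } else {
    load_fragments_bed(path)
  }
}

load_fragments_bed <- function(path) {
  df <- read_bed(path, min_fields = 3L)
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "+")
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$name, score = df$score, strand = strand,
                    s1 = ifelse(strand == "+", df$start, df$end),
                    e2 = ifelse(strand == "+", df$end, df$start),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- 0L
  out
}

load_fragments_bam <- function(path, min_mapq = 0L) {
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isNotPassingQualityControls = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = "mapq")
  gap <- GenomicAlignments::readGAlignmentPairs(path, param = param,
                                                use.names = TRUE)
  total_records <- Rsamtools::countBam(path)$records
  first <- GenomicAlignments::first(gap)
  last <- GenomicAlignments::last(gap)
  keep <- rep(TRUE, length(gap))
  if (min_mapq > 0L) {
    mq1 <- S4Vectors::mcols(first)$mapq
    mq2 <- S4Vectors::mcols(last)$mapq
    keep <- !is.na(mq1) & !is.na(mq2) & mq1 >= min_mapq & mq2 >= min_mapq
  }
  first <- first[keep]
  last <- last[keep]
  # 0-based boundaries: left = start - 1, right = end
  l1 <- GenomicAlignments::start(first) - 1L; r1 <- GenomicAlignments::end(first)
  l2 <- GenomicAlignments::start(last) - 1L;  r2 <- GenomicAlignments::end(last)
  str1 <- as.character(GenomicAlignments::strand(first))
  str2 <- as.character(GenomicAlignments::strand(last))
  s1 <- ifelse(str1 == "-", r1, l1)   # 5' boundary of R1
  e2 <- ifelse(str2 == "-", r2, l2)   # 5' boundary of R2
  out <- data.frame(chrom = as.character(GenomicAlignments::seqnames(first)),
                    start = pmin(l1, l2), end = pmax(r1, r2),
                    name = names(gap) %||% sprintf("pair_%d", seq_along(first)),
                    score = 0, strand = str1, s1 = s1, e2 = e2,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- total_records - 2L * nrow(out)
  out
}

validate_fragments <- function(df) {
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("fragment table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (any(df$end <= df$start)) stopf("fragments must satisfy start < end")
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$s1)) df$s1 <- ifelse(df$strand == "+", df$start, df$end)
  if (is.null(df$e2)) df$e2 <- ifelse(df$strand == "+", df$end, df$start)
  if (is.null(df$name)) df$name <- sprintf("frag_%06d", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- 0
  df
}

#' Split fragments into factor-scale and nucleosome-scale fractions
#'
#' CUT&RUN fragments at or under ~120 bp reflect direct transcription-factor
#' protection, longer ones nucleosomal protection. The boundary value goes
#' into the small fraction. Use `threshold = Inf` to keep all sizes in the
#' small fraction (disabled fractionation).
#'
#' @param fragments fragment data.frame from [load_fragments()]
#' @param threshold size boundary in bp (default 120)
#' @return list with `small` (length <= threshold) and `large` data.frames
#' @export
fractionate <- function(fragments, threshold = 120) {
  len <- fragments$end - fragments$start
  list(small = fragments[len <= threshold, , drop = FALSE],
       large = fragments[len > threshold, , drop = FALSE])
}

dup_key <- function(fragments) {
  paste(fragments$chrom, fragments$s1, fragments$e2, fragments$strand,
        sep = ":")
}

#' Read-pair duplication rate
#'
#' Pairs sharing the first mate's start and the second mate's end (plus
#' chromosome and R1 strand) are duplicates; the rate is
#' `(total - distinct) / total`, 0 for empty input.
#'
#' @param fragments fragment data.frame
#' @return proportion in `[0, 1]`
#' @export
duplication_rate <- function(fragments) {
  n <- nrow(fragments)
  if (n == 0L) return(0)
  (n - length(unique(dup_key(fragments)))) / n
}

#' Flag or remove duplicate fragments
#'
#' The pipeline default is to retain duplicates (stereotyped nuclease
#' cleavage and short fragments make identical pairs from distinct cells
#' likely); `remove = TRUE` keeps the first representative of each
#' (chrom, s1, e2, strand) group.
#'
#' @param fragments fragment data.frame
#' @param remove drop duplicates instead of flagging (default FALSE)
#' @return data.frame with a logical `duplicate` column (first occurrence is
#'   FALSE); rows removed when `remove = TRUE`
#' @export
mark_duplicates <- function(fragments, remove = FALSE) {
  if (nrow(fragments) == 0L) {
    fragments$duplicate <- logical(0)
    return(fragments)
  }
  fragments$duplicate <- duplicated(dup_key(fragments))
  if (remove) fragments[!fragments$duplicate, , drop = FALSE] else fragments
}
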