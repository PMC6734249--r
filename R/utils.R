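#' @importFrom stats rnbinom runif dnbinom dpois qlogis plogis lm coef nls
#'   predict setNames
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(exp(a) + exp(b)) for equal-length vectors
#' @noRd
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Read a BED-like file (first 3-6 columns used, extras ignored)
#'
#' Accepts plain BED3/BED6 and MACS2 narrowPeak (columns beyond 6 ignored).
#' Coordinates are kept 0-based half-open as stored in the file.
#'
#' @param path file path
#' @param min_fields minimum number of tab fields required per line
#' @return data.frame with chrom, start, end and, when present, name, score,
#'   strand
#' @export
read_bed <- function(path, min_fields = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stopf("malformed BED line %d in '%s': expected >= %d fields, found %d",
          bad[1], path, min_fields, nf[bad[1]])
  }
  col <- function(i, default = NA) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else as.character(default),
           character(1))
  }
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    stopf("malformed BED line %d in '%s': bad interval '%s'",
          bad[1], path, lines[bad[1]])
  }
  df <- data.frame(chrom = col(1), start = start, end = end,
                   name = col(4, "."),
                   score = suppressWarnings(as.numeric(col(5, "0"))),
                   strand = col(6, "*"),
                   stringsAsFactors = FALSE)
  df$score[is.na(df$score)] <- 0
  df
}

write_bed <- function(df, path, cols = c("chrom", "start", "end", "name",
                                         "score", "strand")) {
  cols <- intersect(cols, names(df))
  write.table(df[, cols, drop = FALSE], path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' GRanges view of 0-based half-open intervals
#' @noRd
as_gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L,
                                                 end = end0))
}
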