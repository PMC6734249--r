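#' Filter motif sites to clean peaks
#'
#' Removes peaks on excluded chromosomes (mitochondrial by default) or
#' overlapping the blacklist, then keeps motif sites overlapping at least
#' 1 bp of a retained peak (`contained = TRUE` demands full containment
#' instead).
#'
#' @param sites motif-site data.frame (BED6-style, 0-based half-open)
#' @param peaks peak data.frame (BED3+; narrowPeak columns beyond 3 ignored)
#' @param blacklist optional blacklist data.frame (BED3)
#' @param drop_chroms chromosome names whose peaks are discarded
#'   (default chrM/MT)
#' @param contained require the full motif interval inside a peak
#' @return the retained subset of `sites` (row order preserved)
#' @export
filter_sites <- function(sites, peaks, blacklist = NULL,
                         drop_chroms = c("chrM", "MT"), contained = FALSE) {
  if (nrow(sites) == 0L || nrow(peaks) == 0L) {
    return(sites[integer(0), , drop = FALSE])
  }
  keep_peaks <- !(peaks$chrom %in% drop_chroms)
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      as_gr(peaks$chrom, peaks$start, peaks$end),
      as_gr(blacklist$chrom, blacklist$start, blacklist$end))
    keep_peaks[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  peaks <- peaks[keep_peaks, , drop = FALSE]
  if (nrow(peaks) == 0L) return(sites[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(
    as_gr(sites$chrom, sites$start, sites$end),
    as_gr(peaks$chrom, peaks$start, peaks$end),
    type = if (contained) "within" else "any")
  sites[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Call direct binding sites
#'
#' A site is a direct binding site when (1) its motif is primary, (2) it
#' lies in a retained peak (enforced upstream by [filter_sites()]), and
#' (3) its binding log-odds strictly exceeds the threshold. Output is
#' rank-ordered by descending log-odds (ties broken by coordinate).
#'
#' @param scores data.frame from [score_sites()] (site_id, log_odds, ...)
#' @param sites the peak-filtered motif sites the calls are restricted to
#' @param primary logical flag from the symmetry analysis: is the motif
#'   primary?
#' @param threshold log-odds cutoff, strict (default 5)
#' @return data.frame of the filtered sites with log_odds, posterior and a
#'   logical `called` column, sorted by descending log_odds
#' @export
call_direct_binding <- function(scores, sites, primary, threshold = 5) {
  if (is.null(sites$site_id)) stopf("sites need a site_id column")
  idx <- match(sites$site_id, scores$site_id)
  if (anyNA(idx)) {
    stopf("no score for site_id '%s'", sites$site_id[which(is.na(idx))[1]])
  }
  out <- sites
  out$log_odds <- scores$log_odds[idx]
  out$posterior <- scores$posterior[idx]
  out$called <- isTRUE(primary) & out$log_odds > threshold
  ord <- order(-out$log_odds, out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write binding calls as BED6+ (log-odds in column 7) and a TSV report
#' @param calls data.frame from [call_direct_binding()]
#' @param prefix output prefix; writes `<prefix>.bed` (called sites only)
#'   and `<prefix>.tsv` (all scored sites)
#' @return invisibly, the two paths
#' @export
write_binding_calls <- function(calls, prefix) {
  bed <- calls[calls$called, , drop = FALSE]
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  write.table(bed[, c("chrom", "start", "end", "site_id", "score", "strand",
                      "log_odds")],
              bed_path, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  write_tsv(calls, tsv_path)
  invisible(c(bed_path, tsv_path))
}
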