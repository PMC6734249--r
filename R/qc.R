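#' Exact fragment-size histogram
#'
#' Fragment size is the distance between the outer start and end positions
#' of a read pair. The protocol enriches short fragments, so the mass at or
#' under 120 bp is reported alongside the histogram.
#'
#' @param fragments fragment data.frame
#' @return list with `counts` (named integer vector, names = lengths in bp)
#'   and `le120_fraction` (NA for empty input)
#' @export
fragment_size_histogram <- function(fragments) {
  len <- fragments$end - fragments$start
  if (length(len) == 0L) {
    return(list(counts = integer(0), le120_fraction = NA_real_))
  }
  t <- table(len)
  list(counts = setNames(as.integer(t), names(t)),
       le120_fraction = mean(len <= 120))
}

qc_default_thresholds <- function() {
  list(adapter_loss_pct_max = 15,       # reads removed by trimming
       library_size_min = 1e7,          # read pairs
       duplication_pct_max = 15,
       alignment_pct_min = 90,          # inclusive: 90.0 passes
       min_peaks = NA_real_)            # factor-dependent; no default
}

flag_metric <- function(value, ok) {
  if (is.na(value)) "not-available" else if (ok) "pass" else "warn"
}

#' Compute the quality-control report
#'
#' Assembles the standard CUT&RUN quality metrics -- fragment size
#' distribution, adapter content (reads lost to trimming), library size,
#' read duplication rate, concordant alignment percentage, peak count, and
#' enrichment of the expected motif (operationalised as the fraction of
#' peaks containing at least one motif site). Each metric gets a pass/warn
#' flag at the stricter end of the accepted field ranges; missing inputs
#' yield "not-available", never an error. Deliberately, no single overall
#' verdict is emitted.
#'
#' @param trim_counters list from [trim_fastq_pair()] (or NULL)
#' @param alignment_summary list with `total_pairs` and `concordant_pairs`
#'   (alignment is external; supply the aligner's summary), or NULL
#' @param fragments fragment data.frame, or NULL
#' @param peaks peak data.frame, or NULL
#' @param motif_sites motif-site data.frame, or NULL
#' @param thresholds overrides for `qc_default_thresholds()`
#' @return a `QCReport` list: metrics plus per-metric `flags`
#' @export
compute_qc <- function(trim_counters = NULL, alignment_summary = NULL,
                       fragments = NULL, peaks = NULL, motif_sites = NULL,
                       thresholds = list()) {
  th <- utils::modifyList(qc_default_thresholds(), thresholds)
  adapter_loss_pct <- if (!is.null(trim_counters) && trim_counters$pairs_in > 0)
    100 * trim_counters$pairs_dropped / trim_counters$pairs_in else NA_real_
  library_size <- if (!is.null(trim_counters)) trim_counters$pairs_in
    else if (!is.null(alignment_summary)) alignment_summary$total_pairs
    else NA_real_
  alignment_pct <- if (!is.null(alignment_summary) &&
                       (alignment_summary$total_pairs %||% 0) > 0)
    100 * alignment_summary$concordant_pairs / alignment_summary$total_pairs
    else NA_real_
  dup_pct <- if (!is.null(fragments)) 100 * duplication_rate(fragments)
    else NA_real_
  hist <- if (!is.null(fragments)) fragment_size_histogram(fragments)
    else list(counts = integer(0), le120_fraction = NA_real_)
  n_peaks <- if (!is.null(peaks)) nrow(peaks) else NA_real_
  motif_enrichment <- if (!is.null(peaks) && !is.null(motif_sites) &&
                          nrow(peaks) > 0) {
    hits <- GenomicRanges::findOverlaps(
      as_gr(peaks$chrom, peaks$start, peaks$end),
      as_gr(motif_sites$chrom, motif_sites$start, motif_sites$end))
    length(unique(S4Vectors::queryHits(hits))) / nrow(peaks)
  } else NA_real_
  flags <- list(
    adapter_content = flag_metric(adapter_loss_pct,
                                  adapter_loss_pct <= th$adapter_loss_pct_max),
    library_size = flag_metric(library_size,
                               library_size >= th$library_size_min),
    duplication = flag_metric(dup_pct, dup_pct <= th$duplication_pct_max),
    alignment = flag_metric(alignment_pct,
                            alignment_pct >= th$alignment_pct_min),
    n_peaks = if (is.na(th$min_peaks)) "not-assessed" else
      flag_metric(n_peaks, n_peaks >= th$min_peaks))
  structure(list(fragment_size_histogram = hist$counts,
                 le120_fraction = hist$le120_fraction,
                 adapter_content_pct = adapter_loss_pct,
                 library_size = library_size,
                 duplication_rate_pct = dup_pct,
                 alignment_pct = alignment_pct,
                 n_peaks = n_peaks,
                 expected_motif_enrichment = motif_enrichment,
                 thresholds = th, flags = flags),
            class = "QCReport")
}

#' Write a QCReport as JSON (lossless round-trip) plus a text summary
#' @param report a `QCReport`
#' @param path JSON output path; a `.txt` summary is written alongside
#' @return invisibly, the JSON path
#' @export
write_qc_report <- function(report, path) {
  x <- unclass(report)
  # named list keeps the histogram's length keys in the JSON object
  x$fragment_size_histogram <- as.list(x$fragment_size_histogram)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  txt <- sub("\\.json$", ".txt", path)
  fmt <- function(x, d = 2) if (is.na(x)) "NA" else formatC(x, digits = d,
                                                            format = "f")
  lines <- c(
    "CUT&RUN quality control summary",
    sprintf("  adapter content (reads lost to trimming): %s%% [%s]",
            fmt(report$adapter_content_pct), report$flags$adapter_content),
    sprintf("  library size (read pairs): %s [%s]",
            fmt(report$library_size, 0), report$flags$library_size),
    sprintf("  duplication rate: %s%% [%s]",
            fmt(report$duplication_rate_pct), report$flags$duplication),
    sprintf("  concordant alignment: %s%% [%s]",
            fmt(report$alignment_pct), report$flags$alignment),
    sprintf("  peaks: %s [%s]", fmt(report$n_peaks, 0),
            report$flags$n_peaks),
    sprintf("  fraction of peaks with expected motif: %s",
            fmt(report$expected_motif_enrichment, 3)),
    sprintf("  fragments <= 120 bp: %s",
            fmt(report$le120_fraction, 3)),
    "  (no single overall score; judge metrics jointly)")
  writeLines(lines, txt)
  invisible(path)
}

#' Read a QCReport back from JSON
#' @param path JSON written by [write_qc_report()]
#' @return a `QCReport`
#' @export
read_qc_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fragment_size_histogram <- setNames(
    as.integer(x$fragment_size_histogram),
    names(x$fragment_size_histogram))
  for (f in c("adapter_content_pct", "library_size", "duplication_rate_pct",
              "alignment_pct", "n_peaks", "expected_motif_enrichment",
              "le120_fraction")) {
    x[[f]] <- if (is.null(x[[f]])) NA_real_ else as.numeric(x[[f]])
  }
  structure(x, class = "QCReport")
}
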