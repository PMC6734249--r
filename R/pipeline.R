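#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration; [run_pipeline()] merges
#' user settings over these. Paths are NULL until supplied.
#'
#' @return named list of settings
#' @export
default_config <- function() {
  list(
    fastq1 = NULL, fastq2 = NULL,       # optional trimming stage inputs
    fragments = NULL,                   # fragment BED or paired-end BAM
    sites = NULL,                       # motif occurrences, BED6
    peaks = NULL,                       # peak BED / narrowPeak
    blacklist = NULL,
    alignment_summary = NULL,           # JSON: total_pairs, concordant_pairs
    output_dir = "cutfoot_out",
    adapter = "AGATCGGAAGAGC",
    max_overhang = 6L,
    min_read_length = 25L,
    flank = 100L,
    size_threshold = 120,               # Inf disables fractionation
    use_fraction = "small",             # small | large | all
    forward_offset = 0L,
    reverse_offset = 0L,
    pseudocount = 1,
    max_iter = 200L,
    tol = 1e-6,
    log_odds_threshold = 5,
    primary_fss_min = 0.3,
    rate_gap_max = 0.2,
    drop_chroms = c("chrM", "MT"),
    remove_duplicates = FALSE,
    min_mapq = 0L,
    seed = 1L,
    log_level = "info")
}

load_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  for (field in c("flank", "max_overhang", "min_read_length",
                  "size_threshold", "pseudocount", "max_iter", "tol",
                  "log_odds_threshold", "primary_fss_min", "rate_gap_max",
                  "forward_offset", "reverse_offset", "min_mapq", "seed")) {
    # JSON round-trips may deliver numbers as strings ("Inf" in particular)
    cfg[[field]] <- suppressWarnings(as.numeric(cfg[[field]]))
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  check_num <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min) {
      stopf("config field '%s' must be a number >= %s (got %s)",
            field, min, paste(v, collapse = ","))
    }
  }
  check_num("flank"); check_num("max_overhang"); check_num("min_read_length")
  check_num("size_threshold"); check_num("pseudocount"); check_num("max_iter", 1)
  check_num("tol"); check_num("primary_fss_min"); check_num("rate_gap_max")
  if (!cfg$use_fraction %in% c("small", "large", "all")) {
    stopf("config field 'use_fraction' must be small, large or all")
  }
  for (field in c("fastq1", "fastq2", "fragments", "sites", "peaks",
                  "blacklist", "alignment_summary")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stopf("config field '%s': file not found: %s", field, p)
    }
  }
  invisible(cfg)
}

plog <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[cutfoot %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full footprinting pipeline
#'
#' Chains trimming (when FASTQ inputs are given), fragment loading, size
#' fractionation, cut-matrix construction, mixture-model fitting, footprint
#' symmetry scoring, direct-binding-site calling and QC, writing every
#' stage's artifact under `output_dir` together with the resolved
#' configuration. The pipeline itself is deterministic: identical config
#' and inputs give identical outputs.
#'
#' @param config a config list or path to a JSON config file; see
#'   [default_config()] for fields and defaults
#' @return invisibly, a list with the in-memory stage results and an
#'   `artifacts` vector of written paths
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$fragments)) {
    stopf("config must point 'fragments' at a fragment BED or BAM file")
  }
  if (is.null(cfg$sites)) stopf("config must point 'sites' at a motif BED6")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  art <- c(config = file.path(cfg$output_dir, "config.resolved.json"))
  jsonlite::write_json(cfg[order(names(cfg))], art["config"],
                       auto_unbox = TRUE, digits = NA, null = "null")

  trim_counters <- NULL
  if (!is.null(cfg$fastq1)) {
    plog(cfg, "trimming %s / %s", cfg$fastq1, cfg$fastq2)
    art["fastq1"] <- file.path(cfg$output_dir, "trimmed_R1.fastq.gz")
    art["fastq2"] <- file.path(cfg$output_dir, "trimmed_R2.fastq.gz")
    trim_counters <- trim_fastq_pair(cfg$fastq1, cfg$fastq2,
                                     art["fastq1"], art["fastq2"],
                                     adapter = cfg$adapter,
                                     max_overhang = cfg$max_overhang,
                                     min_len = cfg$min_read_length)
    art["trim_summary"] <- file.path(cfg$output_dir, "trim_summary.json")
    jsonlite::write_json(trim_counters[c("pairs_in", "pairs_out",
                                         "pairs_dropped", "reads_trimmed",
                                         "bases_trimmed")],
                         art["trim_summary"], auto_unbox = TRUE, digits = NA)
  }

  plog(cfg, "loading fragments from %s", cfg$fragments)
  fragments <- load_fragments(cfg$fragments, min_mapq = cfg$min_mapq)
  if (cfg$remove_duplicates) fragments <- mark_duplicates(fragments,
                                                          remove = TRUE)
  frac <- fractionate(fragments, cfg$size_threshold)
  used <- switch(cfg$use_fraction, small = frac$small, large = frac$large,
                 all = fragments)
  plog(cfg, "%d fragments (%d small / %d large); using '%s'",
       nrow(fragments), nrow(frac$small), nrow(frac$large), cfg$use_fraction)
  art["fragments"] <- file.path(cfg$output_dir, "fragments.used.bed")
  write_bed(used, art["fragments"])

  sites <- read_bed(cfg$sites, min_fields = 6L)
  sites$site_id <- ifelse(sites$name == ".",
                          sprintf("site_%04d", seq_len(nrow(sites))),
                          sites$name)
  peaks <- if (!is.null(cfg$peaks)) read_bed(cfg$peaks) else NULL
  blacklist <- if (!is.null(cfg$blacklist)) read_bed(cfg$blacklist) else NULL
  filtered_sites <- if (!is.null(peaks)) {
    filter_sites(sites, peaks, blacklist, drop_chroms = cfg$drop_chroms)
  } else sites
  plog(cfg, "%d/%d motif sites retained after peak/blacklist filtering",
       nrow(filtered_sites), nrow(sites))

  plog(cfg, "building cut matrix (flank %g, offsets %g/%g)",
       cfg$flank, cfg$forward_offset, cfg$reverse_offset)
  cm <- build_cut_matrix(used, filtered_sites, flank = cfg$flank,
                         forward_offset = cfg$forward_offset,
                         reverse_offset = cfg$reverse_offset)
  art["cut_matrix_forward"] <- file.path(cfg$output_dir,
                                         "cut_matrix.forward.tsv")
  art["cut_matrix_reverse"] <- file.path(cfg$output_dir,
                                         "cut_matrix.reverse.tsv")
  write_cut_matrix(cm, file.path(cfg$output_dir, "cut_matrix"))
  agg <- aggregate_profile(cm)
  art["aggregate"] <- file.path(cfg$output_dir, "aggregate_profile.tsv")
  write_tsv(data.frame(position = seq_len(cm$W), forward = agg$forward,
                       reverse = agg$reverse, combined = agg$combined),
            art["aggregate"])

  plog(cfg, "fitting footprint mixture model")
  model <- fit_footprint_model(cm, pseudocount = cfg$pseudocount,
                               max_iter = cfg$max_iter, tol = cfg$tol)
  art["model"] <- file.path(cfg$output_dir, "footprint_model.json")
  write_model_json(model, art["model"])
  scores <- score_sites(model, cm)
  art["scores"] <- file.path(cfg$output_dir, "site_scores.tsv")
  write_tsv(scores, art["scores"])

  plog(cfg, "footprint symmetry analysis")
  fss <- footprint_symmetry_score(model_profile(model),
                                  primary_fss_min = cfg$primary_fss_min,
                                  rate_gap_max = cfg$rate_gap_max)
  art["fss"] <- file.path(cfg$output_dir, "fss.tsv")
  write_tsv(data.frame(motif_id = "motif_1",
                       B_left = fss$fit_left$B, B_right = fss$fit_right$B,
                       r2_left = fss$fit_left$r2, r2_right = fss$fit_right$r2,
                       FSS = fss$fss, rate_gap = fss$rate_gap,
                       is_primary = fss$is_primary), art["fss"])

  plog(cfg, "calling direct binding sites (log-odds > %g, primary = %s)",
       cfg$log_odds_threshold, fss$is_primary)
  calls <- call_direct_binding(scores, filtered_sites, fss$is_primary,
                               threshold = cfg$log_odds_threshold)
  art["calls_bed"] <- file.path(cfg$output_dir, "binding_calls.bed")
  art["calls_tsv"] <- file.path(cfg$output_dir, "binding_calls.tsv")
  write_binding_calls(calls, file.path(cfg$output_dir, "binding_calls"))

  alignment_summary <- if (!is.null(cfg$alignment_summary)) {
    jsonlite::read_json(cfg$alignment_summary, simplifyVector = TRUE)
  } else NULL
  qc <- compute_qc(trim_counters = trim_counters,
                   alignment_summary = alignment_summary,
                   fragments = fragments, peaks = peaks, motif_sites = sites)
  art["qc"] <- file.path(cfg$output_dir, "qc.json")
  write_qc_report(qc, art["qc"])
  plog(cfg, "done; %d/%d sites called", sum(calls$called), nrow(calls))

  invisible(list(config = cfg, trim_counters = trim_counters,
                 fragments = fragments, cut_matrix = cm, model = model,
                 scores = scores, fss = fss, calls = calls, qc = qc,
                 artifacts = art))
}
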