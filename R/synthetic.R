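#' Default center-depleted cut-probability template
#'
#' Builds the bound-site cut profile used by the simulator: cut probability
#' rises exponentially across each flank toward the motif edges while the
#' motif core is a low plateau (the protein protects the core from the
#' nuclease). The returned vector has length `motif_length + 2 * flank` and
#' sums to 1.
#'
#' @param motif_length motif width in bp
#' @param flank flanking bp on each side of the motif (default 100)
#' @param rise per-position exponential rate of the flank arms (default 0.03;
#'   at flank = 100 the motif-proximal position is ~ e^3 = 20x the window edge)
#' @param core_depletion motif-core plateau height relative to the flank peak
#'   (default 0.1)
#' @return numeric probability vector of length `motif_length + 2*flank`
#' @export
lambda_template <- function(motif_length, flank = 100L, rise = 0.03,
                            core_depletion = 0.1) {
  stopifnot(is_count(motif_length), motif_length > 0, is_count(flank),
            flank >= 2)
  left <- exp(rise * (seq_len(flank) - 1))
  peak <- max(left)
  core <- rep(core_depletion * peak, motif_length)
  lam <- c(left, core, rev(left))
  lam / sum(lam)
}

#' Parameters of the synthetic CUT&RUN world
#'
#' Collects and validates every knob of the fragment/FASTQ simulator. The
#' defaults describe a plausible transcription-factor CUT&RUN experiment:
#' mostly short fragments, tens of reads per bound motif site, a modest PCR
#' duplicate fraction, and 42-bp reads (a common CUT&RUN read length) subject
#' to adapter read-through for sub-read-length inserts.
#'
#' @param n_bound_sites,n_unbound_sites number of bound / unbound motif sites
#' @param flank bp of flanking sequence on each side of the motif window
#' @param motif_length motif width in bp
#' @param lambda_truth probability vector over the `motif_length + 2*flank`
#'   oriented window positions for bound sites (default: [lambda_template()])
#' @param nb_mean_bound,nb_mean_unbound negative-binomial mean fragment ends
#'   per bound / unbound site
#' @param nb_size_bound,nb_size_unbound negative-binomial size (dispersion)
#' @param frag_len_range two-element bp range fragments are drawn from
#' @param duplicate_fraction fraction of emitted fragments that are exact
#'   (s1, e2) copies of another fragment at the same site, in [0, 1)
#' @param adapter_seq adapter that appears as 3' read-through in short inserts
#' @param read_length sequencing read length in bp
#' @param seed integer seed governing all randomness
#' @return a validated `SimulationParams` list
#' @export
simulation_params <- function(n_bound_sites = 300L, n_unbound_sites = 200L,
                              flank = 100L, motif_length = 6L,
                              lambda_truth = NULL,
                              nb_mean_bound = 40, nb_mean_unbound = 8,
                              nb_size_bound = 5, nb_size_unbound = 2,
                              frag_len_range = c(250L, 400L),
                              duplicate_fraction = 0.1,
                              adapter_seq = "AGATCGGAAGAGC",
                              read_length = 42L, seed = 1L) {
  if (is.null(lambda_truth)) {
    lambda_truth <- lambda_template(motif_length, flank)
  }
  W <- motif_length + 2L * flank
  if (length(lambda_truth) != W) {
    stopf("lambda_truth has length %d but motif_length + 2*flank = %d",
          length(lambda_truth), W)
  }
  if (any(lambda_truth < 0) || abs(sum(lambda_truth) - 1) > 1e-9) {
    stopf("lambda_truth must be non-negative and sum to 1")
  }
  stopifnot(is_count(n_bound_sites), is_count(n_unbound_sites),
            is_count(flank), is_count(motif_length), motif_length > 0,
            is_count(read_length), read_length > 0,
            length(frag_len_range) == 2, frag_len_range[1] > 0,
            frag_len_range[1] <= frag_len_range[2],
            duplicate_fraction >= 0, duplicate_fraction < 1,
            nchar(adapter_seq) > 0,
            nb_mean_bound > 0, nb_mean_unbound > 0,
            nb_size_bound > 0, nb_size_unbound > 0)
  p <- list(n_bound_sites = as.integer(n_bound_sites),
            n_unbound_sites = as.integer(n_unbound_sites),
            flank = as.integer(flank), motif_length = as.integer(motif_length),
            lambda_truth = lambda_truth,
            nb_mean_bound = nb_mean_bound, nb_mean_unbound = nb_mean_unbound,
            nb_size_bound = nb_size_bound, nb_size_unbound = nb_size_unbound,
            frag_len_range = as.integer(frag_len_range),
            duplicate_fraction = duplicate_fraction,
            adapter_seq = adapter_seq, read_length = as.integer(read_length),
            seed = as.integer(seed))
  class(p) <- "SimulationParams"
  p
}

#' Simulate stranded CUT&RUN fragments around motif sites
#'
#' Places `n_bound + n_unbound` motif sites on a synthetic contig, draws a
#' negative-binomial number of fragment ends per site, positions bound-site
#' ends according to `lambda_truth` over the oriented window (uniform for
#' unbound sites), and emits each end as one boundary of a stranded fragment.
#' Minus-strand sites are emitted mirror-imaged so that orientation flipping
#' in [build_cut_matrix()] recovers the same profile. The partner end of each
#' fragment is forced outside the site window (fragment lengths are extended
#' when needed) so that the number of in-window ends per site equals its
#' drawn read total exactly.
#'
#' @param params a [simulation_params()] object
#' @return list with `fragments` (data.frame: chrom, start, end, name, score,
#'   strand, s1, e2), `sites` (data.frame BED6-style with site_id), `peaks`
#'   (data.frame BED3 covering each site window), and `truth` (data.frame:
#'   site_id, bound 0/1, n_ends)
#' @export
simulate_fragments <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  W <- params$motif_length + 2L * params$flank
  n_sites <- params$n_bound_sites + params$n_unbound_sites
  if (n_sites == 0L) {
    empty <- empty_fragments()
    return(list(fragments = empty, sites = empty_sites(),
                peaks = empty[, c("chrom", "start", "end")],
                truth = data.frame(site_id = character(), bound = integer(),
                                   n_ends = integer())))
  }
  spacing <- 2000L + W
  chrom <- "chrSim1"
  motif_start <- 1000L + spacing * (seq_len(n_sites) - 1L)
  strand <- rep(c("+", "-"), length.out = n_sites)
  bound <- sample(rep(c(1L, 0L), c(params$n_bound_sites,
                                   params$n_unbound_sites)))
  sites <- data.frame(chrom = chrom, start = motif_start,
                      end = motif_start + params$motif_length,
                      name = sprintf("site_%04d", seq_len(n_sites)),
                      score = 0, strand = strand, stringsAsFactors = FALSE)
  sites$site_id <- sites$name

  mu <- ifelse(bound == 1L, params$nb_mean_bound, params$nb_mean_unbound)
  size <- ifelse(bound == 1L, params$nb_size_bound, params$nb_size_unbound)
  n_ends <- rnbinom(n_sites, mu = mu, size = size)

  frags <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    R <- n_ends[i]
    if (R == 0L) next
    prob <- if (bound[i] == 1L) params$lambda_truth else rep(1 / W, W)
    col0 <- sample.int(W, R, replace = TRUE, prob = prob) - 1L # oriented, 0-based
    orient_fwd <- runif(R) < 0.5
    ws <- sites$start[i] - params$flank          # window start boundary (0-based)
    we <- sites$end[i] + params$flank            # window end boundary
    if (strand[i] == "+") {
      b <- ws + col0
      is_s1 <- orient_fwd                        # forward cut <-> s1 on + sites
    } else {
      b <- ws + (W - 1L - col0)                  # mirror image
      is_s1 <- !orient_fwd                       # labels swap on - sites
    }
    len <- sample(seq(params$frag_len_range[1], params$frag_len_range[2]),
                  R, replace = TRUE)
    # keep the partner end strictly outside [ws, we)
    len <- ifelse(is_s1, pmax(len, we - b), pmax(len, b - ws + 1L))
    n_dup <- floor(params$duplicate_fraction * R)
    if (n_dup > 0L && R - n_dup >= 1L) {
      # exact (s1, e2) copies of earlier fragments at this site
      src <- sample.int(R - n_dup, n_dup, replace = TRUE)
      tail_idx <- (R - n_dup + 1L):R
      b[tail_idx] <- b[src]
      is_s1[tail_idx] <- is_s1[src]
      len[tail_idx] <- len[src]
    }
    start <- ifelse(is_s1, b, b - len)
    end <- ifelse(is_s1, b + len, b)
    frags[[i]] <- data.frame(chrom = chrom, start = start, end = end,
                             s1 = ifelse(is_s1, b, start),
                             e2 = ifelse(is_s1, end, b),
                             stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frags)
  if (is.null(frags)) frags <- empty_fragments()[, c("chrom", "start", "end",
                                                     "s1", "e2")]
  fragments <- data.frame(chrom = frags$chrom, start = frags$start,
                          end = frags$end,
                          name = sprintf("frag_%06d", seq_len(nrow(frags))),
                          score = 0, strand = "+",
                          s1 = frags$s1, e2 = frags$e2,
                          stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = sites$chrom,
                      start = pmax(0L, sites$start - params$flank - 20L),
                      end = sites$end + params$flank + 20L,
                      stringsAsFactors = FALSE)
  truth <- data.frame(site_id = sites$site_id, bound = bound,
                      n_ends = n_ends, stringsAsFactors = FALSE)
  list(fragments = fragments, sites = sites, peaks = peaks, truth = truth)
}

empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             s1 = integer(), e2 = integer(), stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             site_id = character(), stringsAsFactors = FALSE)
}

#' Simulate paired FASTQ reads with adapter read-through
#'
#' Generates read pairs from random inserts whose lengths are drawn from
#' `params$frag_len_range`. When an insert is shorter than the read length,
#' the 3' end of both mates runs into the adapter, so the read carries
#' `read_length - insert_length` adapter bases. Insert bases are drawn from
#' the three nucleotides other than the adapter's first base, which makes the
#' true overhang exactly recoverable by suffix matching (adapter-free
#' inserts); mates are generated independently (no sequence-level realism).
#'
#' @param params a [simulation_params()] object
#' @param n_pairs number of read pairs
#' @return list with `reads1`, `reads2` (data.frames: name, seq, qual) and
#'   `truth` (data.frame: name, insert_len, overhang where overhang is
#'   `read_length - insert_len` clipped to `[0, read_length)`)
#' @export
simulate_fastq <- function(params, n_pairs) {
  stopifnot(inherits(params, "SimulationParams"), is_count(n_pairs))
  set.seed(params$seed + 1L)
  L <- params$read_length
  adapter <- params$adapter_seq
  alphabet <- setdiff(c("A", "C", "G", "T"), substr(adapter, 1L, 1L))
  insert_len <- sample(seq(params$frag_len_range[1], params$frag_len_range[2]),
                       n_pairs, replace = TRUE)
  overhang <- pmin(pmax(L - insert_len, 0L), L - 1L)
  make_read <- function(ins_len) {
    n_ins <- min(ins_len, L)
    ins <- paste(sample(alphabet, n_ins, replace = TRUE), collapse = "")
    if (n_ins >= L) return(ins)
    # fill with adapter, recycling it if the overhang exceeds its length
    fill <- strsplit(adapter, "")[[1]]
    fill <- rep(fill, length.out = L - n_ins)
    paste0(ins, paste(fill, collapse = ""))
  }
  seq1 <- vapply(insert_len, make_read, character(1))
  seq2 <- vapply(insert_len, make_read, character(1))
  qual <- strrep("I", nchar(seq1))
  name <- sprintf("read_%06d", seq_len(n_pairs))
  list(reads1 = data.frame(name = name, seq = seq1, qual = qual,
                           stringsAsFactors = FALSE),
       reads2 = data.frame(name = name, seq = seq2, qual = qual,
                           stringsAsFactors = FALSE),
       truth = data.frame(name = name, insert_len = insert_len,
                          overhang = overhang, stringsAsFactors = FALSE))
}

#' Write simulator outputs to disk
#'
#' Fragments go to BED6 (strand column is the R1 strand) with s1/e2 implied
#' by the strand convention, sites to BED6, peaks to BED3, truth to TSV, and
#' reads to paired gzip FASTQ.
#'
#' @param sim result of [simulate_fragments()]
#' @param dir output directory (created if needed)
#' @return invisibly, named vector of written paths
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fragments = file.path(dir, "fragments.bed"),
             sites = file.path(dir, "sites.bed"),
             peaks = file.path(dir, "peaks.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_bed(sim$fragments, paths["fragments"])
  write_bed(sim$sites, paths["sites"])
  write_bed(sim$peaks, paths["peaks"], cols = c("chrom", "start", "end"))
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Write paired reads as gzip FASTQ
#' @param reads data.frame with name, seq, qual
#' @param path output path (gzip applied when it ends in .gz)
#' @return invisibly, the path
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$name, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  }
  invisible(path)
}

#' Read a (possibly gzip) FASTQ file into a data.frame
#' @param path FASTQ path
#' @return data.frame with name, seq, qual
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stopf("'%s' is not 4-line FASTQ (%d lines)", path, length(lines))
  }
  idx <- seq(1, length(lines), by = 4)
  data.frame(name = sub("^@", "", sub("[ /].*$", "", lines[idx])),
             seq = lines[idx + 1], qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}
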