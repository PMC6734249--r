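# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-base scans, direct products) and never call the code paths they check.

# ---- brute-force cut-matrix oracle -----------------------------------------

# Per-base scan over every site window and fragment end boundary, applying
# the orientation flip and strand-label swap by first principles.
brute_cut_matrix <- function(fragments, sites, flank,
                             forward_offset = 0, reverse_offset = 0) {
  width <- unique(sites$end - sites$start)
  W <- width + 2L * flank
  n <- nrow(sites)
  fwd <- matrix(0L, n, W)
  rev_ <- matrix(0L, n, W)
  for (i in seq_len(n)) {
    ws <- sites$start[i] - flank
    for (j in seq_len(nrow(fragments))) {
      if (fragments$chrom[j] != sites$chrom[i]) next
      ends <- list(list(b = fragments$s1[j] + forward_offset, fwd = TRUE),
                   list(b = fragments$e2[j] + reverse_offset, fwd = FALSE))
      for (e in ends) {
        col0 <- e$b - ws                       # 0-based genomic column
        if (col0 < 0 || col0 >= W) next
        is_fwd <- e$fwd
        if (sites$strand[i] == "-") {
          col0 <- W - 1L - col0
          is_fwd <- !is_fwd
        }
        if (is_fwd) fwd[i, col0 + 1L] <- fwd[i, col0 + 1L] + 1L
        else rev_[i, col0 + 1L] <- rev_[i, col0 + 1L] + 1L
      }
    }
  }
  list(forward = fwd, reverse = rev_)
}

random_toy_set <- function(seed, max_frags = 50L, max_sites = 5L) {
  set.seed(seed)
  n_f <- sample.int(max_frags, 1L)
  n_s <- sample.int(max_sites, 1L)
  width <- sample(4:12, 1L)
  flank <- sample(5:20, 1L)
  site_start <- sort(sample.int(500L, n_s))
  sites <- data.frame(chrom = "chrT", start = site_start,
                      end = site_start + width,
                      name = sprintf("s%d", seq_len(n_s)), score = 0,
                      strand = sample(c("+", "-"), n_s, replace = TRUE),
                      site_id = sprintf("s%d", seq_len(n_s)),
                      stringsAsFactors = FALSE)
  start <- sample.int(600L, n_f)
  len <- sample(5:80, n_f, replace = TRUE)
  strand <- sample(c("+", "-"), n_f, replace = TRUE)
  fragments <- data.frame(chrom = "chrT", start = start, end = start + len,
                          name = sprintf("f%d", seq_len(n_f)), score = 0,
                          strand = strand,
                          s1 = ifelse(strand == "+", start, start + len),
                          e2 = ifelse(strand == "+", start + len, start),
                          stringsAsFactors = FALSE)
  list(fragments = fragments, sites = sites, flank = flank)
}

# ---- trimming oracle -------------------------------------------------------

# Try every suffix length from longest to shortest; first exact match wins.
brute_trim <- function(seq, adapter, max_overhang = 6L) {
  n <- nchar(seq)
  for (k in seq(min(max_overhang, n), 1L)) {
    if (substr(seq, n - k + 1L, n) == substr(adapter, 1L, k)) return(k)
  }
  0L
}

# ---- toy SAM/BAM -----------------------------------------------------------

# Hand-built paired-end SAM (text) converted to BAM at test time. Each row of
# `pairs` gives 1-based alignment intervals [p1, p1e] for R1 and [p2, p2e]
# for R2 plus the strand of R1 ("+" = flags 99/147, "-" = flags 83/163).
write_toy_bam <- function(pairs,
                          dir = withr::local_tempdir(
                            .local_envir = parent.frame())) {
  sam <- file.path(dir, "toy.sam")
  lines <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrT\tLN:100000")
  recs <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    w1 <- p$p1e - p$p1 + 1L
    w2 <- p$p2e - p$p2 + 1L
    f1 <- if (p$r1_strand == "+") 99L else 83L
    f2 <- if (p$r1_strand == "+") 147L else 163L
    isize <- max(p$p1e, p$p2e) - min(p$p1, p$p2) + 1L
    recs[[length(recs) + 1L]] <- c(pos = p$p1, line = sprintf(
      "pair%d\t%d\tchrT\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
      i, f1, p$p1, w1, p$p2, isize, strrep("A", w1), strrep("I", w1)))
    recs[[length(recs) + 1L]] <- c(pos = p$p2, line = sprintf(
      "pair%d\t%d\tchrT\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
      i, f2, p$p2, w2, p$p1, -isize, strrep("A", w2), strrep("I", w2)))
  }
  ord <- order(vapply(recs, function(r) as.integer(r[["pos"]]), integer(1)))
  writeLines(c(lines, vapply(recs[ord], function(r) r[["line"]],
                             character(1))), sam)
  Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# ---- misc ------------------------------------------------------------------

auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

small_sim_params <- function(seed = 42L, ...) {
  simulation_params(n_bound_sites = 60L, n_unbound_sites = 40L,
                    nb_mean_bound = 40, nb_mean_unbound = 8, seed = seed, ...)
}
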