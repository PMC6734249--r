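#' Map one fragment's cut boundaries into a motif site's oriented window
#'
#' The nuclease leaves blunt ends, so the cut boundaries are the fragment's
#' own end boundaries with zero offset: `s1` is the forward-strand cut and
#' `e2` the reverse-strand cut for a plus-strand motif. For a minus-strand
#' motif the window is read right-to-left: column indices flip and the
#' strand labels swap (`s1` becomes a reverse cut, `e2` a forward cut).
#' Columns are 1-based here; column `i` counts cuts situated just before
#' oriented nucleotide `i` of the window. Offsets exist only for assay
#' variants whose enzyme leaves an overhang (e.g. Tn5 in ATAC-seq); CUT&RUN
#' uses `(0, 0)`.
#'
#' @param fragment one-row fragment data.frame (or list) with s1, e2
#' @param site one-row motif-site data.frame with start, end, strand
#' @param flank window flank in bp (default 100)
#' @param forward_offset,reverse_offset bp added to the s1 / e2 boundary
#'   before window mapping (default 0, CUT&RUN)
#' @return data.frame with columns `strand` ("forward"/"reverse") and
#'   `column`; zero rows when no boundary falls inside the window
#' @export
assign_cut_positions <- function(fragment, site, flank = 100L,
                                 forward_offset = 0L, reverse_offset = 0L) {
  W <- (site$end - site$start) + 2L * flank
  ws <- site$start - flank
  b <- c(fragment$s1 + forward_offset, fragment$e2 + reverse_offset)
  genomic_label <- c("forward", "reverse")
  col <- b - ws + 1L
  inside <- col >= 1L & col <= W
  col <- col[inside]
  label <- genomic_label[inside]
  if (identical(site$strand, "-")) {
    col <- W + 1L - col
    label <- ifelse(label == "forward", "reverse", "forward")
  }
  data.frame(strand = label, column = col, stringsAsFactors = FALSE)
}

#' Build the strand-specific, motif-oriented cut matrix
#'
#' Rows are motif sites (input order), columns the
#' `motif_length + 2*flank` oriented single-nucleotide positions; each cell
#' counts fragment-end boundaries mapping there by
#' [assign_cut_positions()]. One fragment end overlapping several site
#' windows contributes to every such row. All sites must share one motif
#' length.
#'
#' @param fragments fragment data.frame from [load_fragments()]
#' @param sites motif-site data.frame (BED6-style, 0-based half-open); a
#'   `site_id` column is added from `name` when absent
#' @param flank flank in bp on each side of the motif (default 100)
#' @param forward_offset,reverse_offset cut-site offsets in bp (default 0)
#' @return a `CutMatrix`: list with `sites`, `flank`, `motif_length`, `W`,
#'   and integer matrices `forward`, `reverse` of dim n_sites x W
#' @export
build_cut_matrix <- function(fragments, sites, flank = 100L,
                             forward_offset = 0L, reverse_offset = 0L) {
  stopifnot(is_count(flank))
  if (is.null(sites$site_id)) {
    sites$site_id <- if (!is.null(sites$name)) sites$name else
      sprintf("site_%04d", seq_len(nrow(sites)))
  }
  widths <- unique(sites$end - sites$start)
  if (length(widths) > 1L) {
    stopf("sites mix motif lengths (%s); one cut matrix needs one motif",
          paste(widths, collapse = ", "))
  }
  motif_length <- if (length(widths)) widths else 0L
  W <- motif_length + 2L * flank
  n_sites <- nrow(sites)
  fwd <- matrix(0L, n_sites, W)
  rev_ <- matrix(0L, n_sites, W)
  rownames(fwd) <- rownames(rev_) <- sites$site_id
  if (nrow(fragments) > 0L && n_sites > 0L) {
    windows <- as_gr(sites$chrom, sites$start - flank, sites$end + flank)
    # boundary b (0-based, inter-base) occupies 1-based position b + 1
    boundaries <- data.frame(
      chrom = rep(fragments$chrom, 2L),
      b = c(fragments$s1 + forward_offset, fragments$e2 + reverse_offset),
      genomic_fwd = rep(c(TRUE, FALSE), each = nrow(fragments)))
    pts <- GenomicRanges::GRanges(boundaries$chrom,
                                  IRanges::IRanges(boundaries$b + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(pts, windows)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ws <- sites$start[si] - flank
      col <- boundaries$b[qi] - ws + 1L
      fwd_label <- boundaries$genomic_fwd[qi]
      minus <- sites$strand[si] == "-"
      col[minus] <- W + 1L - col[minus]
      fwd_label[minus] <- !fwd_label[minus]
      # accumulate with matrix linear indexing
      lin_f <- (col[fwd_label] - 1L) * n_sites + si[fwd_label]
      lin_r <- (col[!fwd_label] - 1L) * n_sites + si[!fwd_label]
      tf <- tabulate(lin_f, nbins = n_sites * W)
      tr <- tabulate(lin_r, nbins = n_sites * W)
      fwd <- fwd + matrix(tf, n_sites, W)
      rev_ <- rev_ + matrix(tr, n_sites, W)
      rownames(fwd) <- rownames(rev_) <- sites$site_id
    }
  }
  structure(list(sites = sites, flank = as.integer(flank),
                 motif_length = as.integer(motif_length), W = as.integer(W),
                 forward = fwd, reverse = rev_),
            class = "CutMatrix")
}

#' @export
print.CutMatrix <- function(x, ...) {
  cat(sprintf("CutMatrix: %d sites x %d positions (motif %d bp, flank %d bp)\n",
              nrow(x$forward), x$W, x$motif_length, x$flank))
  cat(sprintf("  forward ends: %d, reverse ends: %d\n",
              sum(x$forward), sum(x$reverse)))
  invisible(x)
}

#' Aggregate cut-frequency profile over all sites
#'
#' @param m a `CutMatrix`
#' @return list with per-column totals `forward`, `reverse`, `combined`
#' @export
aggregate_profile <- function(m) {
  stopifnot(inherits(m, "CutMatrix"))
  fwd <- colSums(m$forward)
  rev_ <- colSums(m$reverse)
  list(forward = fwd, reverse = rev_, combined = fwd + rev_)
}

#' Strand-specific per-base cut-frequency tracks for a genomic region
#'
#' Counts s1-derived (forward) and e2-derived (reverse) cut boundaries at
#' each base of the region and returns/writes bedGraph-style intervals
#' (0-based half-open, one row per base with a non-zero count).
#'
#' @param fragments fragment data.frame
#' @param region list or one-row data.frame with chrom, start, end (0-based
#'   half-open)
#' @param out_prefix when non-NULL, writes `<prefix>.forward.bedGraph` and
#'   `<prefix>.reverse.bedGraph`
#' @return list of data.frames `forward`, `reverse` with chrom, start, end,
#'   count
#' @export
write_cut_tracks <- function(fragments, region, out_prefix = NULL) {
  stopifnot(region$end > region$start)
  one_track <- function(b) {
    b <- b[fragments$chrom == region$chrom]
    b <- b[b >= region$start & b < region$end]
    if (length(b) == 0L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), count = integer()))
    }
    t <- table(b)
    pos <- as.integer(names(t))
    data.frame(chrom = region$chrom, start = pos, end = pos + 1L,
               count = as.integer(t), stringsAsFactors = FALSE)
  }
  tracks <- list(forward = one_track(fragments$s1),
                 reverse = one_track(fragments$e2))
  if (!is.null(out_prefix)) {
    for (strand in names(tracks)) {
      write.table(tracks[[strand]],
                  sprintf("%s.%s.bedGraph", out_prefix, strand),
                  quote = FALSE, sep = "\t", row.names = FALSE,
                  col.names = FALSE)
    }
  }
  tracks
}

#' Write a CutMatrix as per-strand TSV files
#' @param m a `CutMatrix`
#' @param prefix output path prefix; writes `<prefix>.forward.tsv` and
#'   `<prefix>.reverse.tsv` (site_id column then W count columns)
#' @return invisibly, the two paths
#' @export
write_cut_matrix <- function(m, prefix) {
  paths <- sprintf("%s.%s.tsv", prefix, c("forward", "reverse"))
  for (i in 1:2) {
    mat <- m[[c("forward", "reverse")[i]]]
    df <- data.frame(site_id = m$sites$site_id, mat, check.names = FALSE)
    names(df) <- c("site_id", sprintf("pos_%d", seq_len(m$W)))
    write_tsv(df, paths[i])
  }
  invisible(paths)
}
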