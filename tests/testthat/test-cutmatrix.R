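test_that("assign_cut_positions maps boundaries with flip and label swap", {
  frag <- list(s1 = 115L, e2 = 130L)
  site_plus <- list(start = 120L, end = 126L, strand = "+")
  # window [110, 136), W = 26; spec columns are 0-based, ours 1-based
  out <- assign_cut_positions(frag, site_plus, flank = 10L)
  expect_equal(out$column[out$strand == "forward"], 5L + 1L)
  expect_equal(out$column[out$strand == "reverse"], 20L + 1L)
  site_minus <- list(start = 120L, end = 126L, strand = "-")
  out <- assign_cut_positions(frag, site_minus, flank = 10L)
  expect_equal(out$column[out$strand == "reverse"], 20L + 1L)  # 26-1-5
  expect_equal(out$column[out$strand == "forward"], 5L + 1L)   # 26-1-20
  # fragment entirely outside the window
  out <- assign_cut_positions(list(s1 = 500L, e2 = 700L), site_plus,
                              flank = 10L)
  expect_equal(nrow(out), 0L)
  # half-open window edge: boundary at window end is excluded
  out <- assign_cut_positions(list(s1 = 110L, e2 = 136L), site_plus,
                              flank = 10L)
  expect_equal(out$strand, "forward")
  expect_equal(out$column, 1L)
})

test_that("build_cut_matrix equals the brute-force per-base oracle", {
  for (seed in c(1, 2, 3, 11, 12)) {
    toy <- random_toy_set(seed, max_frags = 10L, max_sites = 3L)
    cm <- build_cut_matrix(toy$fragments, toy$sites, flank = toy$flank)
    oracle <- brute_cut_matrix(toy$fragments, toy$sites, toy$flank)
    expect_equal(unname(cm$forward), oracle$forward)
    expect_equal(unname(cm$reverse), oracle$reverse)
  }
})

test_that("build_cut_matrix handles degenerate inputs", {
  toy <- random_toy_set(5)
  cm <- build_cut_matrix(toy$fragments[0, ], toy$sites, flank = toy$flank)
  expect_true(all(cm$forward == 0L) && all(cm$reverse == 0L))
  expect_equal(dim(cm$forward), c(nrow(toy$sites), cm$W))
  mixed <- toy$sites
  mixed$end[1] <- mixed$end[1] + 1L
  if (nrow(mixed) > 1L) {
    expect_error(build_cut_matrix(toy$fragments, mixed, flank = toy$flank),
                 "motif length")
  }
})

test_that("one fragment overlapping two site windows contributes to both rows", {
  sites <- data.frame(chrom = "chrT", start = c(100L, 110L),
                      end = c(106L, 116L), name = c("a", "b"), score = 0,
                      strand = "+", site_id = c("a", "b"),
                      stringsAsFactors = FALSE)
  frag <- data.frame(chrom = "chrT", start = 98L, end = 120L, name = "f",
                     score = 0, strand = "+", s1 = 98L, e2 = 120L,
                     stringsAsFactors = FALSE)
  cm <- build_cut_matrix(frag, sites, flank = 20L)
  expect_equal(rowSums(cm$forward) + rowSums(cm$reverse), c(a = 2, b = 2))
  # conservation: total mass = number of (end, window) incidences
  oracle <- brute_cut_matrix(frag, sites, 20L)
  expect_equal(sum(cm$forward) + sum(cm$reverse),
               sum(oracle$forward) + sum(oracle$reverse))
})

test_that("aggregate_profile sums columns and ignores row order", {
  toy <- random_toy_set(21)
  cm <- build_cut_matrix(toy$fragments, toy$sites, flank = toy$flank)
  agg <- aggregate_profile(cm)
  expect_equal(agg$combined, agg$forward + agg$reverse)
  expect_equal(sum(agg$combined), sum(cm$forward) + sum(cm$reverse))
  perm <- sample(nrow(toy$sites))
  cm2 <- build_cut_matrix(toy$fragments, toy$sites[perm, ],
                          flank = toy$flank)
  expect_equal(aggregate_profile(cm2)$combined, agg$combined)
  single <- build_cut_matrix(toy$fragments, toy$sites[1, ],
                             flank = toy$flank)
  expect_equal(aggregate_profile(single)$forward, colSums(single$forward))
})

test_that("mirror-imaging the genome leaves the oriented matrix unchanged", {
  # The flip rule reverses the window's nucleotide columns, i.e. reflects
  # about base centers, so a cut boundary b mirrors to C - 1 - b while
  # base intervals mirror to [C - end, C - start).
  toy <- random_toy_set(33)
  C <- 10000L
  fr <- toy$fragments
  mirrored_fr <- data.frame(chrom = fr$chrom, start = C - 1L - fr$end,
                            end = C - 1L - fr$start, name = fr$name,
                            score = 0,
                            strand = ifelse(fr$strand == "+", "-", "+"),
                            # mate identities swap under reflection
                            s1 = C - 1L - fr$e2, e2 = C - 1L - fr$s1,
                            stringsAsFactors = FALSE)
  st <- toy$sites
  mirrored_sites <- data.frame(chrom = st$chrom, start = C - st$end,
                               end = C - st$start, name = st$name,
                               score = 0,
                               strand = ifelse(st$strand == "+", "-", "+"),
                               site_id = st$site_id,
                               stringsAsFactors = FALSE)
  cm <- build_cut_matrix(fr, st, flank = toy$flank)
  cm_mirror <- build_cut_matrix(mirrored_fr, mirrored_sites,
                                flank = toy$flank)
  expect_equal(cm_mirror$forward, cm$forward)
  expect_equal(cm_mirror$reverse, cm$reverse)
})

test_that("cut-site offsets shift columns exactly", {
  sites <- data.frame(chrom = "chrT", start = 200L, end = 206L, name = "s",
                      score = 0, strand = "+", site_id = "s",
                      stringsAsFactors = FALSE)
  set.seed(4)
  start <- sample(150:230, 30, replace = TRUE)
  fr <- data.frame(chrom = "chrT", start = start, end = start + 40L,
                   name = sprintf("f%d", 1:30), score = 0, strand = "+",
                   s1 = start, e2 = start + 40L, stringsAsFactors = FALSE)
  base <- build_cut_matrix(fr, sites, flank = 30L)
  atac <- build_cut_matrix(fr, sites, flank = 30L, forward_offset = 4L,
                           reverse_offset = -5L)
  W <- base$W
  # forward columns shift +4, reverse columns -5 (within-window entries)
  expect_equal(atac$forward[1, 5:W], base$forward[1, 1:(W - 4)])
  expect_equal(atac$reverse[1, 1:(W - 5)], base$reverse[1, 6:W])
})

test_that("write_cut_tracks matches hand enumeration and conserves ends", {
  fr <- data.frame(chrom = "chrT", start = c(100L, 100L, 105L),
                   end = c(140L, 150L, 160L), name = c("a", "b", "c"),
                   score = 0, strand = "+",
                   s1 = c(100L, 100L, 105L), e2 = c(140L, 150L, 160L),
                   stringsAsFactors = FALSE)
  region <- list(chrom = "chrT", start = 90L, end = 170L)
  tracks <- write_cut_tracks(fr, region)
  expect_equal(tracks$forward$start, c(100L, 105L))
  expect_equal(tracks$forward$count, c(2L, 1L))
  expect_equal(tracks$reverse$start, c(140L, 150L, 160L))
  expect_equal(sum(tracks$forward$count) + sum(tracks$reverse$count), 6L)
  # bedGraph intervals are 0-based half-open single bases
  expect_equal(tracks$forward$end - tracks$forward$start, c(1L, 1L))
  none <- write_cut_tracks(fr, list(chrom = "chrZ", start = 0L, end = 10L))
  expect_equal(nrow(none$forward), 0L)
  # files written when a prefix is given
  prefix <- file.path(withr::local_tempdir(), "track")
  write_cut_tracks(fr, region, out_prefix = prefix)
  expect_true(file.exists(paste0(prefix, ".forward.bedGraph")))
})
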