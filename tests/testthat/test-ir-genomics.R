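test_that("a perfect inverted pair is found and the window rule applies", {
  set.seed(1)
  rep_seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rep_seq)))
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
  genome <- c(chrT = paste0(filler(100), rep_seq, filler(300), rc, filler(100)))
  reps <- repeat_features(c("chrT", "chrT"), c(100, 700), c(400, 1000),
                          c("+", "-"), c("Alu", "Alu"))
  pairs <- find_ir_pairs(reps, genome)
  expect_identical(nrow(pairs), 1L)
  expect_equal(pairs$percent_identity, 100)
  expect_identical(pairs$gap_bp, 300L)
  # same features but beyond the 1.5 kb window: no pair
  genome2 <- c(chrT = paste0(filler(100), rep_seq, filler(2000), rc, filler(100)))
  reps2 <- repeat_features(c("chrT", "chrT"), c(100, 2400), c(400, 2700),
                           c("+", "-"), c("Alu", "Alu"))
  expect_identical(nrow(find_ir_pairs(reps2, genome2)), 0L)
  # same-strand copies are never paired
  genome3 <- c(chrT = paste0(filler(100), rep_seq, filler(300), rep_seq, filler(100)))
  reps3 <- repeat_features(c("chrT", "chrT"), c(100, 700), c(400, 1000),
                           c("+", "+"), c("Alu", "Alu"))
  expect_identical(nrow(find_ir_pairs(reps3, genome3)), 0L)
  # out-of-bounds features are reported by name
  reps4 <- repeat_features("chrT", 100, 99999, "+", "Alu", name = "bad_feature")
  expect_error(find_ir_pairs(reps4, genome), "bad_feature")
})

test_that("the 80% identity gate separates 10% from 25% divergence", {
  sg10 <- synth_genome(n_pairs = 8, divergence = 0.10, n_decoys = 0,
                       n_over_window = 0, seed = 21)
  expect_identical(nrow(find_ir_pairs(sg10$repeats, sg10$genome)), 8L)
  sg25 <- synth_genome(n_pairs = 8, divergence = 0.25, n_decoys = 0,
                       n_over_window = 0, seed = 22)
  expect_identical(nrow(find_ir_pairs(sg25$repeats, sg25$genome)), 0L)
})

test_that("planted-repeat detection is exact at zero divergence", {
  sg <- synth_genome(n_pairs = 20, divergence = 0, n_decoys = 20,
                     n_over_window = 10, seed = 31)
  pairs <- find_ir_pairs(sg$repeats, sg$genome)
  found <- paste(pairs$upstream_name, pairs$downstream_name)
  truth <- paste(sg$truth$upstream_name, sg$truth$downstream_name)
  expect_identical(sort(found), sort(truth))  # recall = precision = 1
  # decoy-only genome yields nothing
  sgd <- synth_genome(n_pairs = 0, divergence = 0, n_decoys = 6,
                      n_over_window = 0, seed = 32)
  expect_identical(nrow(find_ir_pairs(sgd$repeats, sgd$genome)), 0L)
})

test_that("per-million normalization scales values and records totals", {
  tr <- coverage_track("chr1", c(0, 10), c(10, 20), c(10, 4))
  n <- normalize_coverage(tr, 2e6)
  expect_equal(n$value, c(5, 2))
  expect_true(attr(n, "normalized"))
  n2 <- normalize_coverage(tr, 1e6)
  expect_equal(n2$value, tr$value)
  expect_error(normalize_coverage(tr, 0), "> 0")
})

test_that("track subtraction does exact interval arithmetic", {
  a <- coverage_track("chr1", 0, 10, 3)
  b <- coverage_track("chr1", 5, 15, 1)
  d <- subtract_tracks(a, b)
  expect_equal(as.data.frame(d)[, c("start", "end", "value")],
               data.frame(start = c(0L, 5L, 10L), end = c(5L, 10L, 15L),
                          value = c(3, 2, -1)))
  # a - a is identically zero over the covered region
  t2 <- coverage_track(rep("chr1", 3), c(0, 10, 50), c(10, 30, 60), c(2, 5, 1))
  z <- subtract_tracks(t2, t2)
  expect_true(all(z$value == 0))
  # empty subtrahend leaves the track unchanged
  d2 <- subtract_tracks(t2, coverage_track())
  expect_equal(d2$value, t2$value)
  # subtract then add back recovers a on the union breakpoints
  s <- subtract_tracks(t2, b)
  add_chrom <- pkrscan:::combine_chrom(as.data.frame(s), as.data.frame(b), `+`)
  va <- vapply(seq_len(nrow(add_chrom)), function(i) {
    peak_auc(t2, "chr1", add_chrom$start[i], add_chrom$end[i]) /
      (add_chrom$end[i] - add_chrom$start[i])
  }, numeric(1))
  expect_equal(add_chrom$value, va)
})

test_that("peak calling thresholds, merges and filters runs", {
  expect_identical(nrow(call_peaks(coverage_track("chr1", 0, 100, 0))), 0L)
  p <- call_peaks(coverage_track("chr1", 0, 100, 5), min_value = 1,
                  min_length = 50)
  expect_equal(as.data.frame(p),
               data.frame(chrom = "chr1", start = 0L, end = 100L))
  # two runs separated by a 10 bp gap merge across merge_gap = 20
  t2 <- coverage_track(rep("chr1", 2), c(0, 60), c(50, 120), c(5, 5))
  expect_identical(nrow(call_peaks(t2, merge_gap = 20)), 1L)
  expect_identical(nrow(call_peaks(t2, merge_gap = 5)), 2L)
})

test_that("peak AuC matches a per-bp brute-force oracle", {
  tr <- coverage_track(rep("chr1", 2), c(0, 10), c(10, 20), c(2, 1))
  expect_equal(peak_auc(tr, "chr1", 5, 15), 15)  # 5*2 + 5*1
  expect_equal(peak_auc(tr, "chr1", 100, 200), 0)
  set.seed(50)
  worst <- 0
  for (i in 1:50) {
    n <- sample(3:8, 1)
    bnd <- sort(sample(0:200, n + 1))
    keep <- diff(bnd) > 0
    st <- bnd[-(n + 1)][keep]
    en <- bnd[-1][keep]
    tr <- coverage_track(rep("chr1", length(st)), st, en,
                         round(runif(length(st), 0, 10), 3))
    q <- sort(sample(0:200, 2))
    if (q[1] == q[2]) next
    # per-bp oracle
    per_bp <- 0
    for (pos in q[1]:(q[2] - 1)) {
      j <- which(tr$start <= pos & tr$end > pos)
      if (length(j)) per_bp <- per_bp + tr$value[j]
    }
    worst <- max(worst, abs(peak_auc(tr, "chr1", q[1], q[2]) - per_bp))
  }
  expect_lt(worst, 1e-9)
})

test_that("enrichment quantification applies the log2FC criteria pair", {
  fclip <- coverage_track("chr1", 0, 100, 8, normalized = TRUE)
  input <- coverage_track("chr1", 0, 100, 2, normalized = TRUE)
  ctrl_f <- coverage_track("chr1", 0, 100, 1, normalized = TRUE)
  ctrl_i <- coverage_track("chr1", 0, 100, 2, normalized = TRUE)
  peaks <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  pq <- quantify_peaks(peaks, fclip, input, ctrl_f, ctrl_i, pseudo = 0)
  expect_equal(pq$log2fc, 2)          # log2(80 / 20)
  expect_lt(pq$control_log2fc, 0)
  expect_true(pq$enriched)
  # failing the control gate removes the peak
  pq2 <- quantify_peaks(peaks, fclip, input, fclip, ctrl_i, pseudo = 0)
  expect_false(pq2$enriched)
})

test_that("normalized AuC and log2FC are invariant to sequencing depth", {
  set.seed(60)
  raw_f <- coverage_track(rep("chr1", 3), c(0, 30, 80), c(30, 60, 120),
                          c(40, 90, 15))
  raw_i <- coverage_track(rep("chr1", 2), c(0, 50), c(50, 120), c(10, 20))
  quant <- function(k) {
    f <- normalize_coverage(coverage_track(raw_f$chrom, raw_f$start,
                                           raw_f$end, raw_f$value * k),
                            2e6 * k)
    i <- normalize_coverage(coverage_track(raw_i$chrom, raw_i$start,
                                           raw_i$end, raw_i$value * k),
                            3e6 * k)
    pk <- data.frame(chrom = "chr1", start = 10L, end = 100L)
    quantify_peaks(pk, f, i)
  }
  q1 <- quant(1)
  q2 <- quant(2)
  expect_equal(q1$auc_fclip, q2$auc_fclip)
  expect_equal(q1$log2fc, q2$log2fc)
})

test_that("peaks are classified against inverted-repeat pairs by the 300 bp rule", {
  sg <- synth_genome(n_pairs = 2, divergence = 0, n_decoys = 0,
                     n_over_window = 0, gap_range = c(800, 900), seed = 41)
  pairs <- find_ir_pairs(sg$repeats, sg$genome)
  expect_identical(nrow(pairs), 2L)
  up <- sg$repeats[pairs$upstream[1], ]
  dn <- sg$repeats[pairs$downstream[1], ]
  peaks <- data.frame(
    chrom = up$chrom,
    start = c(up$start + 10,       # inside a member
              up$start - 250,      # 250 bp upstream
              up$start - 400,      # 400 bp upstream
              up$end + 100),       # between the members (flanked)
    stringsAsFactors = FALSE)
  peaks$end <- peaks$start + 50
  cls <- annotate_near_ir(peaks, pairs)
  expect_identical(cls, c("IR-Alu", "near IR-Alu", "other", "near IR-Alu"))
})

test_that("editing CPM is exact and proportional", {
  es <- editing_cpm(c(regionA = 50), 1e7)
  expect_equal(es$cpm, 5)
  expect_equal(editing_cpm(c(x = 0), 1e6)$cpm, 0)
  expect_equal(editing_cpm(c(x = 10), 5e5)$cpm,
               2 * editing_cpm(c(x = 10), 1e6)$cpm)
  expect_error(editing_cpm(c(x = 1), 0), "> 0")
})
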