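test_that("cell filtering applies strict exclusion thresholds", {
  st <- data.frame(barcode = c("a", "b", "c", "d"),
                   n_fragments = c(999, 1000, 5000, 2000),
                   tss = c(10, 4.0, 3.9, 8))
  cs <- filter_cells(st)
  expect_setequal(cs$barcodes, c("b", "d"))  # 999 out; tss 4.0 kept; 3.9 out

  # no TSS column with min_tss unset -> fragment filter only
  cs2 <- filter_cells(st[, c("barcode", "n_fragments")], min_tss = NULL)
  expect_setequal(cs2$barcodes, c("b", "c", "d"))
  expect_error(filter_cells(st, min_fragments = 1e7), "no cells pass")
})

test_that("pseudobulk counts insertions and normalizes by library size", {
  layout <- genome_layout("chr1", 10000)
  fr <- data.table::data.table(chrom = "chr1", start = 100L, end = 250L,
                               barcode = "BC01", count = 1L)
  pb <- pseudobulk_accessibility(fr, "BC01", layout, "chr1", scale = 2)
  nz <- which(pb$values > 0)
  expect_equal(nz, c(100 %/% 50 + 1, 249 %/% 50 + 1))  # both endpoints
  expect_equal(pb$library_size, 2)
  expect_equal(pb$values[nz], log1p(c(1, 1)))  # 1 * 2/2

  # doubling depth leaves the track unchanged
  fr2 <- rbind(fr, fr)
  pb2 <- pseudobulk_accessibility(fr2, "BC01", layout, "chr1", scale = 2)
  expect_equal(pb2$values, pb$values)
})

test_that("pseudobulk value formula matches hand computation", {
  # raw counts {0, 1, 10}, library 100, scale 100 -> log1p({0, 1, 10})
  ins <- Matrix::sparseMatrix(i = c(1, 1), j = c(2, 3), x = c(1, 10),
                              dims = c(1, 3))
  # pad library to 100 by adding mass in bin 1
  ins[1, 1] <- 89
  pb <- chromstripe:::pseudobulk_from_matrix(ins, 1L, "chr1", 50L, scale = 100)
  expect_equal(pb$values[2:3], log1p(c(1, 10)))
})

test_that("motif scanning scores consensus and respects strand symmetry", {
  pwm <- matrix(0.05, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(c(1, 1, 2, 3), 1:4)] <- 0.85   # consensus AACG (not palindromic)
  hits <- scan_ctcf_motifs("AACG", pwm)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 4 * log2(0.85 / 0.25), tolerance = 1e-12)
  expect_equal(hits$start, 0L)

  # reverse complement of the consensus scores the same on the minus strand
  minus <- scan_ctcf_motifs(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("AACG"))), pwm)
  expect_equal(max(minus$score), max(hits$score))
  expect_equal(minus$strand[which.max(minus$score)], "-")

  # all-N sequence yields nothing
  expect_equal(nrow(scan_ctcf_motifs("NNNNNNNN", pwm)), 0)

  # zero-probability cells get a pseudocount rather than -Inf
  pwm0 <- pwm; pwm0[1, 1] <- 0
  expect_true(all(is.finite(scan_ctcf_motifs("ACGTACGT", pwm0)$score)))
})

test_that("motif track takes max over hits overlapping >= 10bp", {
  layout <- genome_layout("chr1", 10000)
  hits <- data.frame(start = c(100L, 141L, 110L), end = c(119L, 150L, 125L),
                     strand = "+", score = c(7, 9, 3), pwm = 1L)
  tr <- motif_track_from_hits(hits, layout, "chr1")
  b3 <- tr$values[3]  # bin [100,150)
  expect_equal(b3, 7)  # 19bp and 15bp overlaps qualify; 9bp hit ignored; max 7

  # permuting hit order never changes the track
  tr2 <- motif_track_from_hits(hits[c(2, 3, 1), ], layout, "chr1")
  expect_equal(tr2$values, tr$values)
})

test_that("ChIP bedGraph rebinning is a length-weighted mean", {
  layout <- genome_layout("chr1", 1000)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t25\t2"), p)   # half of bin 1 at value 2
  tr <- chip_track_from_bedgraph(p, layout, "chr1", resolution = 50L)
  expect_equal(tr$values[1], 1.0)

  # constant coverage -> constant track
  p2 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t1000\t3", p2)
  tr2 <- chip_track_from_bedgraph(p2, layout, "chr1", resolution = 50L)
  expect_true(all(tr2$values == 3))

  # round-trip with write_track_bedgraph on bin-aligned input
  set.seed(5)
  v <- sample(0:4, 20, TRUE)
  p3 <- withr::local_tempfile(fileext = ".bedGraph")
  write_track_bedgraph(v, p3, "chr1", 50, chrom_length = 1000)
  tr3 <- chip_track_from_bedgraph(p3, layout, "chr1", resolution = 50L)
  expect_equal(tr3$values, as.numeric(v))
})

test_that("extract_window pads with zeros beyond chromosome edges", {
  g <- miniature_geometry()
  n50 <- 300 * 200  # 300 contact bins worth of 50bp bins
  v <- rep(1, n50)
  # interior center: pure slice
  w <- extract_window(v, 150, g, resolution = 50)
  expect_equal(length(w), g$acc_window_len)
  expect_true(all(w == 1))
  # window length for the full-scale geometry: 4.01 Mb / 50bp
  expect_equal(model_geometry()$acc_window_len, 80200L)
  # center at chromosome start: left half exactly zeros
  w0 <- extract_window(v, 1, g, resolution = 50)
  left <- w0[seq_len(g$max_distance_bins * g$reduction_factor)]
  expect_true(all(left == 0))
  expect_true(all(w0[-seq_along(left)] == 1))
  expect_error(extract_window(v, 0, g, resolution = 50), "outside")
  # constant full-coverage track stays constant outside padding
  wmid <- extract_window(v, 290, g, resolution = 50)
  expect_true(all(wmid[1:100] == 1))
  expect_true(any(wmid == 0))  # right edge padded
})
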