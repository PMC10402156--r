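# shared fixtures, all generated in code

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(1e6, 5e5))

# small random upper-triangular contact map
random_contact_map <- function(n_bins = 60, chrom = "chr1",
                               resolution = 10000L, density = 0.4,
                               seed = 1) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
                 arr.ind = TRUE)
  keep <- sample(nrow(pairs), ceiling(density * nrow(pairs)))
  contact_map(chrom, resolution, n_bins,
              i = pairs[keep, 1], j = pairs[keep, 2],
              value = rpois(length(keep), 5) + 1)
}

# fragments table for a handful of cells
tiny_fragments <- function(layout = tiny_layout(), n = 200, seed = 1) {
  set.seed(seed)
  chrom <- sample(layout$chrom_names, n, replace = TRUE)
  len <- layout$chrom_lengths[chrom]
  start <- floor(runif(n, 0, len - 400))
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(start + sample(50:350, n, TRUE)),
                         barcode = sample(sprintf("BC%02d", 1:8), n, TRUE),
                         count = 1L)
}

# small simulated world shared by the heavier tests (cached per session)
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(chrom_lengths = c(chrA = 2e6, chrV = 1e6, chrT = 1e6),
                        n_cells = 200L, n_loops = 12L,
                        loop_distance_range = c(5e4, 2e5))
      cache <<- simulate_dataset(cfg, seed = 42)
    }
    cache
  }
})

expect_band_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_identical(is.na(a), is.na(b))
  expect_equal(a[!is.na(a)], b[!is.na(b)], tolerance = tol)
}
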