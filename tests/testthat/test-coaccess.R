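test_that("binarization clamps to presence/absence", {
  layout <- genome_layout("chr1", 10000)
  fr <- data.table::data.table(chrom = "chr1",
                               start = c(100L, 110L, 120L, 5000L),
                               end = c(200L, 210L, 220L, 5100L),
                               barcode = c("a", "a", "a", "b"), count = 1L)
  m <- binarize_cells(fr, c("a", "b", "c"), layout, "chr1")
  expect_true(all(m@x == 1))
  expect_equal(as.numeric(m[1, 1]), 1)   # 5 insertions -> 1
  expect_equal(Matrix::rowSums(m)[3], 0) # empty cell keeps its all-zero row
  # density equals the fraction of touched (cell, bin) pairs:
  # cell a's fragments all hit 500bp bin 1, cell b's hit bin 11
  expect_equal(length(m@x) / prod(dim(m)), 2 / prod(dim(m)))
})

test_that("LSI embedding is structure-preserving and matches a dense SVD oracle", {
  set.seed(2)
  m <- Matrix::Matrix(matrix(rbinom(40 * 30, 1, 0.2), 40, 30), sparse = TRUE)
  m[1, ] <- m[2, ]  # identical cells
  emb <- lsi_embedding(m, 5)
  expect_equal(emb[1, ], emb[2, ], tolerance = 1e-9)

  # reconstruction error of the rank-k factorization matches the dense oracle
  m2 <- as.matrix(m)
  rs <- pmax(rowSums(m2), 1)
  idf <- log1p(nrow(m2) / colSums(m2 > 0))
  x <- (m2 / rs) %*% diag(idf)
  x <- x[, colSums(m2) > 0]
  sv <- svd(x)
  k <- 5
  emb_oracle <- sv$u[, 1:k] %*% diag(sv$d[1:k])
  # compare spectra (signs/rotations of singular vectors are arbitrary)
  expect_equal(svd(emb)$d, svd(emb_oracle)$d, tolerance = 1e-8)

  # orthogonal single-bin cells separate
  o <- Matrix::sparseMatrix(i = 1:6, j = c(1, 1, 1, 2, 2, 2), x = 1,
                            dims = c(6, 2))
  e2 <- lsi_embedding(o, 2)
  expect_gt(sum((e2[1, ] - e2[4, ])^2), sum((e2[1, ] - e2[2, ])^2))
})

test_that("metacell construction respects k and the overlap cap", {
  set.seed(4)
  # two well-separated blobs
  emb <- rbind(matrix(rnorm(20 * 2, 0), 20, 2),
               matrix(rnorm(20 * 2, 50), 20, 2))
  mc0 <- build_metacells(emb, k = 20, overlap_cap = 0, seed = 1)
  expect_equal(length(mc0$members), 2)
  expect_equal(length(intersect(mc0$members[[1]], mc0$members[[2]])), 0)

  mc1 <- build_metacells(emb, k = 20, overlap_cap = 1, seed = 1)
  expect_equal(length(mc1$members), 40)  # every candidate accepted

  mc <- build_metacells(emb, k = 10, overlap_cap = 0.5, seed = 2)
  expect_true(all(lengths(mc$members) == 10))
  # brute-force pairwise overlap audit
  for (a in seq_along(mc$members)) for (b in seq_len(a - 1))
    expect_lte(length(intersect(mc$members[[a]], mc$members[[b]])) / 10, 0.5)

  expect_error(build_metacells(emb, k = 100), "exceeds")
})

test_that("metacell profiles are the OR of member rows", {
  cb <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 2, 2), x = 1,
                             dims = c(4, 3))
  asg <- structure(list(members = list(1:3, c(3L, 4L)), k = 3L,
                        overlap_cap = 1), class = "metacell_assignment")
  prof <- metacell_profiles(cb, asg)
  oracle <- rbind(as.numeric(Matrix::colSums(cb[1:3, ]) > 0),
                  as.numeric(Matrix::colSums(cb[3:4, ]) > 0))
  expect_equal(unname(as.matrix(prof)), oracle)
  # bin closed in all members stays 0; threshold variant
  prof2 <- metacell_profiles(cb, asg, threshold = 2)
  expect_equal(as.numeric(prof2[1, ]), c(0, 1, 0))
})

test_that("jaccard co-accessibility matches the brute-force set oracle", {
  # worked example: profiles i = [1,0,1,1], j = [1,1,0,1] -> J = 2/4
  p <- Matrix::Matrix(cbind(c(1, 0, 1, 1), c(1, 1, 0, 1)), sparse = TRUE)
  expect_equal(jaccard_coaccessibility(p, 1, 2)[1, 1], 0.5)
  expect_equal(jaccard_coaccessibility(p, 1, 1)[1, 1], 1)  # identical nonzero

  set.seed(9)
  for (rep in 1:3) {
    M <- 30; B <- 200
    prof <- Matrix::Matrix(matrix(rbinom(M * B, 1, 0.3), M, B), sparse = TRUE)
    centers <- sample(B, 5); window <- sample(B, 40)
    J <- jaccard_coaccessibility(prof, centers, window)
    dense <- as.matrix(prof)
    for (a in seq_along(centers)) for (b in seq_along(window)) {
      x <- dense[, centers[a]]; y <- dense[, window[b]]
      inter <- sum(x & y); uni <- sum(x | y)
      expect_equal(J[a, b], if (uni == 0) 0 else inter / uni)
    }
  }

  # out-of-range window bins give zero-padding columns
  Jpad <- jaccard_coaccessibility(p, 1, c(-1L, 1L, 99L))
  expect_equal(Jpad[1, c(1, 3)], c(0, 0))
})

test_that("jaccard is symmetric, bounded and metacell-permutation invariant", {
  set.seed(10)
  prof <- Matrix::Matrix(matrix(rbinom(25 * 50, 1, 0.4), 25, 50), sparse = TRUE)
  J <- jaccard_coaccessibility(prof, 1:50, 1:50)
  expect_true(all(J >= 0 & J <= 1))
  expect_equal(J, t(J))
  Jp <- jaccard_coaccessibility(prof[sample(25), ], 1:50, 1:50)
  expect_equal(J, Jp)
})

test_that("coaccess_slice geometry and metacell subsetting agree with direct call", {
  g <- miniature_geometry()
  set.seed(12)
  nb <- 300 * g$coacc_per_hic
  prof <- Matrix::Matrix(matrix(rbinom(15 * nb, 1, 0.05), 15, nb),
                         sparse = TRUE)
  t <- 150L
  sl <- coaccess_slice(prof, t, g)
  expect_equal(dim(sl), c(g$center_coacc_bins, g$coacc_window_len))
  f <- g$coacc_per_hic
  centers <- ((t - 1) * f + 1):(t * f)
  window <- seq.int((t - 1 - g$max_distance_bins) * f + 1,
                    length.out = g$coacc_window_len)
  expect_equal(sl, jaccard_coaccessibility(prof, centers, window))
  # subsetting metacells equals slicing the profile matrix first
  idx <- c(2L, 5L, 9L)
  expect_equal(coaccess_slice(prof, t, g, metacells = idx),
               coaccess_slice(prof[idx, ], t, g))
  # self-columns of nonzero center bins carry J = 1
  nzc <- which(Matrix::colSums(prof[, centers, drop = FALSE]) > 0)
  center_cols <- g$max_distance_bins * f + nzc
  expect_true(all(sl[cbind(nzc, center_cols)] == 1))
})

test_that("augmentation subsampling respects ranges and determinism", {
  set.seed(1)
  s <- subsample_for_augmentation(10000, c(500, 5000))
  expect_true(length(s) >= 500 && length(s) <= 5000)
  expect_equal(length(unique(s)), length(s))
  # fixed seed reproduces; exact range (n, n) gives exactly n
  a <- withr::with_seed(7, subsample_for_augmentation(100, c(10, 50)))
  b <- withr::with_seed(7, subsample_for_augmentation(100, c(10, 50)))
  expect_identical(a, b)
  expect_length(subsample_for_augmentation(100, c(25, 25)), 25)
  # small population: sample with replacement up to the lower bound
  s2 <- subsample_for_augmentation(5, c(20, 30))
  expect_length(s2, 20)
  expect_error(subsample_for_augmentation(integer(), c(1, 2)), "empty")
})
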