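test_that("distance-stratified pearson: identity, affine invariance, oracle", {
  m <- random_contact_map(60, seed = 31, density = 1)
  z <- distance_stratified_zscore(m, 2e5)
  r <- distance_stratified_pearson(z, z)
  defined <- !is.na(r$per_distance)
  expect_true(all(abs(r$per_distance[defined] - 1) < 1e-12))

  # per-distance affine transforms (nonzero slope) leave r unchanged
  z2 <- z
  for (d in seq_len(ncol(z2$band)))
    z2$band[, d] <- (1 + d / 10) * z2$band[, d] + d
  r2 <- distance_stratified_pearson(z2, z)
  expect_equal(r2$per_distance, r$per_distance, tolerance = 1e-12)

  # random maps against the direct formula
  set.seed(32)
  zp <- z; zp$band <- matrix(rnorm(length(z$band)), nrow(z$band))
  zp$band[is.na(z$band)] <- NA
  r3 <- distance_stratified_pearson(zp, z)
  for (d in c(1, 5, 15)) {
    ok <- !is.na(zp$band[, d]) & !is.na(z$band[, d])
    expect_equal(r3$per_distance[d], cor(zp$band[ok, d], z$band[ok, d]))
  }
})

test_that("degenerate distances: truth-constant excluded, pred-constant r = 0", {
  truth <- zscore_map("chr1", 1e4, cbind(rnorm(20), rep(1, 20)))
  pred <- zscore_map("chr1", 1e4, cbind(rnorm(20), rnorm(20)))
  r <- distance_stratified_pearson(pred, truth)
  expect_true(is.na(r$per_distance[2]))       # truth has zero variance
  predc <- zscore_map("chr1", 1e4, cbind(rep(2, 20), rnorm(20)))
  rc <- distance_stratified_pearson(predc, truth)
  expect_equal(rc$per_distance[1], 0)         # constant predictor: no skill
})

test_that("AUROC matches the Mann-Whitney oracle and AUPRC behaves", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 40
    sc <- rnorm(n); lab <- runif(n) < 0.3
    if (!any(lab) || all(lab)) next
    wins <- 0
    for (i in which(lab)) for (j in which(!lab))
      wins <- wins + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    expect_equal(auroc(sc, lab), wins / (sum(lab) * sum(!lab)))
  }
  # monotone transform of the labels scores perfectly
  lab <- c(rep(FALSE, 10), rep(TRUE, 5))
  expect_equal(auroc(seq_along(lab) + as.numeric(lab) * 100, lab), 1)
  expect_equal(auprc(as.numeric(lab) * 2 + 1e-9 * rnorm(15), lab), 1)
  expect_true(is.na(auroc(rnorm(5), rep(TRUE, 5))))
})

test_that("random scores give near-chance AUROC", {
  set.seed(34)
  vals <- replicate(50, auroc(rnorm(200), rep(c(TRUE, FALSE), each = 100)))
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("significant-interaction AUC skips single-class distances", {
  truth <- zscore_map("chr1", 1e4,
                      matrix(rnorm(300), 100, 3))
  labs <- label_significant_bins(truth, 0.2)
  labs[, 3] <- FALSE  # force single class at one distance
  pred <- zscore_map("chr1", 1e4, truth$band + rnorm(300, sd = 0.5))
  auc <- significant_interaction_auc(pred, labs)
  expect_true(is.na(auc$auroc[3]))
  expect_true(all(auc$auroc[1:2] > 0.5))
  # scoring truth against its own labels is near-perfect (wiring check)
  auc2 <- significant_interaction_auc(truth, labs)
  expect_true(all(auc2$auroc[1:2] == 1))
})

test_that("peak-to-bin mapping follows half-open overlap rules", {
  peaks <- data.frame(start = c(19995, 12000, 20000),
                      end = c(20010, 13000, 20500))
  bins <- map_peaks_to_bins(peaks, 10000)
  expect_equal(bins[[1]], c(2L, 3L))  # boundary-spanning peak in both bins
  expect_equal(bins[[2]], 2L)
  expect_equal(bins[[3]], 3L)         # start exactly on the boundary
})

test_that("peak-level labels apply strict p < threshold with any-rule", {
  p_band <- matrix(NA_real_, 10, 5)
  p_band[2, 3] <- 0.24   # pair (2, 4)
  p_band[5, 2] <- 0.25   # pair (5, 6) exactly at the threshold
  peak_bins <- list(2L, 4L, 5L, 6L, c(2L, 3L), 9L)
  pairs <- data.frame(p1 = c(1, 3, 5, 6), p2 = c(2, 4, 2, 1))
  labs <- peak_level_labels(pairs, peak_bins, p_band)
  expect_true(labs[1])            # 0.24 < 0.25
  expect_false(labs[2])           # 0.25 is not < 0.25
  expect_true(labs[3])            # peak 5 covers bins {2,3}: any-rule
  expect_true(is.na(labs[4]))     # no p-value -> dropped
  expect_equal(attr(labs, "n_dropped"), 1L)
})

test_that("peak pair scores reduce over associated bin pairs", {
  band <- matrix(seq_len(50) / 10, 10, 5)
  expect_equal(peak_pair_score(band, 3L, 4L), band[3, 2])
  vals <- c(band[2, 3], band[2, 4], band[3, 2], band[3, 3])
  expect_equal(peak_pair_score(band, c(2L, 3L), c(4L, 5L)), max(vals))
  expect_equal(peak_pair_score(band, c(2L, 3L), c(4L, 5L), reduce = "mean"),
               mean(vals))
})

test_that("peak-level AUC respects the 500kb distance constraint", {
  set.seed(35)
  n <- 30
  scores <- rnorm(n)
  labels <- runif(n) < 0.4
  dist <- c(rep(1e5, 20), rep(6e5, 10))
  res <- peak_level_auc(scores, labels, dist)
  expect_equal(res$n_pairs, 20)
  keep <- dist <= 5e5
  expect_equal(res$auroc, auroc(scores[keep], labels[keep]))
  # perfect scores give AUPRC 1
  perfect <- peak_level_auc(as.numeric(labels), labels, rep(1e5, n))
  expect_equal(perfect$auprc, 1)
})

test_that("insulation score matches the nested-loop oracle and finds boundaries", {
  m <- random_contact_map(40, seed = 36, density = 1)
  ins <- insulation_score(m, window_bins = 5)
  M <- as.matrix(m$mat); M <- M + t(M) - diag(diag(M))
  for (b in c(6, 20, 35))
    expect_equal(ins[b], mean(M[(b - 5):b, b:(b + 5)]))
  expect_true(all(is.na(ins[1:5])))
  # two-block toy: the boundary bin is the interior minimum
  n <- 30
  blocks <- matrix(0, n, n)
  blocks[1:15, 1:15] <- 5; blocks[16:30, 16:30] <- 5
  diag(blocks) <- 10
  bm <- contact_map("chr1", 1e4, n,
                    i = row(blocks)[upper.tri(blocks, diag = TRUE)],
                    j = col(blocks)[upper.tri(blocks, diag = TRUE)],
                    value = blocks[upper.tri(blocks, diag = TRUE)])
  insb <- insulation_score(bm, window_bins = 6)
  interior <- 7:24
  expect_true((which.min(insb[interior]) + 6) %in% c(15, 16))
})

test_that("paired t-test matches the closed form and flags degeneracies", {
  a <- c(0.5, 0.6, 0.7, 0.8); b <- c(0.4, 0.5, 0.65, 0.7)
  res <- paired_ttest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_oracle)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), df = 3))
  # antisymmetry
  expect_equal(paired_ttest(b, a)$t, -res$t)
  # degenerate cases
  same <- paired_ttest(a, a)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "no-difference")
  const <- paired_ttest(a + 0.1, a)
  expect_equal(const$flag, "zero-variance")
  expect_equal(const$p, 0)
})

test_that("metrics are invariant to pair storage order", {
  m1 <- random_contact_map(30, seed = 37)
  tr <- cm_triplets(m1)
  perm <- sample(nrow(tr))
  m2 <- contact_map("chr1", 1e4, 30, tr$i[perm], tr$j[perm], tr$value[perm])
  expect_equal(cm_band(m2, 20), cm_band(m1, 20))
})
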