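# All metrics operate on band matrices (rows = bins, column d+1 = pairs at
# distance d), the natural layout for distance-stratified evaluation.

as_band <- function(x, max_d = NULL) {
  if (inherits(x, "zscore_map")) return(x$band)
  if (inherits(x, "contact_map")) {
    if (is.null(max_d)) max_d <- x$n_bins - 1L
    return(cm_band(x, max_d))
  }
  as.matrix(x)
}

#' Distance-stratified Pearson correlation
#'
#' Pearson r between predicted and true values over the valid pairs at each
#' genomic distance, plus the unweighted mean across distances. A distance
#' is undefined (excluded from the mean, not zero-filled) when it has fewer
#' than 3 valid pairs or the truth has zero variance there; if the truth
#' varies but the prediction is constant, r is reported as 0 (the predictor
#' has no within-distance discrimination).
#'
#' @param pred,truth [zscore_map()]s or band matrices of equal shape.
#' @param mask optional [low_signal_mask()]; pairs touching a masked bin are
#'   dropped.
#' @return list with `per_distance` (numeric, NA = undefined), `mean`,
#'   `n_pairs`.
#' @export
distance_stratified_pearson <- function(pred, truth, mask = NULL) {
  P <- as_band(pred); Z <- as_band(truth)
  stopifnot(all(dim(P) == dim(Z)))
  if (!is.null(mask)) Z <- apply_mask_band(Z, mask)
  nd <- ncol(P)
  r <- rep(NA_real_, nd)
  np <- integer(nd)
  for (d in seq_len(nd)) {
    ok <- !is.na(P[, d]) & !is.na(Z[, d])
    np[d] <- sum(ok)
    if (np[d] < 3) next
    x <- P[ok, d]; y <- Z[ok, d]
    if (stats::sd(y) == 0) next
    r[d] <- if (stats::sd(x) == 0) 0 else stats::cor(x, y)
  }
  list(per_distance = r, mean = if (all(is.na(r))) NA_real_
       else mean(r, na.rm = TRUE), n_pairs = np)
}

apply_mask_band <- function(B, mask) {
  bad <- which(mask$masked)
  if (!length(bad)) return(B)
  n <- nrow(B)
  for (d in 0:(ncol(B) - 1L)) {
    rows <- seq_len(max(n - d, 0L))
    drop <- rows %in% bad | (rows + d) %in% bad
    B[rows[drop], d + 1L] <- NA
  }
  B
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midrank tie handling.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels.
#' @return AUROC in `[0, 1]`, or NA when one class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision over descending score thresholds, with tied scores
#' handled as one group.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`, or NA when no positives exist.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  n_seen <- grp_end
  prec <- tp / n_seen
  rec <- tp / n1
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Distance-stratified AUROC/AUPRC of significant-interaction prediction
#'
#' For each genomic distance, uses the predicted values as scores against
#' the significant-interaction labels (e.g. top-decile Z-scores, see
#' [label_significant_bins()]). Distances where only one class is present
#' are skipped; means are over the defined distances.
#'
#' @param pred predicted [zscore_map()] or band matrix.
#' @param labels logical band matrix of the same shape (NA = invalid pair).
#' @return list with per-distance `auroc` and `auprc` vectors and their
#'   means.
#' @export
significant_interaction_auc <- function(pred, labels) {
  P <- as_band(pred)
  stopifnot(all(dim(P) == dim(labels)))
  nd <- ncol(P)
  roc <- pr <- rep(NA_real_, nd)
  for (d in seq_len(nd)) {
    ok <- !is.na(P[, d]) & !is.na(labels[, d])
    if (sum(ok) < 2) next
    y <- labels[ok, d]
    if (all(y) || !any(y)) next
    roc[d] <- auroc(P[ok, d], y)
    pr[d] <- auprc(P[ok, d], y)
  }
  list(auroc = roc, auprc = pr,
       mean_auroc = if (all(is.na(roc))) NA_real_ else mean(roc, na.rm = TRUE),
       mean_auprc = if (all(is.na(pr))) NA_real_ else mean(pr, na.rm = TRUE))
}

#' Map peaks to overlapping contact-map bins
#'
#' Each peak maps to every bin it overlaps by at least 1 bp (a
#' boundary-spanning peak is assigned to both bins; intervals are 0-based
#' half-open, so a peak starting exactly at a bin boundary belongs to the
#' right bin only).
#'
#' @param peaks data.frame with start, end (bp).
#' @param resolution bin size (default 10000).
#' @return list of 1-based bin-index vectors, one per peak.
#' @export
map_peaks_to_bins <- function(peaks, resolution = 10000L) {
  lapply(seq_len(nrow(peaks)), function(k) {
    b0 <- peaks$start[k] %/% resolution + 1L
    b1 <- (peaks$end[k] - 1L) %/% resolution + 1L
    as.integer(b0:b1)
  })
}

#' Label peak pairs as significantly interacting
#'
#' A peak pair is positive iff any of its associated bin pairs has an
#' FDR-corrected p-value strictly below `fdr_threshold`. Pairs whose bin
#' pairs all lack a p-value are dropped (count in attribute `n_dropped`).
#'
#' @param peak_pairs data.frame with columns `p1`, `p2` (peak indices).
#' @param peak_bins list from [map_peaks_to_bins()].
#' @param p_band band matrix of FDR p-values (NA = missing).
#' @param fdr_threshold significance threshold (default 0.25; strict `<`).
#' @return logical vector (NA = dropped) with attribute `n_dropped`.
#' @export
peak_level_labels <- function(peak_pairs, peak_bins, p_band,
                              fdr_threshold = 0.25) {
  out <- rep(NA, nrow(peak_pairs))
  n_dropped <- 0L
  for (k in seq_len(nrow(peak_pairs))) {
    ps <- band_lookup(p_band, peak_bins[[peak_pairs$p1[k]]],
                      peak_bins[[peak_pairs$p2[k]]])
    ps <- ps[!is.na(ps)]
    if (!length(ps)) { n_dropped <- n_dropped + 1L; next }
    out[k] <- any(ps < fdr_threshold)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

# all band values over the cartesian product of two bin sets
band_lookup <- function(band, bins1, bins2) {
  g <- expand.grid(i = bins1, j = bins2)
  i <- pmin(g$i, g$j); d <- abs(g$j - g$i)
  ok <- i >= 1 & i <= nrow(band) & d <= ncol(band) - 1L
  out <- rep(NA_real_, nrow(g))
  out[ok] <- band[cbind(i[ok], d[ok] + 1L)]
  out
}

#' Score a peak pair from a predicted map
#'
#' Reduces the predicted values over all associated bin pairs; default
#' reduction is the maximum (min and mean available).
#'
#' @param pred predicted [zscore_map()] or band matrix.
#' @param bins1,bins2 bin sets of the two peaks.
#' @param reduce `"max"`, `"min"` or `"mean"`.
#' @return scalar score (NA if no bin pair is defined).
#' @export
peak_pair_score <- function(pred, bins1, bins2, reduce = c("max", "min", "mean")) {
  reduce <- match.arg(reduce)
  v <- band_lookup(as_band(pred), bins1, bins2)
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  switch(reduce, max = max(v), min = min(v), mean = mean(v))
}

#' Peak-level AUPRC/AUROC with a distance constraint
#'
#' Restricts peak pairs to genomic distances up to `max_distance` (default
#' 500 kb, for comparability with co-accessibility methods), then computes
#' the areas. Same-bin (distance-0) pairs are excluded.
#'
#' @param scores numeric peak-pair scores.
#' @param labels logical labels (NA entries dropped).
#' @param distances genomic distance of each pair in bp.
#' @param max_distance distance cap in bp (default 5e5).
#' @return list with `auprc`, `auroc`, `n_pairs`; areas are NA when a
#'   single class remains.
#' @export
peak_level_auc <- function(scores, labels, distances, max_distance = 5e5) {
  keep <- !is.na(labels) & !is.na(scores) & distances <= max_distance &
    distances > 0
  s <- scores[keep]; y <- as.logical(labels[keep])
  list(auprc = auprc(s, y), auroc = auroc(s, y), n_pairs = sum(keep))
}

#' Insulation score
#'
#' Mean contact signal in the square `[b - w, b] x [b, b + w]` sliding along
#' the diagonal; local minima mark domain boundaries. Bins within `w` of
#' either chromosome end are NA.
#'
#' @param map a [contact_map()] or [zscore_map()].
#' @param window_bins half-window `w` in bins (default 30).
#' @return numeric per-bin vector.
#' @export
insulation_score <- function(map, window_bins = 30L) {
  w <- window_bins
  if (inherits(map, "contact_map")) {
    n <- map$n_bins
    M <- as.matrix(map$mat)
    M <- M + t(M) - diag(diag(M))
  } else {
    n <- map$n_bins
    M <- matrix(0, n, n)
    B <- map$band
    for (d in 0:(ncol(B) - 1L)) {
      i <- seq_len(max(n - d, 0L))
      v <- B[i, d + 1L]
      v[is.na(v)] <- 0
      M[cbind(i, i + d)] <- v
      M[cbind(i + d, i)] <- v
    }
  }
  if (w >= n) stop("window_bins must be smaller than the number of bins")
  out <- rep(NA_real_, n)
  for (b in (w + 1L):(n - w)) {
    out[b] <- mean(M[(b - w):b, b:(b + w)])
  }
  out
}

#' Paired t-test between per-chromosome metrics
#'
#' Two-sided paired t-test on per-chromosome metric values of two models.
#' Zero-variance differences are flagged: all-zero differences give t = 0,
#' p = 1; constant nonzero differences give infinite t, p = 0.
#'
#' @param metric_a,metric_b equal-length numeric vectors (>= 2 values).
#' @return list with `t`, `p`, `mean_diff`, `flag`.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2)
    stop("need equal-length vectors of at least 2 values")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, mean_diff = 0, flag = "no-difference"))
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                flag = "zero-variance"))
  }
  ht <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_diff = unname(ht$estimate), flag = "ok")
}
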