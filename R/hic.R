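#' Distance-stratified Z-score normalization (stand-in)
#'
#' Normalizes raw contact counts into per-distance Z-scores of `log1p`
#' counts: for every genomic distance `d`, `z = (log1p(x) - mean_d) / sd_d`
#' computed over the unmasked pairs at that distance. Distances with zero
#' variance yield `z = 0`. This is a deliberately simple substitute for
#' covariate-aware negative-binomial normalization; precomputed Z-scores
#' from such a pipeline can be loaded directly with [read_contact_table()]
#' and [cm_to_zscore_map()].
#'
#' @param counts a [contact_map()] of raw counts.
#' @param max_distance maximum distance in bp (default 2e6).
#' @param mask optional [low_signal_mask()]; masked bins are excluded from
#'   the per-distance statistics and set `NA` in the output.
#' @return a [zscore_map()].
#' @export
distance_stratified_zscore <- function(counts, max_distance = 2e6,
                                       mask = NULL) {
  max_d <- as.integer(max_distance %/% counts$resolution)
  if (max_d > counts$n_bins - 1L) {
    warning("max_distance exceeds chromosome span; truncating")
    max_d <- counts$n_bins - 1L
  }
  B <- log1p(cm_band(counts, max_d))
  if (!is.null(mask)) {
    bad <- which(mask$masked)
    for (d in 0:max_d) {
      rows <- seq_len(max(counts$n_bins - d, 0L))
      drop <- rows %in% bad | (rows + d) %in% bad
      B[rows[drop], d + 1L] <- NA
    }
  }
  mu <- colMeans(B, na.rm = TRUE)
  sd <- apply(B, 2, stats::sd, na.rm = TRUE)
  Z <- sweep(B, 2, mu, "-")
  Z <- sweep(Z, 2, ifelse(is.na(sd) | sd == 0, 1, sd), "/")
  Z[, which(is.na(sd) | sd == 0)] <- ifelse(
    is.na(B[, which(is.na(sd) | sd == 0), drop = FALSE]), NA, 0)
  zscore_map(counts$chrom, counts$resolution, Z)
}

#' Clip Z-score targets to fixed bounds
#'
#' Outlier target values are clipped to `[lo, hi]` (default `[-16, 16]`) to
#' avoid training bias from extreme scores. Idempotent.
#'
#' @param z a [zscore_map()].
#' @param lo,hi clip bounds.
#' @return the clipped `zscore_map` with `clipped = TRUE`.
#' @export
clip_targets <- function(z, lo = -16, hi = 16) {
  if (lo >= hi) stop("lo must be < hi")
  z$band <- pmin(pmax(z$band, lo), hi)
  z$clipped <- TRUE
  z
}

#' Mask low-signal bins of a contact map
#'
#' Bins whose marginal (row plus column) contact total is zero, or at most
#' the `quantile`-quantile of the nonzero marginals, are masked: they carry
#' no reliable signal (low mappability) and are excluded from training
#' targets and metrics.
#'
#' @param counts a [contact_map()] of raw counts.
#' @param quantile fraction of nonzero-marginal bins additionally masked
#'   (default 0.01).
#' @return an object of class `bin_mask`: list with logical `masked`,
#'   `marginals`, and the rule parameters.
#' @export
low_signal_mask <- function(counts, quantile = 0.01) {
  marg <- Matrix::rowSums(counts$mat) + Matrix::colSums(counts$mat) -
    Matrix::diag(counts$mat)
  nz <- marg[marg > 0]
  thr <- if (length(nz)) stats::quantile(nz, quantile, names = FALSE) else 0
  masked <- marg == 0 | (quantile > 0 & marg <= thr)
  structure(list(masked = masked, marginals = marg, quantile = quantile,
                 threshold = thr),
            class = "bin_mask")
}

#' One-sided V-stripe target for a center bin
#'
#' The training/inference target: contact values between bin `t` and bins
#' `t +/- d` for `d = 0..max_d` (the diagonal entry is included at `d = 0`).
#' Entries whose partner bin is off-chromosome, or where either bin is
#' masked, are invalid.
#'
#' @param z a [zscore_map()].
#' @param t center bin (1-based).
#' @param side `"right"` (`t + d`) or `"left"` (`t - d`).
#' @param mask optional [low_signal_mask()].
#' @param max_d stripe length minus one, in bins (default: the map's own
#'   maximum distance; use the model geometry's `max_distance_bins` when the
#'   map extends further).
#' @return list with `values` (length `max_d + 1`, `NA` where invalid),
#'   `valid` logical vector, `t`, `side`.
#' @export
target_vstripe <- function(z, t, side = c("right", "left"), mask = NULL,
                           max_d = z$max_d) {
  side <- match.arg(side)
  if (max_d > z$max_d) stop("max_d exceeds the map's distance range")
  d <- 0:max_d
  partner <- if (side == "right") t + d else t - d
  ok <- partner >= 1L & partner <= z$n_bins
  values <- rep(NA_real_, length(d))
  values[ok] <- zs_value(z, rep(t, sum(ok)), partner[ok])
  if (!is.null(mask)) {
    bad <- mask$masked[t] | ifelse(ok, mask$masked[pmax(partner, 1L)], TRUE)
    values[bad] <- NA
  }
  list(values = values, valid = !is.na(values), t = t, side = side)
}

#' Label top-fraction significant interactions
#'
#' Marks exactly `floor(top_fraction * n)` of the `n` valid (finite,
#' unmasked) pairs of a Z-score map as significant, chosen by descending
#' score with a deterministic lexicographic `(i, j)` tie-break. Invariant to
#' any strictly monotone transform of the scores.
#'
#' @param z a [zscore_map()].
#' @param top_fraction fraction labeled positive (default 0.10).
#' @return logical band matrix (same shape as `z$band`; `NA` where the pair
#'   is invalid).
#' @export
label_significant_bins <- function(z, top_fraction = 0.10) {
  B <- z$band
  idx <- which(!is.na(B))
  n_pos <- floor(top_fraction * length(idx))
  lab <- matrix(NA, nrow(B), ncol(B))
  lab[idx] <- FALSE
  if (n_pos > 0) {
    i <- ((idx - 1L) %% nrow(B)) + 1L
    d <- ((idx - 1L) %/% nrow(B))
    j <- i + d
    ord <- order(-B[idx], i, j)
    lab[idx[ord[seq_len(n_pos)]]] <- TRUE
  }
  lab
}
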