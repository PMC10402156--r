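#' Model geometry
#'
#' Bundles every resolution and window-length constant used by the model and
#' its data pipeline. The default geometry works at genome scale: contact maps
#' at 10 kb, accessibility/CTCF tracks at 50 bp, co-accessibility at 500 bp,
#' a 4.01 Mb input window (401 contact bins) and a one-sided output stripe
#' covering distances 0..2 Mb (201 entries, diagonal included). All fields are
#' derived from the three resolutions plus the window size, so a miniature
#' geometry with the same ratios (see [miniature_geometry()]) exercises
#' identical code paths at desk scale.
#'
#' @param hic_resolution contact-map bin size in bp.
#' @param acc_resolution accessibility/CTCF track bin size in bp.
#' @param coacc_resolution co-accessibility bin size in bp.
#' @param hic_window_bins number of contact bins in the input window (odd).
#' @param pool_schedule integer pooling factors inside feature extractor 1;
#'   their product must equal `hic_resolution / acc_resolution`.
#' @param pool_after indices of the conv blocks (out of 15) after which the
#'   pooling factors are applied; default spreads them evenly.
#'
#' @return an object of class `model_geometry`.
#' @export
model_geometry <- function(hic_resolution = 10000L,
                           acc_resolution = 50L,
                           coacc_resolution = 500L,
                           hic_window_bins = 401L,
                           pool_schedule = c(2L, 2L, 2L, 5L, 5L),
                           pool_after = NULL) {
  hic_resolution <- as.integer(hic_resolution)
  acc_resolution <- as.integer(acc_resolution)
  coacc_resolution <- as.integer(coacc_resolution)
  hic_window_bins <- as.integer(hic_window_bins)
  if (hic_window_bins %% 2L != 1L)
    stop("hic_window_bins must be odd (window centered on one bin)")
  if (hic_resolution %% acc_resolution != 0L ||
      hic_resolution %% coacc_resolution != 0L ||
      coacc_resolution %% acc_resolution != 0L)
    stop("resolutions must nest: acc | coacc | hic")
  reduction_factor <- hic_resolution %/% acc_resolution
  if (prod(pool_schedule) != reduction_factor)
    stop("prod(pool_schedule) must equal hic_resolution/acc_resolution (",
         reduction_factor, ")")
  if (is.null(pool_after))
    pool_after <- round(seq_along(pool_schedule) * 15L / length(pool_schedule))
  if (length(pool_after) != length(pool_schedule) || any(pool_after > 15L))
    stop("pool_after must give one conv-block index (<= 15) per pool factor")
  max_distance_bins <- (hic_window_bins - 1L) %/% 2L
  g <- list(
    hic_resolution = hic_resolution,
    acc_resolution = acc_resolution,
    coacc_resolution = coacc_resolution,
    hic_window_bins = hic_window_bins,
    window_bp = hic_window_bins * hic_resolution,
    max_distance_bins = max_distance_bins,
    max_distance_bp = max_distance_bins * hic_resolution,
    out_len = max_distance_bins + 1L,
    acc_window_len = hic_window_bins * reduction_factor,
    reduction_factor = reduction_factor,
    coacc_per_hic = hic_resolution %/% coacc_resolution,
    coacc_window_len = hic_window_bins * (hic_resolution %/% coacc_resolution),
    center_coacc_bins = hic_resolution %/% coacc_resolution,
    pool_schedule = as.integer(pool_schedule),
    pool_after = as.integer(pool_after)
  )
  class(g) <- "model_geometry"
  g
}

#' Miniature geometry for desk-scale tests
#'
#' Same resolutions and ratios as the default geometry but a 0.41 Mb window
#' (41 contact bins, 21-entry output stripe), so a full train/predict cycle
#' runs in seconds on one CPU. The pooling schedule front-loads the large
#' factors so the long 50bp stage shrinks early (a pure efficiency choice;
#' the product is the same 200x reduction).
#'
#' @return a `model_geometry`.
#' @export
miniature_geometry <- function() {
  model_geometry(hic_window_bins = 41L,
                 pool_schedule = c(5L, 5L, 2L, 2L, 2L),
                 pool_after = 1:5)
}

#' @export
print.model_geometry <- function(x, ...) {
  cat("model_geometry:",
      x$window_bp / 1e6, "Mb window =", x$hic_window_bins, "bins @",
      x$hic_resolution, "bp; stripe length", x$out_len,
      "; acc window", x$acc_window_len, "@", x$acc_resolution,
      "bp; coacc window", x$coacc_window_len, "@", x$coacc_resolution,
      "bp\n")
  invisible(x)
}
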