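#' Stripe predictor interface
#'
#' [predict_chromosome()] only needs an object that can produce left/right
#' V-stripes for a center bin. The trained model implements this; so does a
#' ground-truth oracle ([stripe_oracle()]) that reads the stripes straight
#' from a Z-score map — assembling oracle stripes must reproduce the masked
#' map exactly, which isolates stitching bugs from model error.
#'
#' @param object a `chromafold_model` or `stripe_oracle`.
#' @param dataset a [contact_dataset()].
#' @param t center bin.
#' @param ... method-specific arguments.
#' @return list with `left` and `right` numeric vectors (NA = no
#'   prediction).
#' @export
predict_stripes <- function(object, dataset, t, ...) {
  UseMethod("predict_stripes")
}

#' @rdname predict_stripes
#' @param prep precomputed inference inputs from [prepare_inference()].
#' @param stage `"full"` or `"stage1"`.
#' @param zero_coacc replace the co-accessibility input by zeros (ablation).
#' @export
predict_stripes.chromafold_model <- function(object, dataset, t,
                                             prep = NULL, stage = "full",
                                             zero_coacc = FALSE, ...) {
  if (stage == "full" && !"stage2" %in% object$trained_stages &&
      !"finetune" %in% object$trained_stages)
    stop("model has not been trained (run train_stage1/train_stage2)")
  g <- object$geometry
  if (is.null(prep)) prep <- prepare_inference(dataset, g)
  acc <- extract_window(prep$pb, t, g, resolution = g$acc_resolution)
  ctcf <- extract_window(prep$ctcf, t, g, resolution = g$acc_resolution)
  coacc <- if (zero_coacc)
    matrix(0, g$center_coacc_bins, g$coacc_window_len)
  else coaccess_slice(prep$profiles, t, g)
  ex <- list(acc_ctcf = cbind(acc, ctcf), coacc = coacc)
  predict_vstripe(object, ex, stage = stage)
}

#' @rdname predict_stripes
#' @export
stripe_oracle <- function(zmap, mask = NULL) {
  structure(list(zmap = zmap, mask = mask), class = "stripe_oracle")
}

#' @rdname predict_stripes
#' @export
predict_stripes.stripe_oracle <- function(object, dataset, t, ...) {
  list(right = target_vstripe(object$zmap, t, "right", object$mask)$values,
       left = target_vstripe(object$zmap, t, "left", object$mask)$values)
}

#' Precompute population-level inference inputs
#'
#' Full-population pseudobulk and CTCF tracks plus full metacell profiles;
#' they do not depend on the window center, so they are computed once per
#' chromosome.
#'
#' @param dataset a [contact_dataset()].
#' @param geometry a [model_geometry()].
#' @param scale pseudobulk scale.
#' @return list with `pb`, `ctcf`, `profiles`.
#' @export
prepare_inference <- function(dataset, geometry, scale = 1e8) {
  pb <- pseudobulk_from_matrix(dataset$acc_counts,
                               seq_len(nrow(dataset$acc_counts)),
                               dataset$chrom, geometry$acc_resolution,
                               scale = scale)
  list(pb = pb$values, ctcf = dataset$ctcf$values,
       profiles = dataset$profiles)
}

#' Chromosome-wide contact-map prediction by V-stripe assembly
#'
#' Predicts both sides of the V-stripe for every center bin (full
#' population, no augmentation; inputs zero-padded beyond the chromosome
#' edges), then assembles the map: pair `(i, j)` at distance `d` averages
#' the right-stripe prediction from center `i` and the left-stripe
#' prediction from center `j`; the diagonal averages the two `d = 0`
#' estimates; entries with a single available prediction use it alone, and
#' pairs with none are reported as `NA`, not zero.
#'
#' @param object a `chromafold_model` or `stripe_oracle`.
#' @param dataset a [contact_dataset()].
#' @param centers optional subset of center bins (default: all bins).
#' @param ... passed to [predict_stripes()] (e.g. `stage`, `zero_coacc`).
#' @return a [zscore_map()] of predictions.
#' @export
predict_chromosome <- function(object, dataset, centers = NULL, ...) {
  res <- dataset$zmap$resolution
  n <- bin_count(dataset$layout, dataset$chrom, res)
  g <- if (inherits(object, "chromafold_model")) object$geometry else NULL
  max_d <- if (!is.null(g)) g$max_distance_bins else dataset$zmap$max_d
  if (is.null(centers)) centers <- seq_len(n)
  prep <- if (inherits(object, "chromafold_model"))
    prepare_inference(dataset, g) else NULL
  acc <- matrix(0, n, max_d + 1L)
  cnt <- matrix(0L, n, max_d + 1L)
  for (t in centers) {
    st <- if (is.null(prep)) predict_stripes(object, dataset, t, ...)
          else predict_stripes(object, dataset, t, prep = prep, ...)
    d <- 0:max_d
    # right stripe of t covers pairs (t, t + d)
    ok <- !is.na(st$right) & (t + d) <= n
    if (any(ok)) {
      acc[t, which(ok)] <- acc[t, which(ok)] + st$right[ok]
      cnt[t, which(ok)] <- cnt[t, which(ok)] + 1L
    }
    # left stripe of t covers pairs (t - d, t)
    ok <- !is.na(st$left) & (t - d) >= 1
    if (any(ok)) {
      rows <- t - d[ok]
      idx <- cbind(rows, which(ok))
      acc[idx] <- acc[idx] + st$left[ok]
      cnt[idx] <- cnt[idx] + 1L
    }
  }
  band <- ifelse(cnt > 0, acc / cnt, NA_real_)
  zscore_map(dataset$chrom, res, band, clipped = FALSE)
}

#' Per-cluster deconvolution of a bulk contact map
#'
#' Applies a (fine-tuned) model to each cluster's own cells and metacells to
#' produce cluster-specific predicted maps. Each cluster is predicted from
#' its own dataset only.
#'
#' @param model a fine-tuned [chromafold_model()].
#' @param cluster_datasets named list of per-cluster [contact_dataset()].
#' @param centers optional subset of center bins.
#' @param min_cells warn when a cluster has fewer cells than this (default
#'   500; populations of ~1500 cells are known to work).
#' @param ... passed to [predict_chromosome()].
#' @return named list of predicted [zscore_map()]s.
#' @export
deconvolve_clusters <- function(model, cluster_datasets, centers = NULL,
                                min_cells = 500L, ...) {
  lapply(cluster_datasets, function(ds) {
    if (nrow(ds.acc <- ds$acc_counts) < min_cells)
      warning("cluster has only ", nrow(ds.acc), " cells (< ", min_cells, ")")
    predict_chromosome(model, ds, centers = centers, ...)
  })
}
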