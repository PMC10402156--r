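#' Per-chromosome training/inference dataset
#'
#' Bundles everything the model needs for one chromosome and one cell
#' population: per-cell insertion counts at accessibility resolution, the
#' binarized 500bp cell-by-bin matrix, metacell assignment and profiles, the
#' CTCF track, and the (clipped) Z-score target map with its low-signal
#' mask. Training draws augmented examples from it; inference uses the full
#' population.
#'
#' @param chrom chromosome name.
#' @param layout a [genome_layout()].
#' @param acc_counts sparse cells x bins matrix of insertion counts at
#'   `acc_resolution`.
#' @param cell_bins binary cells x bins matrix at `coacc_resolution`.
#' @param ctcf a `bin_track` (motif or ChIP) at `acc_resolution`.
#' @param zmap a [zscore_map()] target (will be clipped if not already).
#' @param mask a [low_signal_mask()] (or NULL for no masking).
#' @param metacells a [build_metacells()] assignment.
#' @param clip clip bounds applied to the target (default c(-16, 16)).
#' @return an object of class `contact_dataset`.
#' @export
contact_dataset <- function(chrom, layout, acc_counts, cell_bins, ctcf,
                            zmap, mask = NULL, metacells = NULL,
                            clip = c(-16, 16)) {
  if (!is.null(zmap) && !zmap$clipped)
    zmap <- clip_targets(zmap, clip[1], clip[2])
  profiles <- if (!is.null(metacells))
    metacell_profiles(cell_bins, metacells) else NULL
  structure(list(chrom = chrom, layout = layout, acc_counts = acc_counts,
                 cell_bins = cell_bins, ctcf = ctcf, zmap = zmap,
                 mask = mask, metacells = metacells, profiles = profiles,
                 n_cells = nrow(acc_counts)),
            class = "contact_dataset")
}

# metacell profiles as a plain dense matrix: they are ~50 percent dense, so the
# sparse form wins nothing and per-window column slicing is much faster dense
densify_profiles <- function(dataset) {
  if (!is.null(dataset$profiles) && !is.matrix(dataset$profiles))
    dataset$profiles <- as.matrix(dataset$profiles)
  dataset
}

#' @export
print.contact_dataset <- function(x, ...) {
  cat("contact_dataset", x$chrom, ":", x$n_cells, "cells,",
      if (!is.null(x$metacells)) length(x$metacells$members) else 0,
      "metacells,", if (!is.null(x$zmap)) "with" else "no", "target map\n")
  invisible(x)
}

#' Attach metacells to a dataset
#'
#' Builds the LSI embedding and kNN metacells from the dataset's own 500bp
#' matrix and precomputes the binary metacell profiles.
#'
#' @param dataset a `contact_dataset`.
#' @param k cells per metacell.
#' @param overlap_cap see [build_metacells()].
#' @param n_components LSI dimension.
#' @param seed RNG seed.
#' @return the dataset with `metacells` and `profiles` filled in.
#' @export
add_metacells <- function(dataset, k = 50L, overlap_cap = 0.76,
                          n_components = 30L, seed = 1L) {
  k <- min(k, nrow(dataset$cell_bins))
  emb <- lsi_embedding(dataset$cell_bins,
                       min(n_components, nrow(dataset$cell_bins) - 1L))
  dataset$metacells <- build_metacells(emb, k = k, overlap_cap = overlap_cap,
                                       seed = seed)
  dataset$profiles <- metacell_profiles(dataset$cell_bins, dataset$metacells)
  densify_profiles(dataset)
}
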