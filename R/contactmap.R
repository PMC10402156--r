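#' Sparse per-chromosome contact map
#'
#' Upper-triangular sparse storage of an intra-chromosomal contact matrix
#' (raw counts or normalized scores) with symmetric access: `cm_value(m, i, j)
#' == cm_value(m, j, i)` and absent pairs read as 0. Duplicate triplets are
#' summed on construction so both-triangle dumps collapse correctly.
#'
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param n_bins number of bins on the chromosome.
#' @param i,j 1-based bin indices (any triangle).
#' @param value numeric values.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(chrom, resolution, n_bins, i = integer(),
                        j = integer(), value = numeric()) {
  if (length(i) != length(j) || length(i) != length(value))
    stop("i, j, value must have equal length")
  ii <- pmin(i, j); jj <- pmax(i, j)
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(value),
                              dims = c(n_bins, n_bins))  # dups summed
  structure(list(chrom = chrom, resolution = as.integer(resolution),
                 n_bins = as.integer(n_bins), mat = mat),
            class = "contact_map")
}

#' @rdname contact_map
#' @param m a `contact_map`.
#' @export
cm_value <- function(m, i, j) {
  ii <- pmin(i, j); jj <- pmax(i, j)
  as.numeric(m$mat[cbind(ii, jj)])
}

#' Nonzero upper-triangle triplets of a contact map
#'
#' @param m a `contact_map`.
#' @return data.frame with i, j (1-based, i <= j) and value.
#' @export
cm_triplets <- function(m) {
  t <- methods::as(m$mat, "TsparseMatrix")
  ord <- order(t@i, t@j)
  data.frame(i = t@i[ord] + 1L, j = t@j[ord] + 1L, value = t@x[ord])
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map", x$chrom, "@", x$resolution, "bp:", x$n_bins, "bins,",
      length(x$mat@x), "stored pairs\n")
  invisible(x)
}

#' Band view of a contact map
#'
#' Matrix `B` with `B[i, d+1] = value(i, i+d)` for distances `d = 0..max_d`;
#' entries whose partner bin falls beyond the chromosome end are `NA`. Bands
#' are the working representation for distance-stratified operations (each
#' distance is one column).
#'
#' @param m a `contact_map`.
#' @param max_d maximum distance in bins.
#' @return numeric matrix `n_bins x (max_d + 1)`.
#' @export
cm_band <- function(m, max_d) {
  n <- m$n_bins
  B <- matrix(NA_real_, n, max_d + 1L)
  for (d in 0:max_d) {
    k <- n - d
    if (k <= 0) break
    B[seq_len(k), d + 1L] <- cm_value(m, seq_len(k), seq_len(k) + d)
  }
  B
}

#' Z-score map stored as a distance band
#'
#' Normalized contact values held as a band matrix (`band[i, d+1]` is the
#' score of pair `(i, i+d)`), with `NA` marking pairs that are out of range,
#' masked, or never predicted.
#'
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param band numeric matrix n_bins x (max_d + 1).
#' @param clipped logical: have clip bounds been applied?
#' @return an object of class `zscore_map`.
#' @export
zscore_map <- function(chrom, resolution, band, clipped = FALSE) {
  structure(list(chrom = chrom, resolution = as.integer(resolution),
                 n_bins = nrow(band), max_d = ncol(band) - 1L,
                 band = band, clipped = clipped),
            class = "zscore_map")
}

#' @rdname zscore_map
#' @param z a `zscore_map`.
#' @param i,j 1-based bin indices.
#' @export
zs_value <- function(z, i, j) {
  ii <- pmin(i, j); d <- abs(j - i)
  out <- rep(NA_real_, length(ii))
  ok <- d <= z$max_d & ii >= 1 & pmax(i, j) <= z$n_bins
  out[ok] <- z$band[cbind(ii[ok], d[ok] + 1L)]
  out
}

#' Convert a zscore_map band to a contact_map (dropping NA entries)
#'
#' @param z a `zscore_map`.
#' @return a `contact_map` holding the defined band entries.
#' @export
zs_to_contact_map <- function(z) {
  idx <- which(!is.na(z$band), arr.ind = TRUE)
  i <- idx[, 1]; d <- idx[, 2] - 1L
  contact_map(z$chrom, z$resolution, z$n_bins, i, i + d, z$band[idx])
}

#' Convert a contact_map into a zscore_map band
#'
#' @param m a `contact_map`.
#' @param max_d maximum distance in bins.
#' @param clipped logical flag carried over.
#' @return a `zscore_map`.
#' @export
cm_to_zscore_map <- function(m, max_d, clipped = FALSE) {
  zscore_map(m$chrom, m$resolution, cm_band(m, max_d), clipped = clipped)
}

#' @export
print.zscore_map <- function(x, ...) {
  cat("zscore_map ", x$chrom, " @ ", x$resolution, "bp: ", x$n_bins,
      " bins, distances 0..", x$max_d, if (x$clipped) " (clipped)" else "",
      "\n", sep = "")
  invisible(x)
}
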