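#' Binarized cell-by-bin accessibility matrix
#'
#' Entry (c, b) is 1 iff cell c has at least one Tn5 insertion in 500bp bin
#' b. This is the substrate for metacell construction and Jaccard
#' co-accessibility.
#'
#' @param fragments fragments table (see [read_fragments()]).
#' @param cells a `cell_set` or barcode vector.
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @param resolution bin size in bp (default 500).
#' @return sparse `ngCMatrix`-like binary `dgCMatrix`, cells x bins; row
#'   order follows the barcode order of `cells`.
#' @export
binarize_cells <- function(fragments, cells, layout, chrom,
                           resolution = 500L) {
  barcodes <- if (inherits(cells, "cell_set")) cells$barcodes else cells
  m <- insertion_matrix(fragments, barcodes, layout, chrom, resolution)
  binarize_matrix(m)
}

# clamp a nonnegative sparse matrix to {0,1}
binarize_matrix <- function(m) {
  m@x <- rep(1, length(m@x))
  m <- Matrix::drop0(m)
  m
}

#' LSI embedding of cells (TF-IDF + truncated SVD)
#'
#' A deliberately simple stand-in for iterative-LSI pipelines: term-frequency
#' scaling per cell, log-IDF per bin, then a rank-`n_components` SVD. Used
#' only to supply a low-dimensional space for metacell kNN.
#'
#' @param cell_by_tile binary (or count) cells x bins matrix.
#' @param n_components embedding dimension (default 30).
#' @return cells x n_components matrix of singular-vector coordinates
#'   (scaled by singular values).
#' @export
lsi_embedding <- function(cell_by_tile, n_components = 30L) {
  m <- methods::as(cell_by_tile, "CsparseMatrix")
  if (nrow(m) < n_components + 1)
    stop("need at least n_components + 1 cells")
  keep <- Matrix::colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  rs <- Matrix::rowSums(m)
  rs[rs == 0] <- 1
  tf <- m / rs
  idf <- log1p(nrow(m) / Matrix::colSums(m > 0))
  x <- tf %*% Matrix::Diagonal(x = idf)
  k <- min(n_components, min(dim(x)) - 1L)
  if (k < n_components)
    warning("degenerate rank: using ", k, " components instead of ",
            n_components)
  sv <- svd(as.matrix(x), nu = k, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(emb) <- rownames(cell_by_tile)
  emb
}

#' Build overlapping metacells by kNN with an overlap cap
#'
#' Cicero-style grouping: candidate seed cells are visited in random order;
#' each seed proposes its k-nearest-neighbor set (including itself, Euclidean
#' distance in the embedding); the set is accepted iff its shared-member
#' fraction with every previously accepted metacell is at most `overlap_cap`.
#'
#' @param embedding cells x d matrix.
#' @param k cells per metacell (default 50).
#' @param overlap_cap maximum shared fraction between any two accepted
#'   metacells (default 0.76).
#' @param seed integer RNG seed for the candidate order.
#' @return an object of class `metacell_assignment`: list with `members`
#'   (list of integer cell-index vectors), `k`, `overlap_cap`.
#' @export
build_metacells <- function(embedding, k = 50L, overlap_cap = 0.76,
                            seed = 1L) {
  n <- nrow(embedding)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  order_cand <- withr_seed(seed, sample.int(n))
  accepted <- list()
  accepted_mat <- NULL  # n x n_accepted logical membership for fast overlap
  for (s in order_cand) {
    d2 <- colSums((t(embedding) - embedding[s, ])^2)
    nn <- order(d2, seq_len(n))[seq_len(k)]  # ties broken by cell index
    memb <- logical(n); memb[nn] <- TRUE
    if (length(accepted)) {
      shared <- as.numeric(crossprod(accepted_mat, memb)) / k
      if (any(shared > overlap_cap)) next
    }
    accepted[[length(accepted) + 1L]] <- sort(nn)
    accepted_mat <- cbind(accepted_mat, memb)
  }
  structure(list(members = accepted, k = as.integer(k),
                 overlap_cap = overlap_cap),
            class = "metacell_assignment")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Binary metacell accessibility profiles
#'
#' Metacell m has bin b accessible iff any member cell does (OR aggregation;
#' a stricter threshold `t >= 1` on the member count is available).
#'
#' @param cell_by_bin binary cells x bins matrix.
#' @param assignment a `metacell_assignment`.
#' @param threshold minimum number of accessible member cells (default 1).
#' @return binary metacells x bins `dgCMatrix`.
#' @export
metacell_profiles <- function(cell_by_bin, assignment, threshold = 1L) {
  memb <- assignment$members
  n_mc <- length(memb)
  ind <- Matrix::sparseMatrix(
    i = rep(seq_len(n_mc), lengths(memb)),
    j = unlist(memb), x = 1,
    dims = c(n_mc, nrow(cell_by_bin)))
  counts <- ind %*% cell_by_bin
  counts@x <- as.numeric(counts@x >= threshold)
  Matrix::drop0(counts)
}

#' Jaccard co-accessibility between two bin sets
#'
#' For metacell profiles `P` (binary, metacells x bins), computes
#' `J(i, j) = |P.,i AND P.,j| / |P.,i OR P.,j|` for every i in `center_bins`
#' and j in `window_bins`; 0/0 is defined as 0. Out-of-range window indices
#' (`< 1` or beyond the matrix) yield zero columns, implementing
#' zero-padding at chromosome edges.
#'
#' @param profiles binary metacells x bins matrix.
#' @param center_bins integer bin indices (rows of the slice).
#' @param window_bins integer bin indices (columns of the slice); may run
#'   off either end of the chromosome.
#' @return dense numeric matrix `length(center_bins) x length(window_bins)`
#'   with values in `[0, 1]`.
#' @export
jaccard_coaccessibility <- function(profiles, center_bins, window_bins) {
  nb <- ncol(profiles)
  ok <- window_bins >= 1L & window_bins <= nb
  A <- profiles[, center_bins, drop = FALSE]
  B <- profiles[, window_bins[ok], drop = FALSE]
  inter <- as.matrix(Matrix::crossprod(A, B))
  nA <- Matrix::colSums(A); nB <- Matrix::colSums(B)
  union <- outer(nA, nB, "+") - inter
  Jok <- ifelse(union > 0, inter / union, 0)
  J <- matrix(0, length(center_bins), length(window_bins))
  J[, ok] <- Jok
  J
}

#' Co-accessibility input slice for one prediction window
#'
#' The model input: Jaccard similarity between the `coacc_per_hic` 500bp bins
#' of the center contact bin and all 500bp bins of the full window, with
#' zero-padding beyond the chromosome edges.
#'
#' @param profiles binary metacells x bins matrix (500bp bins, whole
#'   chromosome).
#' @param center_hic_bin 1-based contact bin at the window center.
#' @param geometry a [model_geometry()].
#' @param metacells optional integer subset of metacells to use (training
#'   augmentation); default all. Column slices of the sparse profile matrix
#'   are taken first, so the per-example cost does not depend on the
#'   chromosome length.
#' @return matrix `center_coacc_bins x coacc_window_len`.
#' @export
coaccess_slice <- function(profiles, center_hic_bin, geometry,
                           metacells = NULL) {
  f <- geometry$coacc_per_hic
  center_bins <- ((center_hic_bin - 1L) * f + 1L):(center_hic_bin * f)
  first <- (center_hic_bin - 1L - geometry$max_distance_bins) * f + 1L
  window_bins <- seq.int(first, length.out = geometry$coacc_window_len)
  nb <- ncol(profiles)
  center_ok <- center_bins >= 1L & center_bins <= nb
  window_ok <- window_bins >= 1L & window_bins <= nb
  J <- matrix(0, length(center_bins), length(window_bins))
  if (!any(center_ok)) return(J)
  A <- profiles[, center_bins[center_ok], drop = FALSE]
  B <- profiles[, window_bins[window_ok], drop = FALSE]
  if (!is.matrix(A)) { A <- as.matrix(A); B <- as.matrix(B) }
  if (!is.null(metacells)) {
    A <- A[metacells, , drop = FALSE]
    B <- B[metacells, , drop = FALSE]
  }
  inter <- crossprod(A, B)
  union <- outer(colSums(A), colSums(B), "+") - inter
  Jok <- ifelse(union > 0, inter / union, 0)
  J[center_ok, window_ok] <- Jok
  J
}

#' Random subsample for training augmentation
#'
#' Draws `n ~ Uniform{range[1]..range[2]}` elements uniformly without
#' replacement (with replacement only when the population is smaller than
#' the lower bound).
#'
#' @param pool integer vector (or its length) to sample from.
#' @param n_range length-2 integer range of the subsample size.
#' @return integer vector of sampled elements (indices when `pool` is a
#'   length).
#' @export
subsample_for_augmentation <- function(pool, n_range) {
  if (length(pool) == 1 && is.numeric(pool)) pool <- seq_len(pool)
  if (length(pool) == 0) stop("empty population")
  n <- sample.int(n_range[2] - n_range[1] + 1L, 1L) + n_range[1] - 1L
  if (length(pool) < n_range[1]) {
    sample(pool, n_range[1], replace = TRUE)
  } else {
    n <- min(n, length(pool))
    sample(pool, n)
  }
}
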