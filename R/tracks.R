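#' Filter cell barcodes on QC thresholds
#'
#' Keeps barcodes with at least `min_fragments` fragments and, when a TSS
#' enrichment column is available, TSS score of at least `min_tss` (the
#' exclusion rules are strict: "fewer than 1000 fragments" and "TSS < 4" are
#' removed, so a cell exactly at a threshold is kept). TSS enrichment is
#' accepted as a precomputed column; it is not computed here.
#'
#' @param barcode_stats data.frame with columns `barcode`, `n_fragments` and
#'   optionally `tss`.
#' @param min_fragments minimum fragment total (default 1000).
#' @param min_tss minimum TSS enrichment (default 4); `NULL` disables the
#'   TSS filter.
#' @return an object of class `cell_set`: list with `barcodes` and the
#'   filtered `stats` table.
#' @export
filter_cells <- function(barcode_stats, min_fragments = 1000, min_tss = 4) {
  st <- data.table::as.data.table(barcode_stats)
  if (!all(c("barcode", "n_fragments") %in% names(st)))
    stop("barcode_stats needs columns 'barcode' and 'n_fragments'")
  fail_frag <- st$n_fragments < min_fragments
  fail_tss <- rep(FALSE, nrow(st))
  if (!is.null(min_tss)) {
    if ("tss" %in% names(st)) fail_tss <- st$tss < min_tss
    # no TSS column: fragment filter only
  }
  keep <- !(fail_frag | fail_tss)
  if (!any(keep))
    stop("no cells pass QC: ", sum(fail_frag), " below min_fragments, ",
         sum(fail_tss), " below min_tss")
  structure(list(barcodes = st$barcode[keep], stats = st[keep]),
            class = "cell_set")
}

# sparse cells x bins matrix of Tn5 insertion counts (both fragment
# endpoints; the end coordinate is half-open so the second insertion sits at
# end - 1), weighted by the fragment count column
insertion_matrix <- function(fragments, barcodes, layout, chrom, resolution) {
  n_bins <- bin_count(layout, chrom, resolution)
  fr <- fragments[fragments$chrom == chrom & fragments$barcode %in% barcodes, ]
  cell_idx <- match(fr$barcode, barcodes)
  pos <- c(fr$start, fr$end - 1L)
  cells <- c(cell_idx, cell_idx)
  cnt <- c(fr$count, fr$count)
  bins <- pos %/% resolution + 1L
  ok <- bins >= 1L & bins <= n_bins
  Matrix::sparseMatrix(i = cells[ok], j = bins[ok], x = as.numeric(cnt[ok]),
                       dims = c(length(barcodes), n_bins))
}

#' Pseudobulk accessibility track
#'
#' Aggregates Tn5 insertion counts (both fragment endpoints) across the
#' retained cells into `resolution`-bp bins, library-size normalizes and log
#' transforms with a pseudocount of 1:
#' `value = log1p(raw * scale / library_size)`, where `library_size` is the
#' total insertion count of the retained cells across all chromosomes of the
#' input. The track is therefore invariant to uniform scaling of sequencing
#' depth.
#'
#' @param fragments fragments table (see [read_fragments()]).
#' @param cells a `cell_set` or character vector of barcodes.
#' @param layout a [genome_layout()].
#' @param chrom chromosome to build the track for.
#' @param scale normalization scale (default 1e8).
#' @param resolution bin size in bp (default 50).
#' @return a `bin_track` (list with chrom, resolution, values, n_cells_used,
#'   library_size).
#' @export
pseudobulk_accessibility <- function(fragments, cells, layout, chrom,
                                     scale = 1e8, resolution = 50L) {
  barcodes <- if (inherits(cells, "cell_set")) cells$barcodes else cells
  fr <- fragments[fragments$barcode %in% barcodes, ]
  library_size <- 2 * sum(fr$count)  # two insertions per fragment
  if (library_size == 0) stop("library size is zero for the retained cells")
  m <- insertion_matrix(fr, barcodes, layout, chrom, resolution)
  raw <- Matrix::colSums(m)
  bin_track(chrom, resolution, log1p(raw * scale / library_size),
            source = "pseudobulk", n_cells_used = length(barcodes),
            library_size = library_size)
}

# fast path used during training: insertion counts are pre-binned per cell;
# the subset column-sum is one sparse matvec with an indicator (multiplicity
# respected when sampling with replacement)
pseudobulk_from_matrix <- function(ins_mat, cell_idx, chrom, resolution,
                                   scale = 1e8) {
  w <- numeric(nrow(ins_mat))
  tab <- tabulate(cell_idx, nbins = nrow(ins_mat))
  w[] <- tab
  raw <- as.numeric(w %*% ins_mat)
  library_size <- sum(raw)
  if (library_size == 0) stop("library size is zero")
  bin_track(chrom, resolution, log1p(raw * scale / library_size),
            source = "pseudobulk", n_cells_used = length(cell_idx),
            library_size = library_size)
}

#' @rdname pseudobulk_accessibility
#' @param values numeric per-bin vector.
#' @param source character tag ("pseudobulk", "motif", "chip").
#' @param ... further fields stored on the track.
#' @export
bin_track <- function(chrom, resolution, values, source = "generic", ...) {
  structure(list(chrom = chrom, resolution = as.integer(resolution),
                 values = as.numeric(values), source = source, ...),
            class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat("bin_track [", x$source, "] ", x$chrom, " @ ", x$resolution, "bp: ",
      length(x$values), " bins\n", sep = "")
  invisible(x)
}

# normalize a PWM: probability columns, pseudocount if any cell is zero
normalize_pwm <- function(pwm, pseudocount = 0.25) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4) stop("PWM must have 4 rows (A,C,G,T)")
  if (any(pwm == 0)) pwm <- pwm + pseudocount
  sweep(pwm, 2, colSums(pwm), "/")
}

#' Scan a sequence for CTCF motif hits
#'
#' Scores every position of both strands of `sequence` against each PWM with
#' log2 odds versus the background, keeps per start position the best
#' (PWM, strand) combination, and discards windows that score <= 0 or contain
#' `N`. PWMs with a zero entry get a pseudocount of 0.25 per cell before the
#' log (columns renormalized).
#'
#' @param sequence character string over A,C,G,T,N (case-insensitive).
#' @param pwms a single PWM (4 x width probability matrix, rows A,C,G,T) or a
#'   list of them.
#' @param background background base probabilities (default uniform).
#' @return data.frame of hits: start, end (0-based half-open), strand, score,
#'   pwm index.
#' @export
scan_ctcf_motifs <- function(sequence, pwms, background = rep(0.25, 4)) {
  if (is.matrix(pwms)) pwms <- list(pwms)
  pwms <- lapply(pwms, normalize_pwm)
  code <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  L <- length(code)
  cand <- list()
  for (pi in seq_along(pwms)) {
    pwm <- pwms[[pi]]
    w <- ncol(pwm)
    if (L < w) next
    lod_f <- log2(sweep(pwm, 1, background, "/"))
    # reverse strand: reverse-complemented PWM scanned on the forward text
    lod_r <- lod_f[4:1, w:1, drop = FALSE]
    n_pos <- L - w + 1L
    for (strand in c("+", "-")) {
      lod <- if (strand == "+") lod_f else lod_r
      sc <- numeric(n_pos)
      valid <- rep(TRUE, n_pos)
      for (k in seq_len(w)) {
        ck <- code[k:(k + n_pos - 1L)]
        valid <- valid & !is.na(ck)
        contrib <- lod[cbind(ck, k)]
        contrib[is.na(contrib)] <- 0
        sc <- sc + contrib
      }
      keep <- valid & sc > 0
      if (any(keep))
        cand[[length(cand) + 1L]] <- data.frame(
          start = which(keep) - 1L, end = which(keep) - 1L + w,
          strand = strand, score = sc[keep], pwm = pi)
    }
  }
  if (length(cand) == 0) return(empty_hits())
  all_hits <- do.call(rbind, cand)
  # per start position retain the best (PWM, strand) combination
  all_hits <- all_hits[order(all_hits$start, -all_hits$score), , drop = FALSE]
  best <- all_hits[!duplicated(all_hits$start), , drop = FALSE]
  rownames(best) <- NULL
  best
}

empty_hits <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             score = numeric(), pwm = integer())
}

#' Build a 50bp motif-score track from motif hits
#'
#' Each bin gets the maximum score over hits that overlap it by at least
#' `min_overlap` bp; bins without a qualifying hit are 0. A pure max
#' reduction: the hit order never matters.
#'
#' @param hits data.frame from [scan_ctcf_motifs()] (start, end, score).
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @param min_overlap minimum hit/bin overlap in bp (default 10).
#' @param resolution bin size in bp (default 50).
#' @return a `bin_track` with `source = "motif"`.
#' @export
motif_track_from_hits <- function(hits, layout, chrom, min_overlap = 10L,
                                  resolution = 50L) {
  n_bins <- bin_count(layout, chrom, resolution)
  v <- numeric(n_bins)
  for (k in seq_len(nrow(hits))) {
    s <- hits$start[k]; e <- hits$end[k]; sc <- hits$score[k]
    b0 <- max(1L, s %/% resolution + 1L)
    b1 <- min(n_bins, as.integer(ceiling(e / resolution)))
    if (b0 > b1) next
    for (b in b0:b1) {
      bin_s <- (b - 1L) * resolution; bin_e <- b * resolution
      ov <- min(e, bin_e) - max(s, bin_s)
      if (ov >= min_overlap) v[b] <- max(v[b], sc)
    }
  }
  bin_track(chrom, resolution, v, source = "motif")
}

#' CTCF ChIP signal track from a bedGraph
#'
#' Rebins an arbitrary-interval bedGraph to `resolution`-bp bins by
#' length-weighted mean (uncovered stretches count as 0).
#'
#' @param path bedGraph file of normalized ChIP signal.
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @param resolution bin size in bp (default 50).
#' @return a `bin_track` with `source = "chip"`.
#' @export
chip_track_from_bedgraph <- function(path, layout, chrom, resolution = 50L) {
  dt <- read_bedgraph(path)
  dt <- dt[dt$chrom == chrom, ]
  n_bins <- bin_count(layout, chrom, resolution)
  acc <- numeric(n_bins)
  for (k in seq_len(nrow(dt))) {
    s <- dt$start[k]; e <- dt$end[k]; val <- dt$value[k]
    b0 <- max(1L, s %/% resolution + 1L)
    b1 <- min(n_bins, as.integer(ceiling(e / resolution)))
    if (b0 > b1) next
    for (b in b0:b1) {
      ov <- min(e, b * resolution) - max(s, (b - 1L) * resolution)
      if (ov > 0) acc[b] <- acc[b] + ov * val
    }
  }
  bin_track(chrom, resolution, acc / resolution, source = "chip")
}

#' Extract a model input window from a chromosome-wide track
#'
#' Returns the fixed-length stretch of `track` centered on contact bin
#' `center_hic_bin`, zero-padding positions that extend beyond the
#' chromosome edges. Optionally shifts the window by whole track bins
#' (`shift_bins`, used for training augmentation).
#'
#' @param track a `bin_track` or numeric vector covering the chromosome.
#' @param center_hic_bin 1-based contact-map bin index of the window center.
#' @param geometry a [model_geometry()].
#' @param resolution track resolution (taken from the track when a
#'   `bin_track` is given).
#' @param shift_bins integer shift in track bins applied to the extracted
#'   window (default 0).
#' @return numeric vector of length `geometry$window_bp / resolution`.
#' @export
extract_window <- function(track, center_hic_bin, geometry,
                           resolution = NULL, shift_bins = 0L) {
  if (inherits(track, "bin_track")) {
    resolution <- track$resolution
    values <- track$values
  } else values <- as.numeric(track)
  if (is.null(resolution)) stop("resolution required for plain vectors")
  if (geometry$window_bp %% resolution != 0)
    stop("track resolution must divide the window size")
  factor <- geometry$hic_resolution %/% resolution
  n_hic <- as.integer(ceiling(length(values) / factor))
  if (center_hic_bin < 1 || center_hic_bin > n_hic)
    stop("center bin outside chromosome")
  len <- geometry$hic_window_bins * factor
  start_bin <- (center_hic_bin - 1L - geometry$max_distance_bins) * factor +
    1L + as.integer(shift_bins)
  idx <- seq.int(start_bin, length.out = len)
  out <- numeric(len)
  ok <- idx >= 1L & idx <= length(values)
  out[ok] <- values[idx[ok]]
  out
}
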