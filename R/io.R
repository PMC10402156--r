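#' Read a 10x-style scATAC fragments file
#'
#' Parses a 4- or 5-column TSV (optionally gzipped): chrom, start, end,
#' barcode and an optional positive integer count (default 1). Coordinates
#' are 0-based half-open. Comment lines starting with `#` are skipped.
#' Records on chromosomes absent from `layout` are dropped with a warning
#' that reports how many were skipped; non-integer coordinates or
#' `start >= end` are errors.
#'
#' @param path fragments TSV(.gz).
#' @param layout a [genome_layout()].
#' @return a `data.table` with columns chrom, start, end, barcode, count and
#'   attribute `n_skipped` (rows dropped for unknown chromosomes).
#' @export
read_fragments <- function(path, layout) {
  dt <- read_text_table(path, header = FALSE, fill = TRUE)
  if (nrow(dt) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), barcode = character(),
                                  count = integer()))
  # fread drops '#' comment lines only at top; filter defensively
  if (is.character(dt[[1]])) dt <- dt[!startsWith(dt[[1]], "#")]
  if (ncol(dt) < 4 || ncol(dt) > 5)
    stop("fragments file must have 4 or 5 columns, got ", ncol(dt))
  names(dt)[1:4] <- c("chrom", "start", "end", "barcode")
  if (ncol(dt) == 4) dt$count <- 1L else names(dt)[5] <- "count"
  dt$count[is.na(dt$count)] <- 1L  # rows in the 4-column dialect
  if (any(is.na(dt$start) | is.na(dt$end) | is.na(dt$barcode)))
    stop("malformed fragment row (fewer than 4 fields)")
  for (col in c("start", "end")) {
    v <- dt[[col]]
    if (!is.numeric(v) || any(v != floor(v)))
      stop("non-integer coordinate in column '", col, "'")
  }
  bad <- which(dt$start >= dt$end)
  if (length(bad))
    stop("fragment with start >= end at data row ", bad[1])
  known <- dt$chrom %in% layout$chrom_names
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(n_skipped, " fragment(s) on chromosomes absent from layout were skipped")
    dt <- dt[known]
  }
  dt <- dt[, c("chrom", "start", "end", "barcode", "count"), with = FALSE]
  dt$start <- as.integer(dt$start); dt$end <- as.integer(dt$end)
  dt$count <- as.integer(dt$count)
  data.table::setattr(dt, "n_skipped", n_skipped)
  dt[]
}

#' Read and merge a BED peak file
#'
#' Reads BED3+ intervals (0-based half-open), sorts them, and merges any
#' peaks separated by at most `merge_gap` bp (the standard post-peak-calling
#' cleanup; merging is transitive). Overlapping or book-ended peaks always
#' merge.
#'
#' @param path BED file.
#' @param merge_gap maximum gap (bp) between peaks that are merged; default
#'   500.
#' @return a `data.table` with columns chrom, start, end, id (sorted, merged).
#' @export
read_peaks <- function(path, merge_gap = 500L) {
  dt <- read_text_table(path, header = FALSE)
  if (nrow(dt) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), id = character()))
  if (is.character(dt[[1]])) dt <- dt[!startsWith(dt[[1]], "#")]
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (any(dt$start >= dt$end)) stop("peak with start >= end")
  merge_peaks(dt[, c("chrom", "start", "end"), with = FALSE], merge_gap)
}

#' Merge peak intervals separated by small gaps
#'
#' @param peaks data.frame with chrom, start, end (0-based half-open).
#' @param merge_gap maximum separating gap in bp that still merges.
#' @return merged, sorted `data.table` with an `id` column.
#' @export
merge_peaks <- function(peaks, merge_gap = 500L) {
  peaks <- data.table::as.data.table(peaks)
  out <- peaks[0]
  res <- lapply(split(peaks, peaks$chrom), function(p) {
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)  # to 1-based closed
    # gap g merges iff g <= merge_gap  <=>  min.gapwidth = merge_gap + 1
    m <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    data.table::data.table(chrom = p$chrom[1],
                           start = IRanges::start(m) - 1L,
                           end = IRanges::end(m))
  })
  out <- data.table::rbindlist(res)
  data.table::setorderv(out, c("chrom", "start"))
  out$id <- sprintf("peak_%d", seq_len(nrow(out)))
  out[]
}

#' Read an intra-chromosomal contact table
#'
#' Triplet text format: chrom, bin1_start, bin2_start, value (tab-separated,
#' optional header line starting with `#`). Bin starts must be multiples of
#' `resolution`; duplicate pairs (including mirrored ones) are summed, so
#' both-triangle dumps are tolerated. Returns one [contact_map()] per
#' chromosome present.
#'
#' @param path triplet TSV.
#' @param resolution bin size in bp.
#' @param layout a [genome_layout()].
#' @return named list of `contact_map` objects.
#' @export
read_contact_table <- function(path, resolution, layout) {
  dt <- read_text_table(path, header = FALSE)
  if (is.character(dt[[1]])) dt <- dt[!startsWith(dt[[1]], "#")]
  names(dt)[1:4] <- c("chrom", "bin1", "bin2", "value")
  if (any(dt$bin1 %% resolution != 0) || any(dt$bin2 %% resolution != 0))
    stop("bin starts must be multiples of resolution = ", resolution)
  unknown <- setdiff(unique(dt$chrom), layout$chrom_names)
  if (length(unknown)) stop("unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  maps <- lapply(split(dt, dt$chrom), function(d) {
    n <- bin_count(layout, d$chrom[1], resolution)
    i <- as.integer(d$bin1 %/% resolution) + 1L
    j <- as.integer(d$bin2 %/% resolution) + 1L
    if (any(i > n) || any(j > n)) stop("bin beyond chromosome end")
    contact_map(d$chrom[1], resolution, n, i, j, d$value)
  })
  maps[order(match(names(maps), layout$chrom_names))]
}

#' Write contact maps as a triplet table
#'
#' Inverse of [read_contact_table()]: upper-triangle nonzero entries as
#' chrom, bin1_start, bin2_start, value.
#'
#' @param maps a `contact_map` or list of them.
#' @param path output file.
#' @export
write_contact_table <- function(maps, path) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    tr <- cm_triplets(m)
    data.table::data.table(chrom = m$chrom,
                           bin1 = (tr$i - 1L) * m$resolution,
                           bin2 = (tr$j - 1L) * m$resolution,
                           value = tr$value)
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track as bedGraph
#'
#' Adjacent equal-value bins are run-length merged. Zero-value runs are
#' written too so that a round-trip reproduces the vector exactly.
#'
#' @param track numeric per-bin vector.
#' @param path output file.
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param chrom_length optional bp length to clip the final bin end.
#' @export
write_track_bedgraph <- function(track, path, chrom, resolution,
                                 chrom_length = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# bedGraph chrom=%s resolution=%d", chrom, resolution),
             con)
  if (length(track) == 0) return(invisible(path))
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  end_bp <- ends * resolution
  if (!is.null(chrom_length)) end_bp <- pmin(end_bp, chrom_length)
  writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom,
                     as.integer(starts * resolution), as.integer(end_bp),
                     r$values), con)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph with optional `#`/track header lines.
#' @return `data.table` with chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                 nzchar(lines)]
  if (length(lines) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), value = numeric()))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  names(dt) <- c("chrom", "start", "end", "value")[seq_len(ncol(dt))]
  dt[]
}

#' Read a bedGraph back into a per-bin vector
#'
#' @param path bedGraph file.
#' @param n_bins number of bins of the target vector.
#' @param resolution bin size in bp.
#' @return numeric vector of length `n_bins` (positions not covered are 0).
#' @export
read_track_bedgraph <- function(path, n_bins, resolution) {
  dt <- read_bedgraph(path)
  v <- numeric(n_bins)
  if (nrow(dt) == 0) return(v)
  for (k in seq_len(nrow(dt))) {
    b0 <- dt$start[k] %/% resolution + 1L
    b1 <- min(as.integer(ceiling(dt$end[k] / resolution)), n_bins)
    if (b0 <= b1) v[b0:b1] <- dt$value[k]
  }
  v
}

#' Write a fragments table as TSV
#'
#' @param fragments data.frame with chrom, start, end, barcode and optional
#'   count.
#' @param path output path (gzipped iff it ends in .gz).
#' @export
write_fragments <- function(fragments, path) {
  dt <- data.table::as.data.table(fragments)
  cols <- intersect(c("chrom", "start", "end", "barcode", "count"), names(dt))
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, open = "wt")
    on.exit(close(con))
    utils::write.table(dt[, cols, with = FALSE], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    data.table::fwrite(dt[, cols, with = FALSE], path, sep = "\t",
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Read JASPAR-style position frequency matrices
#'
#' Accepts the JASPAR text layout: a `>ID name` header followed by four
#' lines `A [ 1 2 ... ]` (brackets optional). Counts are converted to
#' column-probability matrices.
#'
#' @param path PFM text file (may contain several motifs).
#' @return named list of 4 x width probability matrices (rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      id <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]][1]
      rows <- lapply(lines[(i + 1L):(i + 4L)], function(l) {
        as.numeric(strsplit(gsub("[A-Za-z\\[\\]]", " ", l), "[ \t]+")[[1]] |>
                     (\(x) x[nzchar(x)])())
      })
      pfm <- do.call(rbind, rows)
      rownames(pfm) <- c("A", "C", "G", "T")
      out[[id]] <- sweep(pfm, 2, colSums(pfm), "/")
      i <- i + 5L
    } else i <- i + 1L
  }
  out
}
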