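#' Genome layout
#'
#' Ordered chromosome names and lengths; the coordinate frame every reader
#' validates against. All intervals in the package are 0-based half-open.
#'
#' @param chrom_names character vector of chromosome names.
#' @param chrom_lengths integer vector of lengths in bp (> 0).
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names)) stop("duplicate chromosome names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
            class = "genome_layout")
}

#' Read a two-column chrom.sizes table
#'
#' @param path TSV with columns chrom, length.
#' @return a `genome_layout`.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  genome_layout(dt$chrom, dt$length)
}

#' Number of bins of a chromosome at a resolution
#'
#' `ceiling(length / resolution)`; the last bin may be partial.
#'
#' @param layout a `genome_layout`.
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @return integer bin count.
#' @export
bin_count <- function(layout, chrom, resolution) {
  len <- chrom_length(layout, chrom)
  as.integer(ceiling(len / resolution))
}

#' @rdname bin_count
#' @export
chrom_length <- function(layout, chrom) {
  if (!chrom %in% layout$chrom_names) stop("unknown chromosome: ", chrom)
  unname(layout$chrom_lengths[[chrom]])
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout with", length(x$chrom_names), "chromosome(s):\n")
  print(x$chrom_lengths)
  invisible(x)
}

# read a possibly gzipped whitespace table without requiring R.utils;
# comment lines starting with '#' are stripped before parsing
read_text_table <- function(path, header = FALSE, fill = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else path
  lines <- readLines(con)
  if (inherits(con, "connection")) close(con)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(data.table::data.table())
  data.table::fread(text = lines, header = header, sep = "\t", fill = fill)
}
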