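#' Genomic region discretised into fixed-size lattice units
#'
#' A region is a 0-based half-open genomic interval together with a bin size.
#' The simulation treats the region as a 1D lattice of units of `bin_size`
#' base pairs (10 kb by default); a partial terminal bin counts as a full
#' unit, so the number of units is `ceiling((end - start) / bin_size)`.
#'
#' @param chrom chromosome name, e.g. `"chr2L"`.
#' @param start,end 0-based half-open interval bounds in base pairs.
#' @param bin_size lattice unit size in base pairs (default 10000).
#' @return An object of class `"genome_region"`: a list with fields
#'   `chrom`, `start`, `end`, `bin_size` and `n_units`.
#' @examples
#' r <- genome_region("chr2L", 18520000, 23513712)
#' r$n_units  # 500
#' @export
genome_region <- function(chrom, start, end, bin_size = 10000L) {
  start <- as.numeric(start); end <- as.numeric(end)
  bin_size <- as.numeric(bin_size)
  if (length(chrom) != 1L || !nzchar(chrom))
    stop("'chrom' must be a single non-empty string")
  if (!is.finite(start) || !is.finite(end) || end <= start)
    stop("invalid region: 'end' must be greater than 'start'")
  if (!is.finite(bin_size) || bin_size <= 0)
    stop("invalid region: 'bin_size' must be positive")
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         bin_size = bin_size,
         n_units = as.integer(ceiling((end - start) / bin_size))),
    class = "genome_region")
}

#' Parse a region string of the form "chrom:start-end"
#'
#' @param x a string like `"chr2L:18520000-23513712"`.
#' @inheritParams genome_region
#' @return A [genome_region()] object.
#' @export
parse_region <- function(x, bin_size = 10000L) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1L]]
  if (length(m) != 4L)
    stop("cannot parse region string '", x, "'; expected chrom:start-end")
  genome_region(m[2L], as.numeric(m[3L]), as.numeric(m[4L]), bin_size)
}

#' Lattice unit intervals of a region
#'
#' Returns the genomic interval covered by each lattice unit. Unit `i`
#' (1-based) covers `[start + (i-1) * bin_size, min(start + i * bin_size, end))`;
#' the last unit may be shorter than `bin_size`.
#'
#' @param region a [genome_region()].
#' @return A data frame with columns `chrom`, `start`, `end` and `unit`
#'   (1-based unit index), one row per lattice unit.
#' @examples
#' make_lattice(genome_region("toy", 0, 25000))  # 3 units, last one partial
#' @export
make_lattice <- function(region) {
  stopifnot(inherits(region, "genome_region"))
  n <- region$n_units
  s <- region$start + (seq_len(n) - 1) * region$bin_size
  e <- pmin(s + region$bin_size, region$end)
  data.frame(chrom = region$chrom, start = s, end = e, unit = seq_len(n))
}

#' @export
print.genome_region <- function(x, ...) {
  cat(sprintf("<genome_region> %s:%.0f-%.0f (%d units of %.0f bp)\n",
              x$chrom, x$start, x$end, x$n_units, x$bin_size))
  invisible(x)
}
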