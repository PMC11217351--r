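# Genomic file I/O. All coordinates are 0-based half-open in memory,
# matching BED/bedGraph conventions on disk (rtracklayer handles the
# 1-based GRanges shift).

#' Read a bedGraph coverage file
#'
#' @param file path to a 4-column bedGraph (track lines tolerated).
#' @return A data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open).
#' @export
read_bedgraph <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = as.numeric(gr$score))
}

#' Write a per-bin track (or interval data frame) as bedGraph
#'
#' @param x a [signal_track()] or a data frame with `chrom`, `start`,
#'   `end`, `value`.
#' @param file output path.
#' @export
write_bedgraph <- function(x, file) {
  if (inherits(x, "signal_track")) {
    lat <- make_lattice(attr(x, "region"))
    x <- data.frame(chrom = lat$chrom, start = lat$start, end = lat$end,
                    value = as.numeric(x))
  }
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end), score = x$value)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Read a BED interval file
#'
#' @param file path to a BED file (3+ columns).
#' @return A data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and, when present, `name` and `score`.
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' Write intervals as BED
#'
#' @param x a data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name`/`score` columns.
#' @param file output path.
#' @export
write_bed <- function(x, file) {
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end))
  if (!is.null(x$name)) gr$name <- x$name
  if (!is.null(x$score)) gr$score <- x$score
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Convert a per-unit logical mask to BED intervals (and back)
#'
#' Runs of `TRUE` units are merged into single intervals. The reverse
#' mapping marks a unit `TRUE` when any interval overlaps it.
#'
#' @param mask logical mask, one entry per lattice unit.
#' @param region the [genome_region()] defining the units.
#' @return `mask_to_bed`: a BED-style data frame; `bed_to_mask`: a logical
#'   mask of length `region$n_units`.
#' @export
mask_to_bed <- function(mask, region) {
  stopifnot(inherits(region, "genome_region"),
            length(mask) == region$n_units)
  lat <- make_lattice(region)
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(chrom = region$chrom,
             start = lat$start[starts[keep]],
             end = lat$end[ends[keep]])
}

#' @rdname mask_to_bed
#' @param bed a data frame with `chrom`, `start`, `end` (0-based).
#' @export
bed_to_mask <- function(bed, region) {
  stopifnot(inherits(region, "genome_region"))
  mask <- logical(region$n_units)
  bed <- bed[bed$chrom == region$chrom &
             bed$end > region$start & bed$start < region$end, , drop = FALSE]
  if (nrow(bed)) {
    for (r in seq_len(nrow(bed))) {
      first <- floor((max(bed$start[r], region$start) - region$start) /
                     region$bin_size) + 1
      last <- ceiling((min(bed$end[r], region$end) - region$start) /
                      region$bin_size)
      mask[first:last] <- TRUE
    }
  }
  mask
}
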