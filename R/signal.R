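#' Per-bin normalised coverage track over a region
#'
#' A numeric vector with one non-negative value per lattice unit of a
#' [genome_region()], carrying a provenance record of the normalisation
#' factors applied to it.
#'
#' @param values numeric per-bin values (length `region$n_units`).
#' @param region the [genome_region()].
#' @param provenance named list of applied factors.
#' @return An object of class `"signal_track"`.
#' @export
signal_track <- function(values, region, provenance = list()) {
  stopifnot(inherits(region, "genome_region"))
  values <- as.numeric(values)
  if (length(values) != region$n_units)
    stop("track length ", length(values), " != region units ",
         region$n_units)
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("track values must be finite and >= 0")
  structure(values, class = "signal_track", region = region,
            provenance = provenance)
}

#' @export
print.signal_track <- function(x, ...) {
  r <- attr(x, "region")
  cat(sprintf("<signal_track> %s:%.0f-%.0f, %d bins\n", r$chrom, r$start,
              r$end, r$n_units))
  print(summary(as.numeric(x)))
  if (length(attr(x, "provenance")))
    cat("provenance:", paste(names(attr(x, "provenance")),
                             collapse = ", "), "\n")
  invisible(x)
}

retrack <- function(values, template, new_prov) {
  values <- pmax(values, 0)
  signal_track(values, attr(template, "region"),
               c(attr(template, "provenance"), new_prov))
}

#' Spike-in normalisation factors of one library
#'
#' The quantitative scale of a spike-in CUT&Tag library is set by the ratio
#' of genome-mapped (dm6) to spike-in-mapped (lambda phage) reads.
#'
#' @param dm6_reads,lambda_reads read counts mapped to the target genome
#'   and to the spike-in, respectively.
#' @param nuclei_count optional nuclei count for cross-stage comparisons.
#' @return An object of class `"norm_factors"` with the derived `factor`.
#' @export
norm_factors <- function(dm6_reads, lambda_reads, nuclei_count = NULL) {
  if (lambda_reads <= 0)
    stop("spike-in failure: zero lambda (spike-in) reads")
  if (dm6_reads <= 0) stop("no genome-mapped reads")
  structure(list(dm6_reads = dm6_reads, lambda_reads = lambda_reads,
                 factor = dm6_reads / lambda_reads,
                 nuclei_count = nuclei_count),
            class = "norm_factors")
}

#' Spike-in normalisation of a raw coverage track
#'
#' Rescales a sample onto the reference sample's quantitative scale using
#' the relative dm6/lambda read-count factors:
#' `out = raw * reference$factor / sample$factor`.
#'
#' @param raw_track a [signal_track()] of raw per-bin coverage.
#' @param sample,reference [norm_factors()] for the sample and for the
#'   reference it is scaled to.
#' @return The normalised [signal_track()] with provenance updated.
#' @export
spike_in_normalize <- function(raw_track, sample, reference) {
  stopifnot(inherits(raw_track, "signal_track"),
            inherits(sample, "norm_factors"),
            inherits(reference, "norm_factors"))
  retrack(as.numeric(raw_track) * reference$factor / sample$factor,
          raw_track,
          list(spike_in = c(sample_factor = sample$factor,
                            reference_factor = reference$factor)))
}

#' Histone-H3 loading correction
#'
#' Multiplies a mark-specific track by the ratio of the paired H3 library's
#' normalisation factor to the mark's own, compensating differences in
#' starting material: `out = mark_track * h3_factor / mark_factor`.
#'
#' @param mark_track a [signal_track()].
#' @param mark_factor,h3_factor positive scalars (e.g. the `factor` fields
#'   of [norm_factors()] objects).
#' @return The corrected [signal_track()].
#' @export
h3_correct <- function(mark_track, mark_factor, h3_factor) {
  stopifnot(inherits(mark_track, "signal_track"))
  if (mark_factor <= 0 || h3_factor <= 0)
    stop("normalisation factors must be > 0")
  retrack(as.numeric(mark_track) * h3_factor / mark_factor, mark_track,
          list(h3_ratio = h3_factor / mark_factor))
}

#' Scalar rescaling by nuclei counts (cross-stage comparisons)
#'
#' @param track a [signal_track()].
#' @param sample_nuclei,reference_nuclei nuclei counts for the sample and
#'   the reference stage.
#' @return The rescaled [signal_track()].
#' @export
nuclei_normalize <- function(track, sample_nuclei, reference_nuclei) {
  stopifnot(inherits(track, "signal_track"))
  if (sample_nuclei <= 0 || reference_nuclei <= 0)
    stop("nuclei counts must be > 0")
  retrack(as.numeric(track) * reference_nuclei / sample_nuclei, track,
          list(nuclei_ratio = reference_nuclei / sample_nuclei))
}

#' Bin an interval coverage track onto the lattice
#'
#' Computes the length-weighted mean of the interval values over each
#' lattice bin; base pairs not covered by any interval contribute 0.
#' Intervals outside the region are clipped.
#'
#' @param intervals a data frame with `chrom`, `start`, `end`, `value`
#'   (0-based half-open; e.g. from [read_bedgraph()]).
#' @param region the [genome_region()].
#' @return A [signal_track()] of per-bin values.
#' @export
bin_track <- function(intervals, region) {
  stopifnot(inherits(region, "genome_region"))
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(intervals)))
    stop("'intervals' must have columns chrom, start, end, value")
  n <- region$n_units
  bw <- region$bin_size
  acc <- numeric(n)
  iv <- intervals[intervals$chrom == region$chrom &
                  intervals$end > region$start &
                  intervals$start < region$end, , drop = FALSE]
  if (nrow(iv)) {
    s <- pmax(iv$start, region$start); e <- pmin(iv$end, region$end)
    first <- floor((s - region$start) / bw) + 1
    last <- ceiling((e - region$start) / bw)
    for (r in seq_len(nrow(iv))) {
      for (b in first[r]:last[r]) {
        b0 <- region$start + (b - 1) * bw
        ov <- min(e[r], b0 + bw) - max(s[r], b0)
        if (ov > 0) acc[b] <- acc[b] + ov * iv$value[r]
      }
    }
  }
  lat <- make_lattice(region)
  signal_track(acc / (lat$end - lat$start), region)
}

#' Call HP1 binding sites from a normalised signal track
#'
#' Fits a Gaussian to the per-bin signal distribution and calls as binding
#' sites all bins whose signal is strictly larger than the fitted mean plus
#' `n_sigma` (default 4) standard deviations.
#'
#' The default fit is iterative sigma clipping: values further than
#' `clip_sigma` standard deviations from the current mean are discarded and
#' the moments re-estimated, with the clipped standard deviation divided by
#' the truncated-normal consistency factor
#' `sqrt(1 - 2 k phi(k) / (2 Phi(k) - 1))` so that the background estimate
#' is unbiased when the signal really is Gaussian. This keeps the
#' `mean + 4 sd` threshold meaningful when a heavy right tail of true
#' binding sites would otherwise inflate the plain moments; `"moments"`
#' (plain mean/sd) and `"histfit"` (least squares of a Gaussian density to
#' the histogram) are available for comparison.
#'
#' @param track a [signal_track()] or numeric vector.
#' @param n_sigma threshold multiplier (default 4).
#' @param method background fit method.
#' @param clip_sigma clipping threshold in SDs (default 3).
#' @param max_iter maximum clipping iterations.
#' @param min_bins minimum track length accepted (default 50).
#' @return A list of class `"site_call"`: `mask` (logical calls),
#'   `mean`, `sd`, `threshold`, `method` and `iterations`.
#' @export
call_binding_sites <- function(track, n_sigma = 4,
                               method = c("clipped", "moments", "histfit"),
                               clip_sigma = 3, max_iter = 10L,
                               min_bins = 50L) {
  method <- match.arg(method)
  x <- as.numeric(track)
  if (length(x) < min_bins)
    stop("track too short for a distribution fit (", length(x), " < ",
         min_bins, " bins)")
  iterations <- 0L
  if (method == "moments") {
    m <- mean(x); s <- stats::sd(x)
  } else if (method == "histfit") {
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
    fit <- stats::optim(c(mean(x), stats::sd(x)), function(p) {
      if (p[2] <= 0) return(Inf)
      sum((h$density - stats::dnorm(h$mids, p[1], p[2]))^2)
    })
    m <- fit$par[1]; s <- fit$par[2]
  } else {
    # truncation consistency: sd of a normal clipped at +/- k sigma
    k <- clip_sigma
    consistency <- sqrt(1 - 2 * k * stats::dnorm(k) / (2 * stats::pnorm(k) - 1))
    # robust start (median/MAD) so a heavy right tail of true sites cannot
    # drag the initial clip window over itself
    m <- stats::median(x)
    s <- stats::mad(x)
    if (s == 0) s <- stats::sd(x)
    keep_old <- rep(NA, length(x))
    for (it in seq_len(max_iter)) {
      iterations <- it
      keep <- abs(x - m) <= k * s
      if (sum(keep) < 2L) break
      m <- mean(x[keep]); s <- stats::sd(x[keep]) / consistency
      if (identical(keep, keep_old)) break
      keep_old <- keep
    }
  }
  if (!is.finite(s) || s <= 0)
    stop("degenerate signal distribution: zero variance")
  thr <- m + n_sigma * s
  structure(list(mask = x > thr, mean = m, sd = s, threshold = thr,
                 n_sigma = n_sigma, method = method,
                 iterations = iterations),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf(
    "<site_call> %d/%d bins called (fit %s: mean %.4g, sd %.4g, threshold %.4g)\n",
    sum(x$mask), length(x$mask), x$method, x$mean, x$sd, x$threshold))
  invisible(x)
}

#' Integrate normalised signal around peaks
#'
#' Sums the per-base normalised signal over each peak extended by `flank`
#' base pairs on both sides, computed from the binned track by length
#' weighting. Peaks are clipped to the track's region; flanked windows of
#' neighbouring peaks are quantified independently (never merged).
#'
#' @param track a [signal_track()].
#' @param peaks data frame with `chrom`, `start`, `end` (0-based).
#' @param flank extension in base pairs on each side (default 1000).
#' @return Numeric vector of per-peak integrated signal (one per input
#'   row; 0 for peaks that do not overlap the region).
#' @export
quantify_peaks <- function(track, peaks, flank = 1000) {
  stopifnot(inherits(track, "signal_track"))
  region <- attr(track, "region")
  if (!nrow(peaks)) return(numeric())
  lat <- make_lattice(region)
  vals <- as.numeric(track)
  vapply(seq_len(nrow(peaks)), function(r) {
    if (peaks$chrom[r] != region$chrom) return(0)
    ws <- max(peaks$start[r] - flank, region$start)
    we <- min(peaks$end[r] + flank, region$end)
    if (we <= ws) return(0)
    ov <- pmin(lat$end, we) - pmax(lat$start, ws)
    sum(vals[ov > 0] * ov[ov > 0])
  }, numeric(1))
}

#' Log2 ratio of per-peak integrated signals
#'
#' @param a,b aligned numeric vectors of per-peak integrals (e.g. control
#'   and mutant from [quantify_peaks()]).
#' @param pseudocount added to both before the ratio (default 0; with the
#'   default, peaks with zero signal in both samples raise an error).
#' @return `log2((a + pseudocount) / (b + pseudocount))` per peak.
#' @export
log2_peak_ratio <- function(a, b, pseudocount = 0) {
  if (length(a) != length(b)) stop("misaligned peak lists")
  if (pseudocount == 0 && any(a == 0 & b == 0))
    stop("0/0 peak ratio; set a pseudocount")
  log2((a + pseudocount) / (b + pseudocount))
}
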