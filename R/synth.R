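# Synthetic CUT&Tag-like inputs with known ground truth. The generator
# emulates the statistical structure of spike-in + H3 normalised HP1a and
# H3K9me3 tracks at 10 kb resolution: a unimodal Gaussian background with
# a right tail of elevated binding sites arranged as one dense
# pericentromeric-like block plus scattered arm sites.

#' Synthetic binding-site layout
#'
#' Draws a binding-site mask made of one contiguous pericentromeric-like
#' (PCH) block plus arm sites scattered at a given density, together with
#' the PCH mask (the block itself).
#'
#' @param n_sites number of 10-kb lattice units (default 500, the size of
#'   the modelled chr2L region).
#' @param pch_block inclusive 1-based `(first, last)` unit of the PCH
#'   block; the default places it at the centromere-proximal end.
#' @param arm_density fraction of non-block units that are binding sites.
#' @param seed RNG seed (layouts are deterministic given the seed).
#' @param region optional [genome_region()]; defaults to the modelled
#'   chr2L region when `n_sites` is 500, else to a synthetic contig.
#' @return An object of class `"synth_layout"`: list with logical
#'   `binding_sites` and `pch_mask`, the `region`, and the generating parameters.
#' @export
synth_layout <- function(n_sites = 500L, pch_block = NULL,
                         arm_density = 0.05, seed = 1L, region = NULL) {
  n_sites <- as.integer(n_sites)
  if (is.null(pch_block))
    pch_block <- c(max(1L, n_sites - 99L), n_sites)
  pch_block <- as.integer(pch_block)
  if (length(pch_block) != 2L || pch_block[1] < 1L ||
      pch_block[2] > n_sites || pch_block[1] > pch_block[2])
    stop("'pch_block' must be an in-range (first, last) unit pair")
  if (arm_density < 0 || arm_density > 1)
    stop("'arm_density' must be in [0, 1]")
  if (is.null(region)) {
    region <- if (n_sites == 500L)
      genome_region("chr2L", 18520000, 23513712)
    else genome_region("chrSim", 0, n_sites * 10000)
  }
  pch <- logical(n_sites)
  pch[pch_block[1]:pch_block[2]] <- TRUE
  set.seed(seed)
  arm <- which(!pch)
  n_arm <- round(arm_density * length(arm))
  sites <- pch
  if (n_arm > 0) sites[sample(arm, n_arm)] <- TRUE
  structure(list(binding_sites = sites, pch_mask = pch, region = region,
                 pch_block = pch_block, arm_density = arm_density,
                 seed = seed),
            class = "synth_layout")
}

#' @export
print.synth_layout <- function(x, ...) {
  cat(sprintf(
    "<synth_layout> %d units: PCH block %d-%d, %d arm site(s) (density %g)\n",
    length(x$binding_sites), x$pch_block[1], x$pch_block[2],
    sum(x$binding_sites & !x$pch_mask), x$arm_density))
  invisible(x)
}

#' Synthetic CUT&Tag-like tracks with spike-in factors
#'
#' Generates raw HP1 and H3K9me3 coverage tracks for one condition,
#' together with per-library spike-in read counts, such that running the
#' quantification pipeline (spike-in normalisation then H3 correction)
#' recovers the known normalised ground truth.
#'
#' On the normalised scale the ground truth is Gaussian noise of mean
#' `background_mean` and SD `background_sd`, elevated multiplicatively by
#' `site_enrichment` at binding sites. In the control both marks are
#' elevated at binding sites. In the TM the H3K9me3 track is background
#' everywhere, and the HP1 elevation is multiplied by
#' `tm_pch_attenuation` at PCH binding sites only (arm sites keep their
#' control-level HP1); the default 0.65 encodes the experimentally
#' measured ~35% loss of PCH-bound HP1a without H3K9 methylation.
#'
#' @param layout a [synth_layout()].
#' @param condition `"control"` or `"TM"`.
#' @param background_mean,background_sd Gaussian background of the
#'   normalised signal.
#' @param site_enrichment multiplicative elevation at binding sites (> 1).
#' @param tm_pch_attenuation fraction of HP1 elevation retained at PCH
#'   binding sites in the TM.
#' @param spike_in named list of `(dm6_reads, lambda_reads)` pairs for the
#'   `hp1`, `h3k9me3` and `h3` libraries of this sample.
#' @param reference_spike_in same structure for the reference sample the
#'   raw tracks are scaled against (defaults to the control library
#'   sizes, so the control normalises to itself).
#' @param noise_model `"gaussian"` on the normalised scale (default) or
#'   `"poisson"`: counts drawn at depth `poisson_depth` reads per
#'   normalised signal unit and divided back, for stress-testing the
#'   caller under count noise.
#' @param poisson_depth mean reads per unit signal in `"poisson"` mode.
#' @param seed RNG seed.
#' @return An object of class `"synth_data"`: list with `tracks` (raw
#'   [signal_track()]s `hp1`, `h3k9me3`), `factors` ([norm_factors()] per
#'   library plus the reference), `truth` (normalised tracks, masks, and
#'   the generating parameters) and `condition`.
#' @export
synth_tracks <- function(layout, condition = c("control", "TM"),
                         background_mean = 1, background_sd = 0.1,
                         site_enrichment = 10, tm_pch_attenuation = 0.65,
                         spike_in = NULL, reference_spike_in = NULL,
                         noise_model = c("gaussian", "poisson"),
                         poisson_depth = 100, seed = 1L) {
  stopifnot(inherits(layout, "synth_layout"))
  condition <- match.arg(condition)
  noise_model <- match.arg(noise_model)
  if (background_sd <= 0) stop("'background_sd' must be > 0")
  if (site_enrichment <= 1) stop("'site_enrichment' must be > 1")
  if (tm_pch_attenuation < 0 || tm_pch_attenuation > 1)
    stop("'tm_pch_attenuation' must be in [0, 1]")
  if (is.null(spike_in))
    spike_in <- if (condition == "control")
      list(hp1 = c(2e6, 2000), h3k9me3 = c(1.8e6, 2000), h3 = c(2.2e6, 2000))
    else
      list(hp1 = c(1.5e6, 1200), h3k9me3 = c(1.2e6, 1500), h3 = c(2.6e6, 2000))
  if (is.null(reference_spike_in))
    reference_spike_in <- list(hp1 = c(2e6, 2000), h3k9me3 = c(1.8e6, 2000),
                               h3 = c(2.2e6, 2000))
  fac <- lapply(spike_in, function(v) norm_factors(v[1], v[2]))
  ref <- lapply(reference_spike_in, function(v) norm_factors(v[1], v[2]))

  n <- length(layout$binding_sites)
  sites <- layout$binding_sites; pch <- layout$pch_mask
  elev <- background_mean * site_enrichment

  mean_hp1 <- ifelse(sites, elev, background_mean)
  mean_h3k9 <- mean_hp1
  if (condition == "TM") {
    mean_h3k9 <- rep(background_mean, n)
    mean_hp1[sites & pch] <- elev * tm_pch_attenuation
  }

  set.seed(seed)
  draw <- function(mu) {
    if (noise_model == "gaussian") pmax(stats::rnorm(n, mu, background_sd), 0)
    else stats::rpois(n, mu * poisson_depth) / poisson_depth
  }
  truth_hp1 <- draw(mean_hp1)
  truth_h3k9 <- draw(mean_h3k9)

  # raw scale: invert spike-in and H3 corrections so the pipeline recovers
  # the normalised truth
  raw_hp1 <- as.numeric(truth_hp1) *
    (fac$hp1$factor / ref$hp1$factor) * (fac$hp1$factor / fac$h3$factor)
  raw_h3k9 <- as.numeric(truth_h3k9) *
    (fac$h3k9me3$factor / ref$h3k9me3$factor) *
    (fac$h3k9me3$factor / fac$h3$factor)

  region <- layout$region
  structure(list(
    condition = condition,
    tracks = list(hp1 = signal_track(raw_hp1, region),
                  h3k9me3 = signal_track(raw_h3k9, region)),
    factors = c(fac, list(reference = ref)),
    truth = list(hp1 = signal_track(truth_hp1, region),
                 h3k9me3 = signal_track(truth_h3k9, region),
                 binding_sites = sites, pch_mask = pch,
                 params = list(background_mean = background_mean,
                               background_sd = background_sd,
                               site_enrichment = site_enrichment,
                               tm_pch_attenuation = tm_pch_attenuation,
                               noise_model = noise_model, seed = seed)),
    layout = layout),
    class = "synth_data")
}

#' Recover normalised tracks from synthetic raw data via the pipeline
#'
#' Convenience wrapper applying [spike_in_normalize()] and [h3_correct()]
#' to a [synth_tracks()] object exactly as one would to real libraries.
#'
#' @param data a `"synth_data"` object.
#' @return List of normalised [signal_track()]s `hp1` and `h3k9me3`.
#' @export
normalize_synth <- function(data) {
  stopifnot(inherits(data, "synth_data"))
  f <- data$factors
  list(
    hp1 = h3_correct(
      spike_in_normalize(data$tracks$hp1, f$hp1, f$reference$hp1),
      f$hp1$factor, f$h3$factor),
    h3k9me3 = h3_correct(
      spike_in_normalize(data$tracks$h3k9me3, f$h3k9me3,
                         f$reference$h3k9me3),
      f$h3k9me3$factor, f$h3$factor))
}

#' Write a synthetic dataset to disk
#'
#' Emits bedGraph tracks, BED masks, a TSV of spike-in counts and a JSON
#' ground-truth sidecar (all files carry the generating seed).
#'
#' @param data a [synth_tracks()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
synth_write <- function(data, dir) {
  stopifnot(inherits(data, "synth_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  region <- data$layout$region
  p <- c(hp1 = file.path(dir, paste0("hp1_", data$condition, ".bedgraph")),
         h3k9me3 = file.path(dir,
                             paste0("h3k9me3_", data$condition, ".bedgraph")),
         sites = file.path(dir, "binding_sites.bed"),
         pch = file.path(dir, "pch_mask.bed"),
         spike = file.path(dir, paste0("spike_in_", data$condition, ".tsv")),
         truth = file.path(dir, paste0("truth_", data$condition, ".json")))
  write_bedgraph(data$tracks$hp1, p[["hp1"]])
  write_bedgraph(data$tracks$h3k9me3, p[["h3k9me3"]])
  write_bed(mask_to_bed(data$truth$binding_sites, region), p[["sites"]])
  write_bed(mask_to_bed(data$truth$pch_mask, region), p[["pch"]])
  sp <- data.frame(
    library = c("hp1", "h3k9me3", "h3"),
    dm6_reads = vapply(data$factors[c("hp1", "h3k9me3", "h3")],
                       function(f) f$dm6_reads, numeric(1)),
    lambda_reads = vapply(data$factors[c("hp1", "h3k9me3", "h3")],
                          function(f) f$lambda_reads, numeric(1)))
  utils::write.table(sp, p[["spike"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(condition = data$condition, params = data$truth$params,
         region = sprintf("%s:%.0f-%.0f", region$chrom, region$start,
                          region$end),
         pch_block = data$layout$pch_block,
         n_binding_sites = sum(data$truth$binding_sites)),
    p[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
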