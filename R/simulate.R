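#' Simulate the HP1 / H3K9-methylation lattice model
#'
#' Runs the exact Gillespie algorithm for the nine-event kinetic scheme on a
#' 1D lattice of chromatin units with a dynamic spatial contact network.
#' Replicate streams are derived deterministically from the master seed, so
#' trajectories are bit-reproducible given `(seed, replicate, params)`.
#'
#' Conditions: in `"control"` the binding sites start methylated; in `"TM"`
#' (triple mutant lacking the H3K9 methyltransferases) no site is methylated
#' initially and the methylation rate `k_m` is set to zero (set
#' `tm_keep_k_m = TRUE` to retain the residual noisy-methylation rate).
#'
#' @param binding_sites logical mask of HP1 binding sites, one per lattice
#'   unit (e.g. from [call_binding_sites()] or [synth_layout()]).
#' @param params a [rate_params()] object.
#' @param condition `"control"` or `"TM"`.
#' @param duration simulated time in minutes (the published runs use ~100 h,
#'   i.e. 6000 min).
#' @param n_replicates number of independent replicates (default 3).
#' @param sample_interval spacing of state snapshots in minutes.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param region optional [genome_region()] attached for genomic output.
#' @param spread_fiber also spread methylation to fibre neighbours i +/- 1
#'   (default `FALSE`: spreading acts across spatial contacts only).
#' @param tm_keep_k_m keep `k_m` nonzero in the TM condition.
#' @param check_consistency after every event, rebuild the cached distance
#'   matrix and propensities from scratch and stop on any mismatch (slow;
#'   for testing on small lattices).
#' @return An object of class `"hp1_sim"`: a list with `trajectories` (one
#'   per replicate, each with `times`, logical `methylated` and `bound`
#'   matrices of dimension samples x sites, and a per-sample list of 1-based
#'   `contacts` pairs), plus the call metadata.
#' @examples
#' sim <- hp1_simulate(c(TRUE, TRUE, FALSE, FALSE), duration = 50,
#'                     n_replicates = 2, seed = 1)
#' summary(sim)
#' @export
hp1_simulate <- function(binding_sites, params = rate_params(),
                         condition = c("control", "TM"),
                         duration = 6000, n_replicates = 3L,
                         sample_interval = 1, seed = 1L, region = NULL,
                         spread_fiber = FALSE, tm_keep_k_m = FALSE,
                         check_consistency = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "rate_params"))
  binding_sites <- as.logical(binding_sites)
  n <- length(binding_sites)
  if (n < 1L || anyNA(binding_sites)) stop("invalid binding-site mask")
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0")
  if (sample_interval <= 0) stop("'sample_interval' must be > 0")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (!is.null(region) && region$n_units != n)
    stop("region has ", region$n_units, " units but mask has length ", n)

  run_params <- params
  if (condition == "TM" && !tm_keep_k_m) run_params$k_m <- 0
  plist <- unclass(run_params)
  plist$spread_fiber <- isTRUE(spread_fiber)

  state0 <- init_state(n, binding_sites, condition)
  rep_seeds <- derive_replicate_seeds(seed, n_replicates)

  trajectories <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    raw <- gillespie_run_cpp(
      n, as.integer(binding_sites), as.integer(state0$methylated),
      as.integer(state0$hp1_bound),
      matrix(integer(), ncol = 2),  # 0-based contact pairs (none initially)
      plist, duration, sample_interval, check_consistency)
    trajectories[[r]] <- structure(
      list(times = raw$times,
           methylated = raw$methylated > 0L,
           bound = raw$bound > 0L,
           contacts = raw$contacts,
           n_steps = raw$n_steps,
           event_counts = raw$event_counts,
           replicate = r, seed = rep_seeds[r], condition = condition),
      class = "hp1_trajectory")
  }
  structure(list(trajectories = trajectories, condition = condition,
                 params = params, binding_sites = binding_sites,
                 duration = duration, sample_interval = sample_interval,
                 seed = seed, region = region,
                 spread_fiber = isTRUE(spread_fiber)),
            class = "hp1_sim")
}

# Deterministic per-replicate seeds below 2^31, derived from a master seed.
derive_replicate_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' @export
print.hp1_sim <- function(x, ...) {
  cat(sprintf(
    "<hp1_sim> %s condition: %d replicate(s), %d sites, %.0f min (snapshots every %g min)\n",
    x$condition, length(x$trajectories), length(x$binding_sites),
    x$duration, x$sample_interval))
  cat(sprintf("  %d binding sites; seed %d\n", sum(x$binding_sites), x$seed))
  invisible(x)
}

#' @export
summary.hp1_sim <- function(object, burn_in = 0, ...) {
  occ <- probability_profile(object, "hp1_binding", burn_in = burn_in)
  met <- probability_profile(object, "methylation", burn_in = burn_in)
  steps <- vapply(object$trajectories, function(tr) tr$n_steps, numeric(1))
  final_contacts <- vapply(object$trajectories, function(tr) {
    nrow(tr$contacts[[length(tr$contacts)]])
  }, numeric(1))
  out <- list(condition = object$condition,
              n_replicates = length(object$trajectories),
              n_sites = length(object$binding_sites),
              duration = object$duration,
              mean_occupancy = mean(occ),
              mean_occupancy_binding_sites =
                mean(occ[object$binding_sites]),
              mean_methylation = mean(met),
              mean_steps = mean(steps),
              mean_final_contacts = mean(final_contacts))
  class(out) <- "summary.hp1_sim"
  out
}

#' @export
print.summary.hp1_sim <- function(x, ...) {
  cat(sprintf("HP1 lattice simulation, %s condition\n", x$condition))
  cat(sprintf("  %d replicate(s) x %d sites, %.0f min\n",
              x$n_replicates, x$n_sites, x$duration))
  cat(sprintf("  mean HP1 occupancy:            %.3f\n", x$mean_occupancy))
  cat(sprintf("  mean occupancy, binding sites: %.3f\n",
              x$mean_occupancy_binding_sites))
  cat(sprintf("  mean methylation probability:  %.3f\n", x$mean_methylation))
  cat(sprintf("  mean events per replicate:     %.0f\n", x$mean_steps))
  cat(sprintf("  mean final contact count:      %.1f\n",
              x$mean_final_contacts))
  invisible(x)
}

#' Plot per-site probability profiles of a simulation
#'
#' Draws the time-averaged HP1-binding (and optionally methylation)
#' probability along the lattice, with binding sites marked.
#'
#' @param x an `"hp1_sim"` object.
#' @param burn_in minutes discarded before averaging.
#' @param show_methylation overlay the methylation profile.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hp1_sim <- function(x, burn_in = 0, show_methylation = TRUE, ...) {
  occ <- probability_profile(x, "hp1_binding", burn_in = burn_in)
  plot(seq_along(occ), as.numeric(occ), type = "l", ylim = c(0, 1),
       xlab = "lattice unit", ylab = "probability",
       main = sprintf("HP1 binding probability (%s)", x$condition), ...)
  if (show_methylation) {
    met <- probability_profile(x, "methylation", burn_in = burn_in)
    graphics::lines(seq_along(met), as.numeric(met), col = "firebrick")
    graphics::legend("topleft", bty = "n", lty = 1,
                     col = c("black", "firebrick"),
                     legend = c("HP1 bound", "H3K9 methylated"))
  }
  graphics::rug(which(x$binding_sites), col = "grey40")
  invisible(x)
}
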