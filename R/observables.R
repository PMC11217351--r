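#' Per-site methylation or HP1-binding probability profile
#'
#' Sites carry the value 1 when methylated (or HP1-bound) and 0 otherwise;
#' the per-site average of this indicator over the sampled time points,
#' pooled across replicates, defines the methylation (or binding)
#' probability. Snapshots are equally spaced, so the plain mean over
#' samples is the time-weighted average.
#'
#' @param sim an `"hp1_sim"` object (or a bare list of its trajectories).
#' @param quantity `"hp1_binding"` or `"methylation"`.
#' @param burn_in minutes excluded from the start of each trajectory.
#' @return A numeric vector of class `"prob_profile"` with one value in
#'   \[0,1\] per site and attributes `quantity`, `condition`,
#'   `n_replicates` and `burn_in`.
#' @export
probability_profile <- function(sim,
                                quantity = c("hp1_binding", "methylation"),
                                burn_in = 0) {
  quantity <- match.arg(quantity)
  trajectories <- if (inherits(sim, "hp1_sim")) sim$trajectories else sim
  if (!length(trajectories)) stop("no trajectories supplied")
  field <- if (quantity == "methylation") "methylated" else "bound"
  n <- ncol(trajectories[[1L]][[field]])
  cond <- trajectories[[1L]]$condition
  acc <- numeric(n); total <- 0L
  for (tr in trajectories) {
    if (ncol(tr[[field]]) != n) stop("trajectories differ in lattice size")
    if (!identical(tr$condition, cond))
      stop("trajectories mix simulation conditions")
    keep <- tr$times >= burn_in
    if (!any(keep))
      stop("'burn_in' leaves no samples (must be < duration)")
    acc <- acc + colSums(tr[[field]][keep, , drop = FALSE])
    total <- total + sum(keep)
  }
  structure(acc / total, class = "prob_profile", quantity = quantity,
            condition = cond, n_replicates = length(trajectories),
            burn_in = burn_in)
}

#' @export
print.prob_profile <- function(x, ...) {
  cat(sprintf("<prob_profile> %s, %s condition, %d sites (burn-in %g min)\n",
              attr(x, "quantity"), attr(x, "condition"), length(x),
              attr(x, "burn_in")))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Least-squares rescaling of an experimental track onto a simulated profile
#'
#' Finds the factor `c` minimising `sum((exp/c - sim)^2)`, i.e. the
#' normalisation that brings a CUT&Tag coverage track onto the probability
#' scale of the simulation; in closed form
#' `c = sum(exp^2) / sum(exp * sim)`.
#'
#' @param exp_signal numeric experimental per-site signal.
#' @param sim_profile simulated [probability_profile()] (or numeric vector)
#'   of the same length.
#' @return A list with `factor` (the fitted `c`) and `rescaled`
#'   (`exp_signal / factor`).
#' @export
rescale_experimental <- function(exp_signal, sim_profile) {
  exp_signal <- as.numeric(exp_signal)
  sim_profile <- as.numeric(sim_profile)
  if (length(exp_signal) != length(sim_profile))
    stop("signal and profile lengths differ")
  if (all(exp_signal == 0)) stop("degenerate fit: experimental signal is all zero")
  denom <- sum(exp_signal * sim_profile)
  if (denom <= 0)
    stop("degenerate fit: experimental signal and profile do not overlap")
  cc <- sum(exp_signal^2) / denom
  list(factor = cc, rescaled = exp_signal / cc)
}

#' Predicted bound loci from a probability profile
#'
#' A site is called a predicted HP1-bound locus when its simulated binding
#' probability is strictly larger than the threshold (default 0.5).
#'
#' @param profile a [probability_profile()] or numeric vector.
#' @param threshold strict probability cutoff.
#' @return Logical mask of predicted loci.
#' @export
predicted_bound_loci <- function(profile, threshold = 0.5) {
  as.numeric(profile) > threshold
}

#' Accuracy of predicted loci against called peaks, with permutation test
#'
#' Accuracy is the fraction of predicted loci that fall inside peak-covered
#' units. The null distribution is generated by uniformly reshuffling the
#' predicted-locus positions over all units (preserving their count), and
#' the p-value uses the add-one permutation estimator
#' `(1 + #\{shuffled accuracy >= observed\}) / (n_shuffles + 1)`.
#'
#' @param predicted logical mask of predicted loci.
#' @param peak_mask logical mask of peak-covered units (same length).
#' @param n_shuffles number of reshuffles (default 10000).
#' @param seed optional seed for the reshuffling.
#' @param balanced also report balanced accuracy
#'   (mean of sensitivity and specificity) as a diagnostic.
#' @return A list with `accuracy`, `p_value`, `n_shuffles`, `n_predicted`
#'   and, if `balanced`, `balanced_accuracy`.
#' @export
compare_to_peaks <- function(predicted, peak_mask, n_shuffles = 10000L,
                             seed = NULL, balanced = FALSE) {
  predicted <- as.logical(predicted); peak_mask <- as.logical(peak_mask)
  if (length(predicted) != length(peak_mask))
    stop("mask lengths differ")
  k <- sum(predicted)
  if (k == 0L) stop("undefined accuracy: no predicted loci")
  if (!is.null(seed)) set.seed(seed)
  n <- length(predicted)
  acc <- mean(peak_mask[predicted])
  shuffled <- vapply(seq_len(n_shuffles), function(s) {
    mean(peak_mask[sample.int(n, k)])
  }, numeric(1))
  p <- (1 + sum(shuffled >= acc)) / (n_shuffles + 1)
  out <- list(accuracy = acc, p_value = p,
              n_shuffles = as.integer(n_shuffles), n_predicted = k)
  if (balanced) {
    sens <- if (any(peak_mask)) mean(predicted[peak_mask]) else NA_real_
    spec <- if (any(!peak_mask)) mean(!predicted[!peak_mask]) else NA_real_
    out$balanced_accuracy <- mean(c(sens, spec))
  }
  out
}

#' HP1 aggregate (cluster) size distribution
#'
#' For every sampled state, the aggregate is the giant (largest connected)
#' component of the contact graph restricted to HP1-bound sites: vertices
#' are bound sites and edges are contacts whose two endpoints are both
#' bound. Its vertex count — the number of chromatin-bound HP1 molecules in
#' the cluster — is one raw size. Sizes below `min_size` are discarded and
#' the rest are multiplied by `size_scale` (0.096 by default, the factor
#' that maps the model's molecule counts onto the imaged focus-size scale).
#'
#' @param sim an `"hp1_sim"` object (or list of trajectories).
#' @param min_size smallest raw size retained (default 2).
#' @param size_scale multiplicative rescaling of the retained sizes.
#' @param burn_in minutes excluded from the start of each trajectory.
#' @param all_components if `TRUE`, collect every component's size per
#'   state instead of only the giant one (sensitivity analysis).
#' @return An object of class `"aggregate_dist"`: a data frame with
#'   columns `time`, `replicate`, `raw_size`, `rescaled_size`, plus
#'   attributes recording the filter and scale.
#' @export
aggregate_distribution <- function(sim, min_size = 2L, size_scale = 0.096,
                                   burn_in = 0, all_components = FALSE) {
  trajectories <- if (inherits(sim, "hp1_sim")) sim$trajectories else sim
  if (!length(trajectories)) stop("no trajectories supplied")
  rows <- list()
  for (tr in trajectories) {
    keep <- which(tr$times >= burn_in)
    for (s in keep) {
      sizes <- component_sizes(tr$bound[s, ], tr$contacts[[s]])
      if (!length(sizes)) next
      vals <- if (all_components) sizes else max(sizes)
      vals <- vals[vals >= min_size]
      if (length(vals))
        rows[[length(rows) + 1L]] <- data.frame(
          time = tr$times[s], replicate = tr$replicate, raw_size = vals)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(time = numeric(), replicate = integer(),
                         raw_size = integer())
  out$rescaled_size <- out$raw_size * size_scale
  structure(out, class = c("aggregate_dist", "data.frame"),
            min_size = min_size, size_scale = size_scale,
            giant_only = !all_components)
}

# Component sizes of the bound-site contact subgraph for one state:
# isolated bound sites count as components of size 1.
component_sizes <- function(bound, contacts) {
  nb <- sum(bound)
  if (nb == 0L) return(integer())
  if (nrow(contacts)) {
    keep <- bound[contacts[, 1]] & bound[contacts[, 2]]
    contacts <- contacts[keep, , drop = FALSE]
  }
  if (!nrow(contacts)) return(rep(1L, nb))
  g <- igraph::graph_from_edgelist(
    matrix(as.character(contacts), ncol = 2), directed = FALSE)
  cs <- igraph::components(g)$csize
  n_in_graph <- igraph::vcount(g)
  c(cs, rep(1L, nb - n_in_graph))
}

#' @export
print.aggregate_dist <- function(x, ...) {
  cat(sprintf(
    "<aggregate_dist> %d aggregate size(s) (%s, min raw size %d, scale %g)\n",
    nrow(x), if (attr(x, "giant_only")) "giant component per state"
             else "all components", attr(x, "min_size"),
    attr(x, "size_scale")))
  if (nrow(x)) print(summary(x$raw_size))
  invisible(x)
}

#' Histogram of aggregate sizes
#'
#' @param x an [aggregate_distribution()] result.
#' @param rescaled plot rescaled (default) or raw sizes.
#' @param ... passed to [graphics::hist()].
#' @export
plot.aggregate_dist <- function(x, rescaled = TRUE, ...) {
  v <- if (rescaled) x$rescaled_size else x$raw_size
  if (!length(v)) stop("empty aggregate distribution")
  graphics::hist(v, xlab = if (rescaled) "aggregate size (rescaled)"
                           else "aggregate size (HP1 molecules)",
                 main = "HP1 aggregate sizes", ...)
  invisible(x)
}

#' Relative decrease of HP1 occupancy at pericentromeric heterochromatin
#'
#' Integrates the HP1 binding probability over the PCH units in the control
#' and perturbed (TM) conditions and returns the relative decrease
#' `1 - sum(tm\[pch\]) / sum(control\[pch\])`.
#'
#' @param control,tm per-site [probability_profile()]s (or numeric vectors)
#'   of equal length.
#' @param pch_mask logical mask of PCH units.
#' @return The relative decrease as a fraction (0.15 means a 15% drop).
#' @export
pch_occupancy_change <- function(control, tm, pch_mask) {
  control <- as.numeric(control); tm <- as.numeric(tm)
  pch_mask <- as.logical(pch_mask)
  if (length(control) != length(tm) || length(control) != length(pch_mask))
    stop("profiles and mask must be aligned")
  denom <- sum(control[pch_mask])
  if (denom <= 0) stop("control PCH integral is zero")
  1 - sum(tm[pch_mask]) / denom
}
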