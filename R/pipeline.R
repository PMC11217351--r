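#' Configuration for the end-to-end control-vs-TM analysis
#'
#' Builds (and validates) the configuration driving [run_hp1_pipeline()].
#' Defaults reproduce the synthetic-data-backed study setup: a 500-unit
#' lattice with a pericentromeric block, triplicate control and TM
#' simulations under the default kinetic rates, and all downstream
#' observables. Any field can be overridden; `yaml_file` loads overrides
#' from a YAML document instead.
#'
#' @param ... named overrides of the default fields (see the returned
#'   object's names).
#' @param yaml_file optional path to a YAML file of overrides.
#' @return A list of class `"hp1_config"`.
#' @export
hp1_config <- function(..., yaml_file = NULL) {
  cfg <- list(
    region = "chr2L:18520000-23513712",
    bin_size = 10000,
    # synthetic inputs (set tracks/peaks/pch paths to use real files)
    n_sites = 500L,
    pch_block = NULL,
    arm_density = 0.05,
    background_mean = 1, background_sd = 0.1,
    site_enrichment = 10, tm_pch_attenuation = 0.65,
    # real-data inputs (bedGraph / BED paths); NULL means synthesise
    hp1_control_track = NULL, hp1_tm_track = NULL,
    peaks = NULL, pch_mask = NULL, binding_sites = NULL,
    # simulation
    params = list(), coupling_mode = "bridging", spread_fiber = FALSE,
    duration = 300, n_replicates = 3L, sample_interval = 1,
    burn_in = 60, conditions = c("control", "TM"),
    # observables
    threshold = 0.5, n_shuffles = 10000L,
    min_size = 2L, size_scale = 0.096,
    seed = 1L)
  over <- list(...)
  if (!is.null(yaml_file)) {
    if (!file.exists(yaml_file)) stop("config file not found: ", yaml_file)
    over <- utils::modifyList(yaml::read_yaml(yaml_file), over)
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  cfg$conditions <- match.arg(cfg$conditions, c("control", "TM"),
                              several.ok = TRUE)
  for (f in c("hp1_control_track", "hp1_tm_track", "peaks", "pch_mask",
              "binding_sites")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured input file does not exist: ", f, " = ", cfg[[f]])
  }
  structure(cfg, class = "hp1_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full control-vs-TM analysis
#'
#' Executes, in order: input preparation (synthetic generation and
#' normalisation, or loading of user tracks), binding-site calling,
#' control and TM Gillespie simulations, probability profiles,
#' least-squares rescaling of the experimental track onto the simulated
#' profile, permutation-tested prediction accuracy, aggregate-size
#' distributions, and the PCH occupancy change. Optionally writes a
#' machine-readable JSON summary, the derived tracks, and two report
#' figures (profile overlay; aggregate-size histograms).
#'
#' @param config an [hp1_config()].
#' @param outdir output directory; `NULL` disables all file output.
#' @param plots write the report figures (requires `outdir`).
#' @return An object of class `"hp1_report"`: list with the fitted
#'   profiles, simulations, observables and the `summary` written to JSON.
#' @export
run_hp1_pipeline <- function(config = hp1_config(), outdir = NULL,
                             plots = TRUE) {
  stopifnot(inherits(config, "hp1_config"))
  seed <- as.integer(config$seed)

  # --- inputs -------------------------------------------------------------
  inputs <- pipeline_stage("inputs", {
    if (is.null(config$hp1_control_track)) {
      layout <- synth_layout(config$n_sites, config$pch_block,
                             config$arm_density, seed = seed)
      synth <- lapply(c(control = "control", TM = "TM"), function(cond) {
        synth_tracks(layout, cond,
                     background_mean = config$background_mean,
                     background_sd = config$background_sd,
                     site_enrichment = config$site_enrichment,
                     tm_pch_attenuation = config$tm_pch_attenuation,
                     seed = seed + (cond == "TM"))
      })
      list(region = layout$region,
           norm = lapply(synth, function(s) normalize_synth(s)$hp1),
           pch_mask = layout$pch_mask, peaks_mask = NULL, synth = synth)
    } else {
      region <- parse_region(config$region, config$bin_size)
      norm <- list(control = bin_track(
        read_bedgraph(config$hp1_control_track), region))
      if (!is.null(config$hp1_tm_track))
        norm$TM <- bin_track(read_bedgraph(config$hp1_tm_track), region)
      pch_mask <- if (!is.null(config$pch_mask))
        bed_to_mask(read_bed(config$pch_mask), region) else NULL
      peaks_mask <- if (!is.null(config$peaks))
        bed_to_mask(read_bed(config$peaks), region) else NULL
      list(region = region, norm = norm, pch_mask = pch_mask,
           peaks_mask = peaks_mask, synth = NULL)
    }
  })

  # --- binding-site calling ----------------------------------------------
  call <- pipeline_stage("call_binding_sites", {
    if (!is.null(config$binding_sites)) {
      mask <- bed_to_mask(read_bed(config$binding_sites), inputs$region)
      list(mask = mask, mean = NA_real_, sd = NA_real_)
    } else call_binding_sites(inputs$norm$control)
  })
  binding_sites <- call$mask
  if (!any(binding_sites))
    stop("pipeline stage 'call_binding_sites' failed: no sites called")
  pch_mask <- if (!is.null(inputs$pch_mask)) inputs$pch_mask
              else binding_sites
  # peaks default to the experimentally called binding sites
  peaks_mask <- if (!is.null(inputs$peaks_mask)) inputs$peaks_mask
                else binding_sites

  # --- simulations --------------------------------------------------------
  params <- do.call(rate_params,
                    c(config$params,
                      list(coupling_mode = config$coupling_mode)))
  sims <- list()
  for (cond in config$conditions) {
    sims[[cond]] <- pipeline_stage(paste0("simulate_", cond), {
      hp1_simulate(binding_sites, params, cond,
                   duration = config$duration,
                   n_replicates = config$n_replicates,
                   sample_interval = config$sample_interval,
                   seed = seed + match(cond, c("control", "TM")),
                   region = inputs$region,
                   spread_fiber = config$spread_fiber)
    })
  }

  # --- observables --------------------------------------------------------
  profiles <- lapply(sims, probability_profile, quantity = "hp1_binding",
                     burn_in = config$burn_in)
  meth_profiles <- lapply(sims, probability_profile,
                          quantity = "methylation", burn_in = config$burn_in)

  rescale <- comparison <- NULL
  if ("control" %in% names(profiles)) {
    rescale <- pipeline_stage("rescale_experimental",
      rescale_experimental(as.numeric(inputs$norm$control),
                           profiles$control))
    predicted <- predicted_bound_loci(profiles$control, config$threshold)
    comparison <- if (any(predicted))
      pipeline_stage("compare_to_peaks",
        compare_to_peaks(predicted, peaks_mask,
                         n_shuffles = config$n_shuffles, seed = seed))
    else NULL
  }

  aggregates <- lapply(sims, aggregate_distribution,
                       min_size = config$min_size,
                       size_scale = config$size_scale,
                       burn_in = config$burn_in)

  pch_decrease <- NULL
  if (all(c("control", "TM") %in% names(profiles)))
    pch_decrease <- pipeline_stage("pch_occupancy_change",
      pch_occupancy_change(profiles$control, profiles$TM, pch_mask))

  # --- summary ------------------------------------------------------------
  summary <- list(
    schema = "hp1sim-report/1",
    seed = seed,
    n_sites = length(binding_sites),
    n_binding_sites = sum(binding_sites),
    conditions = as.list(names(sims)),
    duration = config$duration, burn_in = config$burn_in,
    coupling_mode = config$coupling_mode,
    site_call = list(mean = call$mean, sd = call$sd),
    rescale_factor = if (!is.null(rescale)) rescale$factor,
    accuracy = if (!is.null(comparison)) comparison$accuracy,
    p_value = if (!is.null(comparison)) comparison$p_value,
    pch_occupancy_decrease = pch_decrease,
    aggregate_upper_quartile = lapply(aggregates, function(a) {
      if (nrow(a)) unname(stats::quantile(a$raw_size, 0.75)) else NULL
    }))

  report <- structure(
    list(summary = summary, config = config, region = inputs$region,
         binding_sites = binding_sites, pch_mask = pch_mask,
         norm_tracks = inputs$norm, sims = sims, profiles = profiles,
         meth_profiles = meth_profiles, rescale = rescale,
         comparison = comparison, aggregates = aggregates),
    class = "hp1_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_bed(mask_to_bed(binding_sites, inputs$region),
              file.path(outdir, "binding_sites.bed"))
    for (cond in names(profiles)) {
      write_bedgraph(signal_track(pmin(pmax(profiles[[cond]], 0), 1),
                                  inputs$region),
                     file.path(outdir, paste0("hp1_probability_", cond,
                                              ".bedgraph")))
      utils::write.table(
        as.data.frame(aggregates[[cond]]),
        file.path(outdir, paste0("aggregates_", cond, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (plots) {
      grDevices::pdf(file.path(outdir, "report.pdf"), width = 9, height = 6)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(report)
    }
  }
  report
}

#' @export
print.hp1_report <- function(x, ...) {
  s <- x$summary
  cat("<hp1_report>\n")
  cat(sprintf("  %d sites, %d binding sites; conditions: %s\n",
              s$n_sites, s$n_binding_sites,
              paste(unlist(s$conditions), collapse = ", ")))
  if (!is.null(s$accuracy))
    cat(sprintf("  prediction accuracy %.3f (permutation p = %.2g)\n",
                s$accuracy, s$p_value))
  if (!is.null(s$pch_occupancy_decrease))
    cat(sprintf("  PCH occupancy decrease in TM: %.1f%%\n",
                100 * s$pch_occupancy_decrease))
  invisible(x)
}

#' Report figures: profile overlay and aggregate-size histograms
#'
#' @param x an `"hp1_report"`.
#' @param ... ignored.
#' @export
plot.hp1_report <- function(x, ...) {
  # simulated binding probability vs rescaled experimental signal
  if ("control" %in% names(x$profiles)) {
    prof <- as.numeric(x$profiles$control)
    plot(seq_along(prof), prof, type = "l", ylim = c(0, 1.1),
         xlab = "lattice unit", ylab = "probability / rescaled signal",
         main = "HP1 binding: simulation vs experiment (control)")
    if (!is.null(x$rescale))
      graphics::lines(seq_along(prof), pmin(x$rescale$rescaled, 1.1),
                      col = "steelblue")
    graphics::legend("topleft", bty = "n", lty = 1,
                     col = c("black", "steelblue"),
                     legend = c("simulated probability",
                                "experimental / fitted factor"))
  }
  sizes <- lapply(x$aggregates, function(a) a$rescaled_size)
  sizes <- sizes[vapply(sizes, length, integer(1)) > 0]
  if (length(sizes)) {
    brk <- pretty(range(unlist(sizes)), 30)
    cols <- c(control = grDevices::adjustcolor("grey30", 0.6),
              TM = grDevices::adjustcolor("firebrick", 0.6))
    first <- TRUE
    for (cond in names(sizes)) {
      graphics::hist(sizes[[cond]], breaks = brk, freq = FALSE,
                     col = cols[[cond]], border = NA, add = !first,
                     xlab = "aggregate size (rescaled)",
                     main = "HP1 aggregate sizes")
      first <- FALSE
    }
    graphics::legend("topright", bty = "n", fill = cols[names(sizes)],
                     legend = names(sizes))
  }
  invisible(x)
}
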