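# Shared study-scale simulation fixture: triplicate control and TM runs on
# the 500-unit lattice with the default rates and layout, computed once per
# test session (several tests read different observables from it).
.sim_cache <- new.env(parent = emptyenv())

study_scale_sims <- function() {
  if (!is.null(.sim_cache$sims)) return(.sim_cache$sims)
  layout <- synth_layout(seed = 1)
  params <- rate_params()
  sims <- list(
    layout = layout,
    control = hp1_simulate(layout$binding_sites, params, "control",
                           duration = 300, n_replicates = 3,
                           sample_interval = 1, seed = 101,
                           region = layout$region),
    TM = hp1_simulate(layout$binding_sites, params, "TM",
                      duration = 300, n_replicates = 3,
                      sample_interval = 1, seed = 102,
                      region = layout$region),
    burn_in = 60)
  .sim_cache$sims <- sims
  sims
}
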