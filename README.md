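# hp1sim

Stochastic modelling of HP1 clustering on methylated chromatin, with the
quantitative CUT&Tag-style analysis stages it is compared against.

## What this is for

In early fly embryos, heterochromatin protein 1a (HP1a) reads
H3K9me2/3 and condenses into foci over pericentromeric heterochromatin
(PCH). A long-standing question is whether the methyl mark recruits HP1 to
chromatin or instead licenses HP1–HP1 interactions that cluster already
bound molecules. `hp1sim` is for researchers who want to explore that
question in a minimal, fully reproducible lattice model and to run the
accompanying genomics arithmetic (spike-in normalisation, binding-site
calling, permutation-tested overlap, cluster-size statistics) on real or
synthetic coverage tracks.

## The model

A genomic region is discretised into 10-kb units (the modelled region,
chr2L:18520000-23513712, gives 500 units). Each unit has three flags —
H3K9-methylated *m_i*, HP1-bound *b_i*, and a static binding-site
annotation — and holds up to `n_val = 5` spatial contacts. A continuous-time
Markov jump process with nine event classes is simulated exactly
(Gillespie SSA): noisy (de)methylation (`k_m`, `k_d`), HP1 binding
(`k_b`) and unbinding (`k_u` at binding sites, `k_y` elsewhere, both
blocked while the unit is in a contact), methylation spreading from
methylated+bound units through contacts (`k_n`), contact formation at
`k_c / L_ij^α` with `L_ij` the genomic distance possibly shortcut by one
existing contact, and contact breaking (`k_w` for methylated+bound
bridges, `k_z` otherwise). The triple-mutant (TM) condition zeroes `k_m`
and starts unmethylated. Observables are per-site binding/methylation
probabilities, predicted bound loci (probability > 0.5) with permutation
accuracy testing, and the giant component of the bound-site contact graph
as the HP1 aggregate (sizes ≥ 2, rescaled by 0.096).

See the vignette (`vignettes/hp1-clustering-model.Rmd`) for the full
model description, the numerical design, and an analysis of two regimes
of the published rate set (a network condensation transition under the
literal distance-shortcut rule, and a methylation-spreading ratchet in
the control) that bound what the model can reproduce.

## Worked example

Generate a synthetic CUT&Tag-like dataset, call binding sites, simulate
control and TM, and compare:

```r
library(hp1sim)

layout <- synth_layout(n_sites = 500, seed = 1)   # PCH block 401-500 + arm sites
data   <- synth_tracks(layout, "control", seed = 2)
norm   <- normalize_synth(data)                   # spike-in + H3 correction
call   <- call_binding_sites(norm$hp1)
call
#> <site_call> 120/500 bins called (fit clipped: mean 1.012, sd 0.1037, threshold 1.427)

params <- rate_params(formation_distance = "genomic")
ctrl <- hp1_simulate(call$mask, params, "control", duration = 150,
                     n_replicates = 3, seed = 3)
tm   <- hp1_simulate(call$mask, params, "TM", duration = 150,
                     n_replicates = 3, seed = 4)
pc <- probability_profile(ctrl, burn_in = 50)
pt <- probability_profile(tm,   burn_in = 50)

100 * pch_occupancy_change(pc, pt, layout$pch_mask)
#> 6.1      # percent HP1 lost from the PCH block in the TM

ac <- aggregate_distribution(ctrl, burn_in = 50)
at <- aggregate_distribution(tm,   burn_in = 50)
quantile(ac$raw_size, 0.75); quantile(at$raw_size, 0.75)
#> 491      # control: one giant HP1 cluster spanning the methylated network
#> 9        # TM: only small transient clusters remain
```

The caller recovers all 120 true sites with its background fit
(mean ≈ 1.01, sd ≈ 0.104, threshold = mean + 4·sd). In the TM the large
HP1 aggregates disappear (upper-quartile giant-component size 491 → 9
bound molecules) and PCH-bound HP1 drops by ~6%. The decrease at a pure
binding-site block is mathematically capped at
`1 − k_b/(k_b+k_u) ≈ 11.2%`; the vignette discusses this bound and why
prediction accuracy against peaks is poor when the control run
delocalises (`compare_to_peaks()` then reports accuracy ≈ 0.24, p ≈ 1 —
the honest outcome at the published rates).

An end-to-end run (synthesis → calling → both simulations → all
observables → JSON summary, BED/bedGraph tracks and report figures) is one
call:

```r
report <- run_hp1_pipeline(hp1_config(seed = 1), outdir = "out/")
```

or from a shell via the bundled thin CLI
(`inst/scripts/hp1sim synth|simulate|run-all`).

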