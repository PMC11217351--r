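---
title: "Modelling HP1 clustering on methylated chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HP1 clustering on methylated chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(hp1sim)
```

## The model

Heterochromatin protein 1 (HP1) reads H3K9 di/trimethylation and clusters
into foci that compact pericentromeric heterochromatin (PCH). This package
implements a minimal stochastic model of that process on a one-dimensional
chromatin lattice, together with the CUT&Tag-style quantification used to
confront it with data.

A chromosome region is discretised into units of 10 kb (the modelled
region, the last 5 Mb of *Drosophila* chr2L, gives 500 units). Each unit
carries three binary flags — H3K9-methylated, HP1-bound, and the static
annotation "HP1 binding site" (derived from data or synthesised) — and can
engage in up to `n_val = 5` spatial contacts with other units. The system
evolves by an exact Gillespie algorithm over nine event classes:

| event | rate (min^-1) | guard |
|---|---|---|
| random methylation | `k_m = 3.4e-6` | site unmethylated |
| demethylation | `k_d = 0.34` | methylated and HP1-free |
| HP1 binding | `k_b = 0.27` | site unbound |
| HP1 unbinding (binding site) | `k_u = 0.034` | bound, no contact |
| HP1 unbinding (other site) | `k_y = 3.4` | bound, no contact |
| methylation spreading | `k_n = 0.51` | donor methylated+bound, per contacted unmethylated acceptor |
| contact formation | `k_c / L_ij^alpha`, `k_c = 0.1`, `alpha = 1.5` | pair not in contact, both below valence cap |
| contact breaking, bridged | `k_w = 0.034` | both endpoints methylated+bound |
| contact breaking, other | `k_z = 0.69` | any other contact |

The published rates are used as defaults (`rate_params()`); they were fitted
in arbitrary units with `k_d = 1` and rescaled to minutes by a factor of
0.34 min^-1, which is carried as metadata. Two couplings make methylation
matter: it licenses its own spreading through the contact network, and it
stabilises HP1–HP1 bridges (the 20-fold gap between `k_w` and `k_z`). The
rejected alternative in which methylation gates only HP1 residence — `k_u`
on methylated, `k_y` on unmethylated sites, all contacts breaking at `k_z`
— is available as `coupling_mode = "binding_only"`; no separate rates are
published for it, so the defaults are reused and overridable.

Initial conditions mirror the experiments: all sites start HP1-free with no
contacts; binding sites start methylated in the control, while the TM
condition (triple mutant lacking all H3K9 methyltransferases) starts
unmethylated and has `k_m` set to zero.

```{r quick-sim}
sim <- hp1_simulate(rep(c(TRUE, FALSE), 10), rate_params(), "control",
                    duration = 100, n_replicates = 2, seed = 1)
summary(sim)
```

## Effective distance and the single-shortcut approximation

The contact-formation propensity uses an effective distance `L_ij`: the
genomic link count `|i - j|`, possibly shortcut by **at most one** existing
spatial contact,

`L_ij = min(|i - j|,  min over contacts (a, b) of |i - a| + 1 + |b - j|,
|i - b| + 1 + |a - j|)`.

This is deliberately *not* a shortest path on the full link graph: a route
chaining two contacts is never taken, so `effective_distance()` can exceed
the BFS distance (the tests pin this divergence explicitly). The `alpha`
exponent encodes the equilibrium contact probability of a polymer,
`P(contact) ~ d^-1.5`.

```{r distance}
con <- rbind(c(1, 11), c(11, 21))
effective_distance(2, 20, con)   # 11: a single shortcut only
```

### A condensation transition, and the `formation_distance` choice

Implementing the formation rule literally — re-evaluating `L_ij` against
the *current* contact set — produces a strong positive feedback at the
default rates: long-range contacts arise at a baseline rate of several per
minute across a 500-unit lattice, each one collapses the effective
distances of all pairs spanning it, which multiplies the formation
propensity of further long-range contacts. In our simulations the network
condenses within minutes (mean pairwise `L` drops from ~167 to ~12, ~700
concurrent contacts, mean degree ~2.8, median contact span >100 units), and
the onset is nucleation-limited, so whether a given 300-minute run
condenses depends on the random stream. In the condensed phase almost every
unit is engaged in some contact at all times. Because unbinding is blocked
for contacted sites, HP1 occupancy then saturates near 1 everywhere, in
both control and TM, and methylation spreads along the dense network far
beyond the binding-site block in long control runs. None of the behaviour
this model family is meant to capture — localised occupancy profiles,
TM-sensitive PCH binding, the disappearance of large HP1 clusters without
methylation — survives in that phase.

We therefore expose the kernel as a parameter. The default,
`formation_distance = "shortcut"`, is the literal rule and defines the
package's contracts and oracle tests. The alternative,
`formation_distance = "genomic"`, uses the plain genomic distance in the
formation rate — i.e. it treats `d^-alpha` as the polymer's equilibrium
contact kernel without network feedback — while all other rules (spreading,
breaking, valence, unbinding guards) still act on the actual dynamic
contact set. Under the genomic kernel the TM network stays sparse and
local: its large HP1 aggregates disappear (upper-quartile giant-component
size drops from ~490 bound sites in the control to ~10 in the TM at our
run lengths) and its PCH-bound HP1 decreases by ~6%, which is the
qualitative TM behaviour reported for this model class.

A second ratchet operates in the control under *either* kernel:
methylation spreads through contacts into non-binding sites, a freshly
methylated site that binds HP1 has its contacts stabilised at `k_w`, and a
stabilised, contacted site can neither unbind nor demethylate. At the
published rates this creep is faster than demethylation can erase it, so
in control runs of a few hundred minutes methylation and high HP1
occupancy extend far beyond the binding-site block regardless of the
formation kernel. Localised control profiles — a prerequisite for
meaningful binding-site prediction accuracy — are therefore not
reproducible in this implementation at the published rates, and the
accuracy/permutation stage will report honestly poor agreement on
model-derived predictions.

### A hard ceiling on the TM occupancy decrease

At binding sites the TM occupancy can never fall below the two-state value
`k_b / (k_b + k_u) = 0.888`, because contact protection can only *slow*
unbinding; the control occupancy is at most 1. Over a block consisting
purely of binding sites, the relative TM decrease is therefore bounded by
11.2% no matter what the contact network does. Larger decreases, such as
the ~15% reported for PCH in this model family, are only reachable when the
integration region also contains sub-threshold units, whose occupancy is
governed by the fast rate `k_y` and is far more sensitive to the loss of
contact protection. With the default layout (the PCH block consists
entirely of binding sites) the simulated decrease is ~0.7% in the condensed
phase and ~6% in the sparse phase — both well short of 15%, the first
because protection never lapses, the second because of the ceiling. We keep
the layout and the published rates as they are rather than tuning either;
the acceptance checks report the honestly computed value.

## Observables

*Probability profiles.* A site contributes 1 when methylated (or bound) and
0 otherwise; the mean over equally spaced snapshots, pooled across
replicates after an optional burn-in, is the methylation (binding)
probability (`probability_profile()`).

*Profile rescaling.* To compare a normalised CUT&Tag track with simulated
probabilities, the track is divided by the factor `c` minimising
`sum((exp/c - sim)^2)`, with the closed form
`c = sum(exp^2) / sum(exp * sim)` (`rescale_experimental()`).

*Bound-locus prediction and permutation testing.* Sites with binding
probability strictly above 0.5 are predicted bound loci. Their accuracy
against peaks is the fraction of predicted loci covered by peaks, and the
p-value reshuffles the predicted positions uniformly (10,000 times by
default) with the add-one estimator
`(1 + #{shuffled >= observed}) / (n + 1)`, which cannot return zero
(`compare_to_peaks()`). Uniform reshuffling is used because no blocking
structure is specified for the null.

*Aggregates.* For each sampled state the aggregate is the giant (largest)
connected component of the graph whose vertices are HP1-bound sites and
whose edges are contacts with both endpoints bound; one HP1 molecule is
counted per bound site. Sizes below 2 are discarded and the rest multiplied
by 0.096, the factor that matches the model's molecule counts to the imaged
focus-size scale (`aggregate_distribution()`; `all_components = TRUE`
collects every component for sensitivity analyses).

*PCH occupancy change.* `1 - sum(tm[pch]) / sum(control[pch])` over the PCH
mask (`pch_occupancy_change()`).

## The CUT&Tag-facing signal stages

Raw per-bin coverage is placed on a common quantitative scale by the
relative dm6/lambda spike-in read-count factors
(`spike_in_normalize()`), corrected for starting material by the
H3-to-mark factor ratio (`h3_correct()`), and optionally rescaled by
nuclei counts across developmental stages (`nuclei_normalize()`). All
three are scalar multiplications, so they are linear and commute; each is
recorded in the track's provenance.

Binding sites are called by fitting a Gaussian to the per-bin signal
distribution and thresholding strictly at the mean plus 4 standard
deviations (`call_binding_sites()`). A plain moment fit is biased by the
heavy right tail of true sites, so the default fit is iterative sigma
clipping initialised at the median/MAD (so a dense block of elevated bins
cannot capture the initial window) with the clipped standard deviation
divided by the truncated-normal consistency factor
`sqrt(1 - 2 k phi(k) / (2 Phi(k) - 1))` at the clip point `k = 3`; on pure
Gaussian noise the threshold then recovers the nominal tail expectation of
`N * P(Z > 4)` (about 0.016 false calls per 500 bins). Moment and
histogram-least-squares fits are selectable for comparison.

Peak-level quantification integrates the per-base normalised signal over
each peak extended by ±1 kb, by length-weighting the binned track
(`quantify_peaks()`); windows of neighbouring peaks are never merged.
Changes between conditions are summarised as `log2` ratios of the
integrals with an optional pseudocount (`log2_peak_ratio()`; the default
pseudocount of 0 raises an explicit error on 0/0).

Uncovered bedGraph positions count as zero coverage, matching dense
deepTools-style output; all coordinates are 0-based half-open in memory
and on disk.

## The synthetic-data generator

`synth_layout()` and `synth_tracks()` produce every input the pipeline
needs with known ground truth: a binding-site mask made of one contiguous
PCH-like block (by default the last 100 of 500 units) plus arm sites at 5%
density; HP1 and H3K9me3 tracks whose normalised scale is Gaussian
background (mean 1, SD 0.1) elevated 10-fold at binding sites; and
per-library spike-in read counts chosen so that running the normalisation
stages recovers the normalised truth exactly. In the TM the H3K9me3 track
is background everywhere and the HP1 elevation at PCH binding sites is
multiplied by 0.65, encoding the experimentally measured ~35% loss of
PCH-bound HP1a; arm sites keep control-level HP1, consistent with
methylation-independent recruitment there. A Poisson count mode
(`noise_model = "poisson"`) stresses the caller with count noise.

The generator emulates the *statistical* structure of spike-in normalised
tracks, not their genomic texture: no mappability gaps, repeat content,
fragment-length effects, or irregular peak shapes. Tests passing on
synthetic data therefore validate the pipeline's arithmetic and
calibration, not its robustness to those artefacts.

## Numerical and design notes

* The Gillespie loop is exact (no tau-leaping). Waiting times use the
  exponential law on the total propensity; events are chosen by a single
  uniform draw walked through the category totals.
* Site events cannot change any `L_ij` or formation eligibility, so the
  total formation propensity is cached between contact events. Contact
  events update the distance cache incrementally (a pruned min-update on
  addition; on removal, only pairs whose cached distance ran through the
  removed contact are recomputed) and refresh the cached total exactly
  every 512 contact events to keep floating-point drift negligible.
  `check_consistency = TRUE` rebuilds everything from scratch after every
  event and aborts on any mismatch; the test suite runs this on small
  lattices in both kernels.
* A state with zero total propensity is absorbing; the trajectory holds it
  to the horizon so degenerate parameter sets still produce full-length
  output.
* Replicate streams are derived deterministically from one master seed;
  trajectories are bit-reproducible given `(seed, replicate, params)`.
* Methylation spreading acts across spatial contacts only, matching the
  event rules; `spread_fiber = TRUE` additionally allows the fibre
  neighbours `i ± 1`.
* Test and acceptance runs use 300 simulated minutes with a 60-minute
  burn-in on the 500-unit lattice (occupancy plateaus well before the
  burn-in ends); the published simulations run ~100 h, which changes none
  of the occupancy conclusions but lets slow network coarsening proceed
  further.

## Known limitations

* No freely diffusing HP1 pool: the chromatin-bound interaction network is
  the proxy for focus formation, so absolute aggregate sizes depend on the
  0.096 calibration.
* No 3D polymer embedding; space enters only through the `d^-alpha`
  kernel and the valence cap.
* The literal dynamic-shortcut kernel condenses at the published rates
  (see above); quantitative occupancy contrasts between control and TM are
  bounded by the `k_b/(k_b + k_u)` ceiling at binding sites under either
  kernel.
* Parameter fitting is out of scope; the published fitted rates are
  shipped as defaults.
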