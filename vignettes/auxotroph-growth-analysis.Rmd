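---
title: "Modeling and measuring auxotroph fate in structured populations"
author: "auxofate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring auxotroph fate in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxofate)
```

## The scientific question

When a mutation knocks out an amino-acid biosynthesis pathway, the
resulting auxotroph saves the cost of synthesis but becomes dependent on
amino acids supplied by its environment -- in a dense, spatially
structured population, mostly on what its prototrophic ("wildtype")
neighbors leak. Whether such a mutant can invade therefore depends on
two opposing quantities: the growth benefit of dropping the pathway, and
the leakage flux actually available in its neighborhood.

`auxofate` implements the complete quantitative pipeline for studying
this question in time-lapse single-cell data from microfluidic growth
chambers: single-cell growth-rate estimation, local neighborhood
composition statistics with permutation nulls, a Monod-type
leakage/uptake growth model, and inference of the wildtype leakage rate
from observed auxotroph growth. Because raw imaging data are large and
external, the package also includes a first-class synthetic generator
that emulates the statistical structure of chamber tracking tables, so
every stage is testable end to end.

## Data model

The interchange format is a long *track table*: one row per cell per
frame with replicate, chamber, 0-based frame, time in hours, track id,
cell type (`WT` or `AUX`), centroid in chamber-local micrometers, length
and area. Frames are 5 minutes apart by default; coordinates live in a
40 um chamber whose `y = 0` side faces the feeding channel. Two
invariants matter downstream and are enforced by `validate_tracks()`:
frames within a track are consecutive (a track with a gap is split by
`split_track_gaps()`, because the growth fit and the minimum-frames
filter are defined on consecutive observations), and the cell type never
changes within a track. Files are plain CSV written with 17 significant
digits, so write/read round trips are value-exact.

## Single-cell growth rates

Cell length is the biomass proxy. For each track the specific growth
rate is the OLS slope of `ln(length)` against time over the full
lifetime of the cell (birth to division or loss); `doubling_time_min()`
converts to doubling times via `60 ln 2 / mu`. Three quality filters are
applied in a fixed order, and an exclusion log reports how many tracks
each rule removed:

1. *jump filter*: any consecutive-frame pair whose observed length
   changes by more than +/-15% (relative to the earlier frame) discards
   the whole track -- such jumps are segmentation artifacts, and the rule
   is evaluated on raw observed lengths;
2. *minimum frames*: tracks shorter than 5 consecutive frames are
   dropped;
3. *goodness of fit*: after fitting, records with R^2 not strictly
   greater than 0.8 are dropped. A zero-variance response is assigned
   R^2 = 0 (it carries no growth information), and an exactly linear
   log-length series R^2 = 1.

Strain comparisons are made at the replicate level: per-replicate mean
rates (mean +/- SEM) feed a classical paired t-test, with
Kruskal-Wallis available for distribution-level contrasts. Cell-level
t-tests are deliberately not offered for strain comparisons -- cells
within a chamber are not independent. No multiple-testing correction is
applied; raw p-values are reported with the conventional star labels.

## Neighborhood composition

The local covariate is the *auxotroph area fraction*: auxotroph area
divided by total cell area within a circular neighborhood centered on
the focal cell's centroid, excluding the focal cell itself. The default
geometry rule counts a neighbor's whole area if its centroid falls
within the radius; `rasterized_aux_fraction()` provides the pixel-area
variant (0.065 um grid) for segmentation masks, and the two agree up to
discretization. The default radius is 5 um -- the length scale over
which amino-acid exchange is effectively local -- with a 5/9/13 um sweep
(`radius_sweep()`) to show how the signal decays with distance.

Growth rate is a track-level quantity, so the default pairing covariate
is the lifetime mean of the per-frame fraction (frames with no neighbor
are skipped; tracks with no defined frame are dropped from correlations,
with counts logged). Association is measured by Spearman's rho on
mid-ranks, and significance by a permutation test: the growth rates are
shuffled against the fractions (10,000 draws by default) and the
two-sided p-value is the plain fraction of permutations with |rho| at
least the observed one, so the resolution floor is `1/n_perm`.
Correlations pool cells across replicates ("combined" statistics);
per-replicate values can be obtained by subsetting. Binned summaries
(`bin_growth_by_fraction()`, fixed-width or quartile bins) are for
visualization only -- inference always uses the continuous data.

## The leakage/uptake growth model

For an auxotroph surrounded entirely by producers, the model predicts
the best achievable growth rate relative to the wildtype:

    r = (1 + s) * i / (K_M + i)

where `s = (mu_max_aux - mu_wt) / mu_wt` is the fitness benefit of
dropping the pathway (measured between the supplemented auxotroph rate
and the minimal-medium wildtype rate), `K_M` the Monod constant of
growth on the internal amino-acid pool, and `i` the steady-state
internal concentration

    i = K_M * (eps L - lt + sqrt((eps L + lt)^2 + 4 eps L (1 + s))) /
        (2 ((1 + s) + lt)).

Here `L = l_wt I_C / (mu_wt K_M)` is the relative leakage flux of
producers (leaked vs growth-consumed amino acid), `lt = l_aux /
mu_max_aux` the relative auxotroph leakage, and `eps` the
auxotroph/wildtype ratio of transport rates. Defaults follow the
biological assumptions: `eps = 1` (no transporter mutations), `I_C = 20
K_M` (producers are internally saturated), and all concentrations are
expressed in units of `K_M`, on which `r` depends only through `i/K_M`.

`growth_heatmap()` evaluates `r` over a leakage x benefit grid using the
*shared-rate coupling* `l_aux = l_wt = l` (a single leakage rate in /h
feeds both `L` and `lt`), with `mu_max_aux = (1 + s) mu_wt` so the
auxotroph axis stays consistent with the benefit axis.
`critical_leakage()` finds the equal-growth point `r = 1` by bracketing
plus Brent root-finding (1e-10 relative tolerance); at that point the
internal concentration equals `K_M / s` exactly, which gives an
algebraic cross-check (for `s = 0.2`, `lt = 0.1` fixed, the squared
system is linear in `L` and yields `L* = 5.5` exactly). Two numerical
edge cases are made explicit rather than silent: parity has no solution
for `s <= 0`, and under the shared-rate coupling `r` saturates at
`(1+s) i_inf / (K_M + i_inf)` with `i_inf = eps (1+s) I_C`, so parity is
also unattainable for small positive `s` (roughly `s < 1/(eps I_C)`).

## Inferring the leakage rate

`infer_leakage()` chains the experimental estimate to the model: the
auxotroph growth rates are regressed linearly on the local *wildtype*
fraction and extrapolated to a fully wildtype neighborhood (`f_wt = 1`);
the shared leakage rate `l` is then found by inverting the strictly
monotone map `l -> r(l)` so the predicted maximum matches the
extrapolated one. The fold-change `L*/L_fit` states how much higher
wildtype leakage would have to be for auxotrophs to stop being
disadvantaged. Uncertainty is propagated by inverting at `mu_max_obs +/-
1 SE` -- an interval, not a posterior, matching the order-of-magnitude
spirit of the estimate.

One bias is worth knowing about: `r` is concave in the wildtype
fraction, so the linear extrapolation slightly *overestimates* the
maximum rate (about 1-2 SE at the scales used in the tests, i.e. a few
percent on the inferred `l`). This is a property of the extrapolation
method itself, not of its implementation; the recovery tests therefore
assert a relative-error bound on `l` rather than strict
confidence-interval coverage.

## The synthetic generator

`generate_chamber()` / `generate_replicates()` emulate the tracking
tables of chamber experiments with the conditions the analysis assumes:
40 um chambers, ~90/10 wildtype/auxotroph seeding, 5-minute frames over
12 h, five replicates with Normal(0, 0.01 /h) wildtype-rate offsets, a
wildtype rate of 0.70 /h, exponential length growth with division at 4
um into two exact half-length daughters, multiplicative lognormal length
noise (CV 2%), rare spurious length jumps (probability 0.005/frame,
factor drawn outside +/-15% so the jump filter has real work), washout
of cells crossing the open chamber side, and an 8 um exclusion strip
next to the feeding channel that is dropped from the output, as in the
image analysis.

Space is a 2D monolayer discretized into 1-um lanes. Cells in a lane are
stacked from the closed back wall and pushed toward the open side as the
stack grows -- a deliberately simple shoving rule (not a mechanical
model) that reproduces the qualitative boundary retention of real
chambers: lineages at the back wall persist, cells near the open side
wash out. At division the front daughter slips into an adjacent lane
with probability 0.2, letting mutant clusters spread sideways. The local
auxotroph fraction that drives the growth coupling is recomputed every
frame with the *same* 5 um centroid rule the analyzer uses, so generator
and analysis agree by construction.

Two couplings are available. In `linear` mode an auxotroph grows at
`mu_wt * max(0, r0 + beta * f)`; the defaults `r0 = 0.23/0.70` and
`beta = -0.3` echo the observed regime (auxotrophs about three times
slower than wildtype at `f = 0`, and roughly a 9% growth decrease per
10% increase in local auxotroph fraction). In `model` mode the relative
rate comes from the exchange model with the wildtype leakage flux scaled
by the local wildtype fraction `(1 - f)`; the default shared rate `l =
0.004 /h` was chosen once because the forward model then yields a
maximum auxotroph rate of 0.230 /h, again the observed regime.

What the generator does *not* emulate: mechanical cell-cell forces,
amino-acid reaction-diffusion fields, lineage-correlated growth noise,
fluorescence measurement, or real segmentation/tracking failure modes
beyond isolated length jumps. Passing tests on synthetic data therefore
demonstrate correctness and statistical behavior of the *analysis*, not
fidelity of any particular biological parameter; conclusions about real
data still require the real tracking tables. One visible consequence of
the shoving rule is that pooled wildtype correlations at very large n
(~1e5 tracks) can reach "significance" at |rho| ~ 0.03 through subtle
track-duration structure, even though wildtype rates are uncoupled by
construction -- a useful reminder that pooled permutation p-values at
that scale detect any departure from exchangeability, not necessarily a
growth effect.

## Numerical and testing choices

* Growth fits use exact two-pass centered sums, vectorized over all
  tracks; they match a per-track QR fit to 1e-12.
* `internal_concentration()` is validated against an independent
  bracketed root of the defining quadratic over randomized parameter
  sweeps (1e-9 relative).
* Permutation p-values are deterministic given a seed; seeded RNG is
  always scoped (`.Random.seed` is restored), so library calls never
  perturb user randomness.
* Type-I error of the permutation test is checked on 1,000 simulated
  null chambers (every cell growing at the wildtype rate, 2 h, one
  chamber each): the 5% rejection rate must sit inside the binomial 99%
  band. Piloted at 0.060.
* Parameter recovery is checked at the scale of the real data: datasets
  of ~300 auxotroph tracks (5 replicates x 2 chambers, 5 h, 150 initial
  cells) with `beta = -0.5` must give pooled negative rho at
  permutation p < 0.001 in at least 95 of 100 seeds; with `beta = 0`
  the correlation collapses and p-values are uniform. These problem
  sizes (shorter duration, denser seeding than the 12 h defaults) keep
  the suite fast while preserving the per-dataset track count that
  matters for power.
* The full default experiment (5 replicates x 5 chambers, 12 h) is
  exercised by `scripts/acceptance.R`, which regenerates every headline
  quantity from scratch.

## Known limitations

The shoving rule is an explicit invention (chamber hydrodynamics are not
modeled); the generator's growth couplings are phenomenological; the
leakage inference inherits the extrapolation bias described above; and
the permutation test assumes exchangeability of track-level rates, which
dense spatial structure can violate mildly at very large pooled n. The
model itself deliberately averages over space: it has no diffusion
length scale, so it upper-bounds the amino-acid supply an auxotroph in a
real cluster would see.
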