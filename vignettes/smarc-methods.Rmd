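---
title: "Dispersal-limited range shifts along river corridors: model and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersal-limited range shifts along river corridors: model and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smarc)
```

## The problem

Mountain plant communities respond to millennial-scale climate change by
shifting their elevation ranges, but the shift is not instantaneous: taxa
must physically disperse, and in complex terrain the realised migration
route is often the river valley.  Two lakes at the same elevation under the
same climate can therefore show very different vegetation histories purely
because one sits above a short, steep corridor to lowland refugia and the
other above a long, gentle one.  Sedimentary ancient DNA (sedaDNA) from
lake cores records which taxa were present in a catchment through time;
`smarc` provides (i) a deliberately simple stochastic simulator of taxon
migration along a one-dimensional river corridor (SMARC: Species Migration
Along River Corridors) and (ii) the statistical pipeline needed to compare
such simulations against sedaDNA count tables at single-taxon and community
level.

## The dispersal model

The landscape is a chain of cells along the river (default cell size 250
m), each with an elevation; the lake sits at distance zero.  Climate enters
only through a temperature-anomaly series (degrees C relative to present,
default time step 25 yr).  A taxon is described by its modern elevation
envelope `[elev_min, elev_max]` and a *distributional breadth*
`(elev_max - elev_min) / median(observations)`; the observations pooled
into the median are, by default, each constituent species' range endpoints
(a `pooling = "means"` switch uses range midpoints instead, since the
convention used to summarise multi-species sequence variants is not
uniquely determined by field practice).

At every time step, in order:

1. **Niche shift.** The anomaly is converted to an elevation shift through
   a fixed lapse rate (0.55 degC / 100 m): `shift = anomaly / lapse * 100`.
   The suitable band is the modern envelope translated rigidly by this
   shift; a cooling anomaly lowers it.  Band membership is closed at both
   ends.
2. **Extinction.** Occupied cells outside the band are vacated immediately.
   This is also the model's retreat mechanism: the niche edge sweeps the
   occupied range back.  We considered a stochastic retreat mirroring the
   advance rule, but rejected it because it would leave cells occupied
   outside the suitable band, breaking the invariant that occupancy is a
   subset of suitability on which several consistency checks rest.
3. **Establishment or colonization.**  A taxon absent from the whole
   corridor establishes with probability `p_establish` (0.8) *and* then
   colonizes the lowest-elevation suitable cell with probability `p_lowest`
   (0.01) — two sequential Bernoulli draws, net 0.008 per 25-yr step, so a
   waiting time of a few millennia under constant glacial forcing, which is
   why simulations start from 50,000 cal yr BP under a constant spin-up
   anomaly (the value interpolated at 21,500 cal yr BP).  An established
   taxon spreads according to the mode:
   * `terrain`: the occupied set grows only at its two ends.  An advance
     attempt at a front succeeds with probability
     `min(1, breadth * multiplier)`, the multiplier being 1 for a single
     occupied cell, 2 for 2–10 and 3 for more than 10 (dispersal ability
     grows with population extent).  On success the front extends by `k`
     cells, `k` uniform on `{1, ..., K}` where `K` caps at the dispersal
     limit (100 m/yr, i.e. 10 cells per step) and at the contiguous run of
     suitable unoccupied cells beyond the front.  The uniform draw
     realises "at least one cell, at most the dispersal maximum" without
     further assumptions; `deterministic_advance = TRUE` replaces it by
     `k = K`, and `p_advance` can replace the breadth law by a constant —
     both exist chiefly to create exactly solvable limits for testing.
   * `elevation_only`: no dispersal limitation; every suitable unoccupied
     cell is colonized independently with probability `p_establish` this
     step.  This is the null model against which the effect of terrain is
     measured.
4. **Presence extraction.** The taxon counts as present in the catchment
   when its highest occupied elevation reaches the lake elevation
   (inclusive by default — a range exactly touching the lake counts; a
   strict rule is available via `presence_rule = "gt"`).

Ensembles repeat the run (default 30 times, run `r` seeded `seed + r`, so
everything is bit-reproducible), and are summarised by the per-step
presence fraction, a majority-vote series (> 50% of runs), and 1,000-yr
bins in which a bin is present when any of its 40 steps is present (a
majority-of-steps rule is available; the any-step rule matches how a
millennial proxy sample integrates decades of input).

### What the engine deliberately ignores

One-dimensional corridors (no 2-D diffusion), no seed banks, no species
interactions, no taphonomy, and a niche of constant width (pure shift).
These are modelling choices inherited from the design the package
implements, not incidental omissions: the point is to isolate the effect
of corridor geometry on migration timing.

## The proxy pipeline

sedaDNA count tables (samples x taxa with sample ages) are normalised by
**rarefaction**: each sample is subsampled without replacement to a fixed
depth (default 6,652 reads, a typical minimum sample total) 100 times, and
the per-cell mean over replicates is used downstream; samples below the
depth are dropped because subsampling beyond the total is undefined.
Replicate row sums equal the depth exactly and the mean is an unbiased
estimate of the hypergeometric expectation — both are tested.

Taxa are filtered by occurrence frequency (present in at least 3 samples)
and overall relative abundance (strictly above 0.03% for model evaluation;
0.02% is the conventional display threshold).  The thresholds are applied
to the mean rarefied table; whether one filters before or after rarefaction
is not settled by convention, so the functions accept either input.

Samples are then averaged in half-open 1,000-yr bins (`[k, k+1)` ka, so an
age of exactly 14,000 falls in the 14–15 ka bin), and compositions receive
the **Box-Cox-chord transformation with exponent 0**: `log(y + 1)` per cell
(the count-data variant of the log transform, so zeros map to zeros)
followed by row scaling to unit Euclidean norm.  All-zero rows stay zero.
Binarisation to presence/absence uses a strictly-greater-than-zero rule on
the mean rarefied count — the minimal choice, exposed as a threshold
parameter.

Grouped richness counts present taxa per elevation band of their mean
species elevation maximum (lowland below 4,000 m, mid 4,000–4,800 m,
upland above 4,800 m; the first boundary is exclusive from below and the
second inclusive, so both boundary values fall in the middle band), and
community trait means average a trait over the present taxa per bin.

## Model–proxy comparison

Per taxon, agreement between the binned simulated and proxy
presence/absence series is the **simple matching coefficient** (fraction
of bins agreeing, counting joint absences as agreement — appropriate here
because absence is an informative state of the catchment).  Its
significance comes from a permutation test that permutes the time order of
the simulated series freely (999 permutations by default; exhaustive
enumeration, hence exact p-values, for 8 bins or fewer).  The p-value
counts ties, `p = (1 + #{SMC_perm >= SMC_obs}) / (n_perm + 1)`, so it is
valid but — as for any permutation test on short, heavily tied binary
series — conservative: its null distribution given the two series' margins
is hypergeometric with few support points, and the realised size at
nominal 5% is nearer 1.5–2% for 18 bins.  A constant simulated series is
invariant under permutation and gets p = 1 with a note.

At the community level, the (transformed) bins-x-taxa matrices of both
lakes are stacked into one **joint principal component analysis**
(column-centred, unscaled — the standard ordination of pre-transformed
community data), so both lakes' 1-ka time slices live in a common space.
Simulated presence/absence matrices receive the same Box-Cox-chord
transform before ordination by default so that model and proxy
trajectories share a geometry; a raw-binary route is available.
Trajectories are summarised by their PC1 scores and by **segment lengths**
(Euclidean distances between consecutive time slices in the PC1–PC2
plane — the plane one plots; full-space segments via a flag), and model
and proxy are correlated with Pearson's r and the usual t-test on n - 2
degrees of freedom.  `compare_modes()` tallies, per taxon and growth form,
whether the terrain mode agrees with the proxy better than the
elevation-only mode.

Where the paper-scale analysis does not pin down an aggregation rule, the
default here is: ensemble to single series by majority vote before the
SMC, with a per-run-SMC-then-mean variant behind `per_run = TRUE`.

## Synthetic scenarios

The generator builds everything needed for a desk-scale study:

* `make_profile()`: monotone linear corridors from a 4,000-m lake to a
  3,000-m lowland — 100 km ("steep") or 400 km ("gentle"), the contrast
  that produces a migration lag, or arbitrary piecewise profiles.
* `make_forcing()`: a stylised deglaciation through anomaly knots — -6
  degC at 18 ka, warming to -2 by 14 ka, a cold reversal to -4 at 12 ka, 0
  through 10–4 ka, -1 at present — padded and regridded.  The values
  sketch the familiar late-glacial/Younger-Dryas/Holocene sequence at the
  magnitude of Northern-Hemisphere deglacial warming.
* `make_taxa()`: niches drawn per elevation band (lowland taxa top out at
  4,000–4,200 m so catchment presence at a 4,000-m lake is climate-gated;
  upland taxa live above 4,600 m) with growth forms and heights (trees
  tallest, cushion plants smallest).
* `make_proxy()`: sedaDNA-like counts conditioned on simulated presence —
  negative-binomial read totals (mean 10,000, dispersion 20: overdispersed
  like real libraries), reads shared multinomially among present taxa,
  and an optional false-detection rate for absent taxa (default 0: clean
  fixtures; noise studies set it explicitly).

What passing tests on such scenarios show — and what they do not: they
validate the machinery (conservation laws, oracle limits, calibration,
sign properties such as "gentle corridors delay lowland trees by more than
a millennium relative to steep ones, and the terrain mode then agrees
better with the proxy") under a generative model whose detections track
presence almost perfectly.  Real sedaDNA adds taphonomic loss, PCR bias
and taxonomic ambiguity that the generator does not emulate, so agreement
statistics on real data will be lower and noisier than on these fixtures.

## Numerical choices and degenerate inputs

Linear interpolation everywhere (forcing and terrain regridding) —
splines would invent structure the inputs do not have.  Grids must be
regular before simulation; the constructors enforce it.  Ties: band
membership inclusive; presence at exactly lake elevation inclusive;
establishment picks the first of equally lowest suitable cells; age bins
half-open.  Degenerate cases defined rather than erroring where a value
exists: zero-breadth niches never spread beyond their establishment cell;
empty suitable sets simply prevent establishment; all-zero composition
rows stay zero through the chord step; constant series give permutation
p = 1.  Errors are classed (`smarc_input_error`, `smarc_config_error`) and
the command-line driver maps them to exit codes 2 and 3.

## Problem sizes

The packaged study conditions use 2,001 forcing steps (50 ka at 25 yr),
401- and 1,601-cell corridors, 30-run ensembles, and scenario taxon sets
of a dozen niches; a full paired-lake scenario with both modes runs in a
couple of minutes on one core.  Unit tests use a 5-ka forcing and a 41-cell
corridor so the whole suite stays under a minute.

## Known limitations

The advance-probability law (`min(1, breadth * multiplier)`) is the
simplest monotone choice consistent with the qualitative description it
implements; other monotone laws would change absolute colonization ages
(not the steep-vs-gentle ordering, which the tests check).  The
permutation test's conservatism on short binary series is intrinsic;
treat per-taxon p-values as honest upper bounds.  Majority-vote
aggregation before the SMC discards between-run variance; use
`per_run = TRUE` when that matters.  The engine's corridor is strictly
one-dimensional: braided valleys or multiple routes to a catchment are
out of scope.
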