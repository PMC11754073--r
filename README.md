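# smarc

Dispersal-limited simulation of plant taxon migration along river
corridors, with the statistical pipeline to compare such simulations
against sedimentary ancient DNA (sedaDNA) records.

## The problem

On millennial time-scales, mountain plant taxa track climate by shifting
their elevation ranges — but only as fast as they can disperse, and in
steep terrain the realised route is the river valley.  Two alpine lakes at
the same elevation under the same climate history can show very different
vegetation trajectories if one lies above a short, steep corridor to
glacial lowland refugia and the other above a long, gentle one: the second
catchment is colonized with a *migration lag* of centuries to millennia.
sedaDNA metabarcoding of lake sediments records which taxa were actually
present in each catchment through time, so pairing a dispersal simulation
with a sedaDNA time series lets one test how much of the vegetation
trajectory is explained by terrain-mediated connectivity rather than
climate alone.

`smarc` is aimed at paleoecologists and modellers who want that pairing at
desk scale: simulate, generate or ingest count tables, and quantify
model–proxy agreement.

## The model in brief

The corridor is a 1-D chain of 250-m cells with elevations; climate is a
temperature-anomaly series on 25-yr steps.  A taxon's suitable band is its
modern envelope `[elev_min, elev_max]` shifted by `anomaly / 0.55 * 100` m
(lapse rate 0.55 °C/100 m).  Each step applies: (1) the band shift, (2)
immediate extinction of occupied cells outside the band, (3) establishment
(probability 0.8 × 0.01 per step while absent, at the lowest suitable
cell) or colonization — in `terrain` mode the occupied set grows only at
its two fronts, with probability `min(1, breadth × multiplier)` (breadth =
range/median of the elevation observations; multiplier 1, 2 or 3 as 1,
2–10 or >10 cells are occupied) and by at most the dispersal limit of 100
m/yr; in `elevation_only` mode every suitable cell is colonized with
probability 0.8, no dispersal limit — and (4) presence extraction: the
taxon is present in the catchment when its highest occupied elevation
reaches the lake elevation.  Ensembles of 30 seeded runs are summarised by
majority vote and 1-ka bins.

The proxy pipeline rarefies count tables to a common depth (6,652 reads,
100 replicates, means kept), filters taxa by frequency (≥ 3 samples) and
relative abundance (> 0.03 %), bins to 1 ka, and applies the
Box-Cox-chord transform with exponent 0 (log1p then unit row norm).
Agreement per taxon is the simple matching coefficient with a permutation
test; at community level, a joint principal component analysis of both
lakes' trajectories yields PC1 scores and segment lengths that are
correlated (Pearson) between model and proxy.

## Worked example

A lowland tree analog (envelope 3000–4100 m a.s.l.) migrating toward a
4000-m lake behind a steep 100-km versus a gentle 400-km corridor, under a
stylised deglacial forcing:

```r
library(smarc)

forcing <- make_forcing()                      # -6 °C at 18 ka ... -1 °C today
steep   <- make_profile("steep")               # 4000 -> 3000 m over 100 km
gentle  <- make_profile("gentle")              # same drop over 400 km
tree    <- build_niche("lowland_tree", c(3000, 4100))
tree
#> Taxon niche lowland_tree: 3000-4100 m a.s.l. (median 3550, mean 3550), breadth 0.3099

cfg <- smarc_config(mode = "terrain", n_runs = 30, seed = 1)
fit_steep  <- smarc(tree, steep,  forcing, cfg)
fit_gentle <- smarc(tree, gentle, forcing, cfg)
fit_gentle
#> SMARC simulation: 1 taxa, 30 runs, terrain mode
#>   window 18000-0 cal yr BP (721 steps, 18 complete 1000-yr bins)
#>   lake elevation 4000 m a.s.l.

summary(fit_steep)
#>       taxon_id   breadth mean_presence bins_present median_first_arrival
#> 1 lowland_tree 0.3098592     0.4687009           10                10225
summary(fit_gentle)
#>       taxon_id   breadth mean_presence bins_present median_first_arrival
#> 1 lowland_tree 0.3098592     0.2939898            7                 7075
```

Behind the steep corridor the tree reaches the lake at a median 10,225 cal
yr BP — essentially as soon as the warming climate allows.  Behind the
gentle corridor it arrives at 7,075 cal yr BP: a migration lag of ~3,150
years caused purely by the longer dispersal route, the corridor-connectivity
effect the model exists to isolate.  `plot(fit_gentle)` draws the ensemble
presence fractions; `make_proxy()` turns fits into sedaDNA-like count
tables; `compare_presence()` and `joint_pca()` quantify model–proxy
agreement (see the vignette in `vignettes/smarc-methods.Rmd`).

A thin command-line driver with `synth` / `simulate` / `compare`
subcommands lives at `inst/cli/smarc.R` (exit codes: 0 success, 2 input
error, 3 config error).

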