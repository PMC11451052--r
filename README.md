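# proximap

Proximity mapping for multiplexed single-molecule localization microscopy.

## The problem

Sequential multiplexed DNA-PAINT (Exchange-PAINT / FLASH-PAINT) images many
protein targets in the same cell, one per imaging round: each round's blinking
events are fitted to super-resolved localizations, the previous round's signal
is erased, and the next target is imaged. The result is one localization table
per target. Two questions follow immediately:

1. **Registration.** Rounds are acquired minutes apart, so each channel
   carries its own rigid stage offset. Before any cross-channel geometry can
   be measured, every round must be brought into a common frame.
2. **Proximity.** Given aligned point clouds, how close is target A to target
   B? The statistic used for multiplexed Golgi mapping is the *directed median
   nearest-neighbor distance*: for every localization in channel A, the
   Euclidean distance to its nearest neighbor in channel B, discarding
   distances of 500 nm or more; the median of the retained distances is the
   heatmap entry for A → B. Applied to Golgi markers ordered along the
   cis-to-trans axis, this matrix reads out sub-compartment organization —
   e.g. whether a protein such as VPS13B sits nearer the cis face (GM130,
   GRASP65) or the trans side (Golgin97, TGN46).

proximap implements the full pipeline — rendering, cross-correlation
registration with sub-bin refinement, kd-tree NN distances with cutoff,
median matrices, violin-table exports, and NeNA-style localization-precision
estimation — plus a synthetic-data generator that emulates the experiment
(layered Golgi ministacks, interface-confined puncta, blinking, linkage
error, nonspecific background, per-round misalignment, inter-round
carryover) so every stage is testable against known ground truth.

## The statistic

For source channel `S` and target channel `T` with cutoff `c` (default
500 nm):

```
d_i = min_{t in T} || s_i - t ||        for every s_i in S
D(S -> T) = { d_i : d_i < c }
M[S, T]  = median( D(S -> T) )
```

The matrix is directed (`M[S,T] != M[T,S]` in general); an optional
symmetrized variant pools both directions. Entries backed by fewer than
`min_pair_count` retained distances (default 50) are reported missing.
Per-channel localization precision is estimated from within-channel repeats:
distances between localizations in adjacent camera frames follow a Rayleigh
distribution `d/(2σ²)·exp(−d²/(4σ²))` for true repeats, fitted as a mixture
with a linear background.

## Worked example

```r
library(proximap)

model <- default_golgi_model(seed = 7)          # 7 Golgi markers + VPS13B
cfg   <- acquisition_config(names(model$layouts))
ex    <- simulate_experiment(model, cfg, seed = 7)

al <- align_rounds(ex$tables)                   # register rounds to GM130
pm <- proximity_map(al$aligned)                 # median NN-distance matrix
pm
#> Proximity map: 8 channels, cutoff 500 nm (directed)
#> Median NN distances (nm), source rows -> target columns:
#>          GM130 GRASP65 Giantin GALNT2 Rab6 Golgin97 TGN46 VPS13B
#> GM130      0.0     9.1    39.5   54.8 70.0    118.4 137.4   37.6
#> GRASP65    8.3     0.0    29.0   42.9 54.4    107.7 126.4   28.8
#> Giantin   46.3    34.0     0.0    8.9 15.1     55.2  75.5   52.5
#> GALNT2    64.2    50.2     9.4    0.0  9.0     36.2  55.7   69.9
#> Rab6      76.0    59.1    12.8    8.6  0.0     20.9  36.2   82.8
#> Golgin97 129.8   116.9    47.6   33.3 20.9      0.0   9.7  128.3
#> TGN46    153.5   138.3    69.2   54.7 37.2      9.5   0.0  140.9
#> VPS13B    15.0     8.6    24.9   35.0 50.5    106.6 120.3    0.0

rank_partners(pm, "VPS13B")
#>   target_id  median_nm
#> 1   GRASP65   8.552049
#> 2     GM130  14.951674
#> 3   Giantin  24.936210
#> 4    GALNT2  34.980867
#> 5      Rab6  50.476590
#> 6  Golgin97 106.560423
#> 7     TGN46 120.295257

estimate_precision(al$aligned$GM130)
#> Localization precision (GM130): sigma = 4.95 nm from 1742 pairs [nena_adjacent_frame_nn]
```

Reading the output: the reference-marker block shows the expected
cis-to-trans gradient — markers adjacent in the stack are ~9 nm apart
(dominated by localization error and labeling offsets), while GM130 → TGN46
spans ~140 nm. The VPS13B row ranks the cis markers (GRASP65, GM130) closest
and the TGN markers furthest, the signature of a protein confined to the
cis/medial interface; the simulated ground truth places its puncta exactly
there. The precision estimate recovers the simulated 5 nm localization error.

`plot(pm)` draws the annotated heatmap. `as.data.frame(pm)` returns the
long-format per-pair distances behind violin plots, and
`precision_table(al$aligned)` the per-channel precision table.

The same pipeline runs from a single YAML configuration —
`run_pipeline("config.yaml")` in R, or from a shell:

```sh
Rscript inst/cli/proximap init-config --output config.yaml --seed 7
Rscript inst/cli/proximap run --config config.yaml --output out/
```

which writes the per-channel tables, registration report, median matrix,
heatmap, violin table, precision table, and a run manifest. Real data enter
through `mode: real` with per-channel CSV or HDF5 localization tables
(camera-pixel units are converted with the effective pixel size, default
108 nm).

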