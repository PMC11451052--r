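---
title: "Methods: proximity mapping of multiplexed localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity mapping of multiplexed localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind proximap, the choices
made where the method leaves room, and what the synthetic-data generator
does and does not capture about real multiplexed DNA-PAINT experiments.

## 1. The measurement model

A sequential multiplexed experiment produces one localization table per
target: rows of `(x, y)` coordinates in nm, a camera frame index, and
optionally a per-localization precision. Each labeled binding site
contributes many localizations ("blinks"), each displaced from the true
epitope by two errors:

* **localization error** — isotropic Gaussian noise with per-coordinate
  standard deviation `sigma_loc`, independent per blink;
* **linkage error** — the antibody/nanobody/docking-strand stalk, a fixed
  offset per site (drawn once, uniform direction, fixed magnitude
  `linkage_radius`), because the label does not move between blinks.

Rounds are acquired sequentially, so each table additionally carries a rigid
stage shift, a uniform rate of false localizations, and — when the erasure of
the previous round's adapter is incomplete — carryover blinks from the
previous target's sites.

## 2. The proximity statistic

For source channel $S$ and target channel $T$, every source localization
contributes its Euclidean distance to the nearest target localization;
distances $\ge c$ (cutoff, default 500 nm) are discarded, and the median of
the retained sample is the matrix entry $M[S,T]$. Choices made here:

* **Strict cutoff.** Only pairs *strictly closer* than the cutoff are
  considered; boundary equality is excluded.
* **Directed by default.** $M[S,T]$ and $M[T,S]$ differ whenever densities or
  geometries differ (a sparse channel inside a dense one is close to it, not
  vice versa). Both directions are always computed and stored; an optional
  `symmetrize` mode pools the two distance samples per unordered pair.
* **Median** is the standard sample median (midpoint of central order
  statistics for even $n$); no interpolation variant.
* **Small samples.** Entries with fewer than `min_pair_count` (default 50)
  retained distances are reported `NA` rather than as unstable medians.
* **Ties** in the NN search resolve to the lowest target row index; tied
  candidates are equidistant, so nothing downstream changes.
* **Degenerate inputs.** An empty target channel yields an empty distance
  sample (`n_kept = 0`), not an error; a single-channel dataset is a contract
  error.
* **2D.** Distances are 2D Euclidean, matching TIRF acquisition where the
  axial dimension is not resolved.

The NN queries go through a kd-tree (RANN) with radius-bounded search; the
test suite holds it to *exact* agreement with an exhaustive $O(n^2)$ search
over hundreds of random instances, so the tree is an implementation detail,
not an approximation.

The interpretation caveat: measured medians include both labels' linkage
errors and localization noise, so they overestimate true epitope separations
by an amount that is not corrected (none is published for this assay). For
dense targets the minimum over many noisy candidates also biases distances
*down* by roughly $\sigma\sqrt{2\ln k}$ for $k$ effective competitors; at
separations well above the noise scale the median still tracks the true
separation, which is what the layer-separation recovery test asserts (within
10% at separations of 50-100 nm with 5 nm localization error).

## 3. Round registration

Rounds are aligned by rendering each channel as a 2D histogram (half-open
bins, default 10 nm), cross-correlating each moving channel against the
reference channel's render via FFT, taking the admissible integer peak
(bounded by `max_shift`, default 500 nm), and refining to sub-bin precision
with a 1D quadratic fit per axis around the peak. The sign convention is
that applying the reported `(dx, dy)` to the moving channel superimposes it
on the reference. Rigid translation only: rounds share one mechanical mount,
and frame-resolved drift correction is assumed done upstream by the
reconstruction software. The reference round defaults to the first.

Registration of *different* targets deserves a caution that shaped the
synthetic model: two laterally disjoint structures (say, thin cis and trans
bands 200 nm apart) contain *no information* about their relative alignment —
any correlation peak is an artifact of band tangency. What anchors
cross-round correlation in practice is structure shared by all rounds:
overlapping footprints of tilted stacks and, importantly, nonspecific
binding — imagers stick to the same high-affinity spots in every round. The
generator therefore models false localizations as blinks from a persistent
set of nonspecific sites (fixed positions across rounds within one
experiment), at a default rate of 25 localizations/µm²/round (~7% of signal,
a realistic DNA-PAINT background fraction), concentrated on fewer, brighter
sites (`false_site_brightness = 3`), as sticky hotspots are. With that
component present, injected shifts up to 100 nm are recovered to well within
half a bin per axis (asserted over 20 seeds in the acceptance tests).

## 4. The synthetic Golgi model

The generator emulates the statistical structure of a multiplexed Golgi
experiment in 2D projection:

* **Geometry.** A ribbon of total length 5.6 µm fragmented into 8 ministack
  segments placed on a jittered ring (a perinuclear ribbon), each with a
  random in-plane orientation, a random cis-to-trans polarity, and a random
  3D tilt. With $z$ the cosine of the stack axis' angle to the optical axis,
  in-plane offsets are foreshortened by $\sqrt{1-z^2}$ and the projected band
  widens by $|z| \cdot$ `face_extent` (default 300 nm). Tilts are drawn
  $|z| \sim \mathrm{Beta}(1,3)$: predominantly edge-on, as in the
  acquisitions this emulates, where cis and trans bands are laterally
  resolved; the tilted minority contributes the overlapping mass real
  registration relies on. A single-segment mode (`segments = 1`) gives a
  deterministic flat (or constant-curvature) edge-on ribbon used throughout
  the tests.
* **Layers.** Each reference marker is a band parallel to the segment axis at
  its cis-to-trans offset. Default offsets (nm): GM130 0, GRASP65 15,
  Giantin 90, GALNT2 110, Rab6 130, Golgin97 190, TGN46 210 — a ~210 nm
  stack with 25-40 nm inter-cisternal spacing, consistent with EM
  ultrastructure of the mammalian Golgi. Site counts scale with membrane
  area (band length x thickness, default 20 nm), not projected area, at
  4000 sites/µm² (one site per ~12 nm of ribbon, so edge-on bands render as
  continuous lines at 5 nm precision).
* **VPS13B.** 20 puncta of radius 40 nm confined to the cis/medial
  interface. The contact-site disk lies in the interface plane (normal =
  stack axis): edge-on it projects to a line at the interface offset,
  foreshortened axially by the tilt. Its offset (35 nm) sits on the cis side
  of the cleft between the cis cisternae (0-15 nm) and the first medial
  cisterna (90 nm), encoding the reported finding that the protein is
  closest to cis markers, then the medial set, then the TGN.
* **Acquisition.** Blinks per site follow a Poisson law by default (mean 5);
  a geometric option exists because DNA-PAINT blink counts are often closer
  to geometric, and a deterministic `fixed` law supports noise-off
  construction checks. Frames are assigned in binding-event runs (geometric
  event length, mean 3 frames) so that adjacent-frame repeats exist, as they
  do in real movies — this is what the precision estimator consumes.
  Carryover is modeled as whole sites persisting one round (binomial with
  probability `1 - erasure_efficiency`, default 0.995); no second-order
  carryover.
* **Determinism.** Same seed, same everything: sub-streams for segment
  placement, per-target sites, per-round noise and the nonspecific sites are
  derived from the model seed by a small label-hash, and every seeded call
  restores the caller's RNG state.

Parameters the experiment does not publish — labeling densities, blink
statistics, erasure efficiency, background rates, inter-cisternal offsets —
are set once to the field-realistic values above; they are configuration,
not fitted quantities.

What the generator does **not** capture: frame-level photophysics (on/off
kinetics, camera noise, PSF fitting — simulation starts at the localization
level), 3D structure beyond the tilt projection, chromatic effects,
cell-to-cell variability of Golgi architecture, and any spatial correlation
between specific and nonspecific binding. Passing tests therefore validate
the *analysis* under a faithful statistical emulation, not the upstream
reconstruction of real movies.

## 5. Localization precision (NeNA-style)

The same site localized in adjacent frames yields two independent estimates
of one position, whose displacement magnitude is Rayleigh:
$p(d) = \frac{d}{2\sigma^2} e^{-d^2/(4\sigma^2)}$. For every localization in
frame $f$ the distance to its nearest neighbor in frame $f+1$ (within
`fit_range`, default 100 nm) is collected, and the mixture of this Rayleigh
with a linear chance-pair background $2d/R^2$ is fitted by maximum
likelihood (Nelder-Mead on $(\log\sigma, \mathrm{logit}\,w)$, initialized at
the Rayleigh median estimator). $\sigma$ is reported as the per-coordinate
precision, with the method label embedded in the output. Tables with fewer
than 100 localizations, or fewer than 30 adjacent-frame pairs, are an
insufficient-data error; an exactly repeated-localization sample (zero
error) short-circuits to $\sigma = 0$. The estimator is validated against
simulations with known $\sigma \in \{5, 10, 20\}$ nm to within 10%.

Pairing adjacent frames rather than taking the plain within-channel NN is
essential: with $k$ blinks per site, the plain NN is the *minimum* of $k-1$
Rayleigh draws and underestimates $\sigma$ by up to several-fold, while
adjacent-frame pairs are single draws regardless of $k$.

## 6. Pipeline, configuration, problem sizes

`run_pipeline()` chains simulate/ingest, optional alignment, proximity, and
precision from one YAML file in which every default is explicit (the shipped
`inst/extdata/example_config.yaml` is the generated default). Every run
writes a manifest (config snapshot, package version, seed, per-stage row
counts, output inventory, wall time) whether it succeeds or fails; on
failure the manifest names the failed stage. Numeric outputs are
byte-reproducible for a fixed seed.

The default problem sizes — ~3,000-4,000 localizations per channel, 8
channels, 20-100 replicate seeds in the validation suite — were chosen so the
full test suite and the acceptance script each run in a few minutes on a
single core while keeping Monte-Carlo error far below every asserted
tolerance; all sizes scale through the configuration.

## 7. Known limitations

* Rigid translation registration only; rotation, scaling, and non-rigid
  warps are out of scope.
* No correction of linkage-error inflation in reported medians.
* The heatmap's directedness convention (source rows -> target columns) is a
  package choice; published heatmaps do not always state theirs.
* Real deposited datasets may use other column names or units; the reader
  accepts a column mapping and pixel-size conversion (108 nm default
  effective pixel size) rather than guessing.
* The precision estimator requires a frame column with genuine adjacent-frame
  repeats; localization tables whose events were merged upstream will return
  insufficient-data errors rather than wrong numbers.
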