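# Shared fixtures and independent oracles, all built in code.

# exhaustive O(n^2) nearest-neighbor search: the independent oracle against
# which the kd-tree path is checked
brute_nn <- function(src, tgt, cutoff) {
  if (!nrow(src) || !nrow(tgt)) return(numeric(0))
  d <- vapply(seq_len(nrow(src)), function(i) {
    min(sqrt((tgt[, 1] - src[i, 1])^2 + (tgt[, 2] - src[i, 2])^2))
  }, numeric(1))
  d[d < cutoff]
}

make_table <- function(x, y, channel = "X", ...) {
  localization_table(x, y, channel = channel, ...)
}

# flat, single-segment, edge-on two-layer model: layer A at offset 0 and
# layer B at offset `d`, band width `width` nm
flat_two_layer_model <- function(d, width = 1, density = 20000,
                                 length = 20000, seed = 1,
                                 fov = c(30000, 30000)) {
  geom <- golgi_geometry(ribbon_length = length, ribbon_width = width,
                         curvature = 0, segments = 1,
                         field_of_view = fov)
  golgi_model(geom, list(
    target_layout("A", "layer", axial_offset = 0, site_density = density),
    target_layout("B", "layer", axial_offset = d, site_density = density)),
    seed = seed)
}

# acquisition with every stochastic nuisance switched off: one blink per
# site, no localization error, no linkage, no background, perfect erasure
noise_off_config <- function(round_order, ...) {
  acquisition_config(round_order, mean_blinks_per_site = 1,
                     blink_count_law = "fixed", sigma_loc = 0,
                     linkage_radius = 0, false_rate = 0,
                     erasure_efficiency = 1, ...)
}

# repeated localizations of isolated emitters: n_emitters sites, fixed blink
# count, localization error sigma, short movie so adjacent-frame repeats are
# plentiful (the regime the precision estimator consumes)
sim_emitters <- function(sigma, n_emitters = 500, blinks = 10, seed = 1) {
  set.seed(seed)
  side <- 20000
  sites <- cbind(stats::runif(n_emitters, 0, side),
                 stats::runif(n_emitters, 0, side))
  cfg <- acquisition_config("E", mean_blinks_per_site = blinks,
                            blink_count_law = "fixed", sigma_loc = sigma,
                            linkage_radius = 10, false_rate = 0,
                            n_frames = 200, mean_event_frames = 4)
  simulate_target_round(sites, cfg, 1, fov = c(side, side), seed = seed)
}

translate_tab <- function(tab, dx, dy) {
  tab$x_nm <- tab$x_nm + dx
  tab$y_nm <- tab$y_nm + dy
  tab
}

# uniform random localization table over a square field
uniform_table <- function(n, side, channel = "U") {
  localization_table(stats::runif(n, 0, side), stats::runif(n, 0, side),
                     channel = channel)
}
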