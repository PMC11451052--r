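#' Acquisition configuration for sequential-round imaging
#'
#' Stochastic imaging parameters for a simulated Exchange/FLASH-PAINT
#' experiment: one target imaged per round, each labeled site producing a
#' random number of blinks (localizations), each blink displaced by a fixed
#' per-site linkage offset (the antibody/nanobody/docking-strand stalk, drawn
#' once per site with uniform direction) plus per-blink Gaussian localization
#' error, the whole round rigidly misaligned by its stage shift, uniform false
#' localizations added, and — because erasure of the previous round's adapter
#' is not perfect — a small fraction of the previous round's sites blinking
#' again as carryover.
#'
#' @param round_order character vector of target ids, one per imaging round.
#' @param mean_blinks_per_site expected localizations per labeled site.
#' @param blink_count_law `"poisson"` or `"geometric"` (both with the given
#'   mean; DNA-PAINT blink counts are often closer to geometric), or `"fixed"`
#'   for a deterministic integer count — useful for noise-free checks.
#' @param sigma_loc per-coordinate Gaussian localization error in nm.
#' @param linkage_radius fixed magnitude of the per-site label offset in nm.
#' @param false_rate false localizations per square micrometre per round.
#'   False localizations arise from nonspecific binding sites: imagers stick
#'   to the same high-affinity spots in every round, so within one simulated
#'   experiment the underlying sites persist across rounds (their blinks are
#'   redrawn each round). This shared background is what makes round-to-round
#'   registration by image correlation well-posed even between channels whose
#'   specific structures do not overlap.
#' @param erasure_efficiency fraction of the previous round's sites silenced
#'   before the next round starts (in `[0, 1]`).
#' @param false_site_brightness mean blinks at a nonspecific site relative to
#'   a specific docking site (high-affinity sticky spots bind imagers
#'   repeatedly, so they are fewer but brighter at the same false_rate).
#' @param round_shifts per-round rigid stage shifts: a matrix (or list) of
#'   `(dx, dy)` in nm, one row per round; defaults to all-zero.
#' @param pixel_size camera pixel size in nm (used for unit conversion of real
#'   inputs; the simulator works directly in nm).
#' @param n_frames frames per round.
#' @param mean_event_frames mean duration (frames) of one binding event. A
#'   site's localizations are grouped into events; localizations within an
#'   event occupy consecutive frames, as per-frame fits of one dwelling imager
#'   do in real data. Adjacent-frame repeats are what the NeNA-style precision
#'   estimator consumes.
#' @return an object of class `acquisition_config`.
#' @examples
#' acquisition_config(c("GM130", "TGN46"), sigma_loc = 5)
#' @export
acquisition_config <- function(round_order,
                               mean_blinks_per_site = 5,
                               blink_count_law = c("poisson", "geometric", "fixed"),
                               sigma_loc = 5,
                               linkage_radius = 10,
                               false_rate = 25,
                               false_site_brightness = 3,
                               erasure_efficiency = 0.995,
                               round_shifts = NULL,
                               pixel_size = 108,
                               n_frames = 30000L,
                               mean_event_frames = 3) {
  blink_count_law <- match.arg(blink_count_law)
  if (!is.character(round_order) || !length(round_order)) {
    abort_config("round_order must name at least one target")
  }
  check_scalar(mean_blinks_per_site, "mean_blinks_per_site", min = 0)
  check_scalar(sigma_loc, "sigma_loc", min = 0)
  check_scalar(linkage_radius, "linkage_radius", min = 0)
  check_scalar(false_rate, "false_rate", min = 0)
  check_scalar(false_site_brightness, "false_site_brightness", min = 1)
  check_scalar(erasure_efficiency, "erasure_efficiency", min = 0, max = 1)
  check_scalar(pixel_size, "pixel_size", min = 1e-9)
  check_scalar(n_frames, "n_frames", min = 1)
  check_scalar(mean_event_frames, "mean_event_frames", min = 1)
  k <- length(round_order)
  if (is.null(round_shifts)) {
    round_shifts <- matrix(0, nrow = k, ncol = 2)
  }
  if (is.list(round_shifts)) round_shifts <- do.call(rbind, round_shifts)
  round_shifts <- matrix(as.numeric(round_shifts), ncol = 2)
  if (nrow(round_shifts) != k) {
    abort_config("round_shifts must provide one (dx, dy) pair per round")
  }
  if (any(!is.finite(round_shifts))) abort_config("round_shifts must be finite")
  dimnames(round_shifts) <- list(round_order, c("dx", "dy"))
  structure(
    list(round_order = round_order,
         mean_blinks_per_site = mean_blinks_per_site,
         blink_count_law = blink_count_law,
         sigma_loc = sigma_loc, linkage_radius = linkage_radius,
         false_rate = false_rate,
         false_site_brightness = false_site_brightness,
         erasure_efficiency = erasure_efficiency,
         round_shifts = round_shifts, pixel_size = pixel_size,
         n_frames = as.integer(n_frames),
         mean_event_frames = mean_event_frames),
    class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(paste0("Acquisition: %d rounds (%s)\n",
                     "  blinks/site %.1f (%s), sigma_loc %.1f nm, linkage %.1f nm\n",
                     "  false rate %.2f /um^2/round, erasure %.3f, pixel %.0f nm\n"),
              length(x$round_order), paste(x$round_order, collapse = ", "),
              x$mean_blinks_per_site, x$blink_count_law, x$sigma_loc,
              x$linkage_radius, x$false_rate, x$erasure_efficiency,
              x$pixel_size))
  invisible(x)
}

# persistent nonspecific binding sites; the site count is set so the expected
# number of false localizations per round is false_rate x FOV area
draw_false_sites <- function(cfg, fov) {
  if (cfg$false_rate <= 0 || cfg$mean_blinks_per_site <= 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  n <- stats::rpois(1, cfg$false_rate * prod(fov) / 1e6 /
                         (cfg$mean_blinks_per_site * cfg$false_site_brightness))
  cbind(stats::runif(n, 0, fov[1]), stats::runif(n, 0, fov[2]))
}

draw_blink_counts <- function(n, law, mean) {
  if (n == 0L) return(integer(0))
  switch(law,
    poisson = stats::rpois(n, mean),
    geometric = stats::rgeom(n, prob = 1 / (1 + mean)),
    fixed = rep.int(as.integer(round(mean)), n))
}

# blinks for a set of sites: per-site fixed linkage offset, per-blink Gaussian
# localization error, rigid round shift. Frames are assigned in binding-event
# runs: a site's localizations are partitioned into events of geometric length
# (mean mean_event_frames); within an event, frames are consecutive, the way
# per-frame fits of one dwelling imager strand appear in real acquisitions.
blinks_from_sites <- function(sites, cfg, shift, linkage = TRUE,
                              blink_mult = 1) {
  n_sites <- nrow(sites)
  counts <- draw_blink_counts(n_sites, cfg$blink_count_law,
                              cfg$mean_blinks_per_site * blink_mult)
  total <- sum(counts)
  if (total == 0L) {
    return(list(x = numeric(0), y = numeric(0), site = integer(0),
                frame = integer(0)))
  }
  r_link <- if (linkage) cfg$linkage_radius else 0
  ang <- stats::runif(n_sites, 0, 2 * pi)
  lx <- sites[, 1] + r_link * cos(ang)
  ly <- sites[, 2] + r_link * sin(ang)
  idx <- rep.int(seq_len(n_sites), counts)
  new_event <- stats::runif(total) < 1 / cfg$mean_event_frames
  new_event[1] <- TRUE
  if (total > 1L) new_event[which(diff(idx) != 0L) + 1L] <- TRUE
  ev <- cumsum(new_event)
  starts <- sample.int(cfg$n_frames, ev[total], replace = TRUE) - 1L
  pos <- sequence(rle(ev)$lengths) - 1L
  frame <- (starts[ev] + pos) %% cfg$n_frames
  list(
    x = lx[idx] + stats::rnorm(total, 0, cfg$sigma_loc) + shift[1],
    y = ly[idx] + stats::rnorm(total, 0, cfg$sigma_loc) + shift[2],
    site = idx,
    frame = as.integer(frame))
}

#' Simulate one imaging round for one target
#'
#' Generates the localization table observed in a single round: blinks from the
#' target's labeled sites, uniform false localizations over the field of view,
#' and blinks from the fraction of the previous round's sites that escaped
#' erasure. Every row carries an `origin_flag`.
#'
#' @param sites matrix of site coordinates (`x`, `y` in nm) for the target
#'   imaged this round.
#' @param cfg an [acquisition_config].
#' @param round_index 1-based index into `cfg$round_order`.
#' @param previous_round_sites site matrix of the round before, or `NULL`;
#'   a fraction `1 - erasure_efficiency` of them blink again this round.
#' @param fov field of view as `c(width, height)` nm (support of false
#'   localizations).
#' @param false_sites matrix of persistent nonspecific binding sites, as drawn
#'   once per experiment by [simulate_experiment()]; if `NULL`, a fresh
#'   uniform set is drawn for this round alone.
#' @param seed integer seed.
#' @return a [localization_table] for the round's target channel.
#' @export
simulate_target_round <- function(sites, cfg, round_index,
                                  previous_round_sites = NULL,
                                  fov = c(6000, 6000), false_sites = NULL,
                                  seed = 1L) {
  if (!inherits(cfg, "acquisition_config")) {
    abort_config("cfg must be an acquisition_config")
  }
  round_index <- as.integer(round_index)
  if (round_index < 1L || round_index > length(cfg$round_order)) {
    abort_config("round_index outside round_order")
  }
  if (is.null(sites)) sites <- matrix(numeric(0), ncol = 2)
  sites <- matrix(as.numeric(sites), ncol = 2,
                  dimnames = list(NULL, c("x", "y")))
  shift <- cfg$round_shifts[round_index, ]
  with_seed(seed, {
    true <- blinks_from_sites(sites, cfg, shift)

    if (is.null(false_sites)) {
      false_sites <- draw_false_sites(cfg, fov)
    }
    # a nonspecific sticky spot is itself the binding site: no label stalk,
    # so its blinks scatter around the fixed spot by localization error only
    fo <- blinks_from_sites(false_sites, cfg, shift, linkage = FALSE,
                            blink_mult = cfg$false_site_brightness)
    fx <- fo$x; fy <- fo$y

    cx <- numeric(0); cy <- numeric(0); cframe <- integer(0)
    if (!is.null(previous_round_sites) && nrow(previous_round_sites) &&
        cfg$erasure_efficiency < 1) {
      keep <- stats::runif(nrow(previous_round_sites)) <
        (1 - cfg$erasure_efficiency)
      if (any(keep)) {
        co <- blinks_from_sites(previous_round_sites[keep, , drop = FALSE],
                                cfg, shift)
        cx <- co$x; cy <- co$y; cframe <- co$frame
      }
    }

    x <- c(true$x, fx, cx)
    y <- c(true$y, fy, cy)
    flag <- c(rep("true_site", length(true$x)),
              rep("false_positive", length(fx)),
              rep("carryover", length(cx)))
    frame <- c(true$frame, fo$frame, cframe)
    localization_table(x, y, frame = frame,
                       precision = rep(cfg$sigma_loc, length(x)),
                       origin_flag = flag,
                       channel = cfg$round_order[round_index],
                       round_index = round_index)
  })
}

#' Simulate a full sequential multiplexed experiment
#'
#' Runs [sample_sites()] and [simulate_target_round()] for every round in
#' `cfg$round_order`, chaining carryover from each round into the next (first
#' order only: erasure failures do not persist beyond one round). The returned
#' ground truth records the true site coordinates, the applied per-round
#' shifts, and the true inter-support axial separations for every target pair,
#' so downstream registration and proximity estimates can be scored.
#'
#' @param model a [golgi_model].
#' @param cfg an [acquisition_config] whose `round_order` names targets of
#'   `model`.
#' @param seed integer seed; defaults to the model seed.
#' @return a list of class `paint_experiment` with elements `tables` (named
#'   list of [localization_table]s, one per round) and `ground_truth` (list
#'   with `sites`, `shifts`, `support_separation`).
#' @examples
#' m <- default_golgi_model(seed = 2)
#' cfg <- acquisition_config(names(m$layouts))
#' ex <- simulate_experiment(m, cfg, seed = 2)
#' names(ex$tables)
#' @export
simulate_experiment <- function(model, cfg, seed = NULL) {
  if (!inherits(model, "golgi_model")) abort_config("model must be a golgi_model")
  if (!inherits(cfg, "acquisition_config")) {
    abort_config("cfg must be an acquisition_config")
  }
  missing <- setdiff(cfg$round_order, names(model$layouts))
  if (length(missing)) {
    abort_config(sprintf("round_order names target(s) absent from model: %s",
                         paste(missing, collapse = ", ")))
  }
  if (is.null(seed)) seed <- model$seed
  fov <- model$geometry$field_of_view
  false_sites <- with_seed(derive_seed(seed, "false_sites"),
                           draw_false_sites(cfg, fov))
  tables <- vector("list", length(cfg$round_order))
  names(tables) <- cfg$round_order
  sites <- vector("list", length(cfg$round_order))
  names(sites) <- cfg$round_order
  prev <- NULL
  for (i in seq_along(cfg$round_order)) {
    id <- cfg$round_order[i]
    s <- sample_sites(model, id, seed = derive_seed(seed, "sites", id))
    sites[[id]] <- s
    tables[[id]] <- simulate_target_round(
      s, cfg, i, previous_round_sites = prev, fov = fov,
      false_sites = false_sites,
      seed = derive_seed(seed, "round", i))
    prev <- s
  }
  offs <- vapply(model$layouts[cfg$round_order], `[[`, numeric(1), "axial_offset")
  sep <- abs(outer(offs, offs, `-`))
  structure(
    list(tables = tables,
         ground_truth = list(sites = sites, shifts = cfg$round_shifts,
                             support_separation = sep),
         model = model, config = cfg, seed = as.integer(seed)),
    class = "paint_experiment")
}

#' @export
print.paint_experiment <- function(x, ...) {
  n <- vapply(x$tables, nrow, integer(1))
  cat(sprintf("Simulated FLASH-PAINT experiment: %d rounds, %d localizations (seed %d)\n",
              length(n), sum(n), x$seed))
  for (id in names(n)) cat(sprintf("  %-10s %6d\n", id, n[[id]]))
  invisible(x)
}

#' Simulate localization data from a Golgi model
#'
#' `simulate()` method wrapping [simulate_experiment()]; draws `nsim`
#' independent experiments.
#'
#' @param object a [golgi_model].
#' @param nsim number of experiments.
#' @param seed integer seed (defaults to the model seed).
#' @param cfg an [acquisition_config]; defaults to one round per model target
#'   with default acquisition parameters.
#' @param ... unused.
#' @return a `paint_experiment` if `nsim = 1`, else a list of them.
#' @export
simulate.golgi_model <- function(object, nsim = 1, seed = NULL, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- acquisition_config(names(object$layouts))
  if (is.null(seed)) seed <- object$seed
  out <- lapply(seq_len(nsim), function(i) {
    simulate_experiment(object, cfg, seed = derive_seed(seed, "sim", i))
  })
  if (nsim == 1) out[[1]] else out
}
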