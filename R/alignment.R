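#' Render a localization table as a 2D density histogram
#'
#' Bins localizations on half-open bins `[k*bin_size, (k+1)*bin_size)` relative
#' to the extent origin. Rows of the returned count matrix index x bins,
#' columns index y bins. Localizations outside the extent are dropped and
#' counted in the `n_dropped` field.
#'
#' @param table a [localization_table].
#' @param bin_size bin edge length in nm.
#' @param extent numeric `c(x0, y0, x1, y1)` in nm; defaults to the table's
#'   bounding box snapped outward to the bin grid.
#' @return an object of class `density_grid`: list with `counts`, `bin_size`,
#'   `origin`, `n_dropped`.
#' @export
render_density <- function(table, bin_size = 10, extent = NULL) {
  check_scalar(bin_size, "bin_size", min = 1e-12)
  if (is.null(extent)) {
    if (!nrow(table)) {
      extent <- c(0, 0, bin_size, bin_size)
    } else {
      extent <- c(floor(min(table$x_nm) / bin_size) * bin_size,
                  floor(min(table$y_nm) / bin_size) * bin_size,
                  ceiling(max(table$x_nm) / bin_size + 1) * bin_size,
                  ceiling(max(table$y_nm) / bin_size + 1) * bin_size)
    }
  }
  if (length(extent) != 4L || extent[3] <= extent[1] || extent[4] <= extent[2]) {
    abort_config("extent must be c(x0, y0, x1, y1) with positive size")
  }
  nx <- ceiling((extent[3] - extent[1]) / bin_size - 1e-9)
  ny <- ceiling((extent[4] - extent[2]) / bin_size - 1e-9)
  ix <- floor((table$x_nm - extent[1]) / bin_size)
  iy <- floor((table$y_nm - extent[2]) / bin_size)
  inside <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  counts <- matrix(0L, nrow = nx, ncol = ny)
  if (any(inside)) {
    tab <- table(factor(ix[inside] + nx * iy[inside],
                        levels = 0:(nx * ny - 1)))
    counts <- matrix(as.integer(tab), nrow = nx, ncol = ny)
  }
  structure(list(counts = counts, bin_size = bin_size,
                 origin = extent[1:2], n_dropped = sum(!inside)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %d x %d bins of %.1f nm, %d localizations (%d dropped)\n",
              nrow(x$counts), ncol(x$counts), x$bin_size, sum(x$counts),
              x$n_dropped))
  invisible(x)
}

# circular cross-correlation of zero-padded count matrices via FFT;
# cc[si, sj] = sum_x ref(x) * mov(x + s)
cross_correlate <- function(ref, mov, pad) {
  nr <- nrow(ref) + pad; nc <- ncol(ref) + pad
  a <- matrix(0, nr, nc); a[seq_len(nrow(ref)), seq_len(ncol(ref))] <- ref
  b <- matrix(0, nr, nc); b[seq_len(nrow(mov)), seq_len(ncol(mov))] <- mov
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    (nr * nc)
}

# quadratic (parabolic) sub-bin peak refinement along one axis
parabolic_offset <- function(cm, c0, cp) {
  denom <- cm - 2 * c0 + cp
  if (!is.finite(denom) || denom >= 0) return(0)
  delta <- 0.5 * (cm - cp) / denom
  max(-0.5, min(0.5, delta))
}

#' Estimate the rigid shift between two rendered channels
#'
#' Finds the translation maximizing the cross-correlation between two density
#' grids, then refines it to sub-bin precision with a local quadratic fit
#' around the integer peak. Sign convention: applying `(dx, dy)` to the moving
#' channel superimposes it on the reference, so a channel whose content sits
#' at `+t` relative to the reference yields an estimate of `-t`.
#'
#' @param reference,moving [render_density()] grids sharing bin size and shape.
#' @param max_shift largest shift magnitude searched, in nm, per axis.
#' @return an object of class `shift_estimate`: list with `dx`, `dy` (nm),
#'   `peak_correlation` (normalized cross-correlation at the integer peak, in
#'   `[-1, 1]`), and `subpixel = TRUE`.
#' @export
estimate_shift <- function(reference, moving, max_shift = 500) {
  if (!inherits(reference, "density_grid") || !inherits(moving, "density_grid")) {
    abort_config("reference and moving must be density_grid objects")
  }
  if (reference$bin_size != moving$bin_size ||
      !identical(dim(reference$counts), dim(moving$counts))) {
    abort_config("grids must share bin_size and shape")
  }
  check_scalar(max_shift, "max_shift", min = 0)
  ref <- reference$counts; mov <- moving$counts
  if (max(ref) == min(ref) || max(mov) == min(mov)) {
    abort_data("cannot register a flat (featureless) density grid")
  }
  bin <- reference$bin_size
  max_bins <- min(ceiling(max_shift / bin), nrow(ref) - 1L, ncol(ref) - 1L)
  pad <- max_bins + 1L
  cc <- cross_correlate(ref, mov, pad)
  nr <- nrow(cc); nc <- ncol(cc)
  # shift s lives at index (s mod nr) + 1; admissible s in [-max_bins, max_bins]
  sx <- c(0:max_bins, -(max_bins:1))
  ix <- (sx %% nr) + 1L
  iy <- (sx %% nc) + 1L
  sub <- cc[ix, iy]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  sxi <- sx[pk[1]]; syi <- sx[pk[2]]
  at <- function(si, sj) cc[(si %% nr) + 1L, (sj %% nc) + 1L]
  fx <- parabolic_offset(at(sxi - 1, syi), at(sxi, syi), at(sxi + 1, syi))
  fy <- parabolic_offset(at(sxi, syi - 1), at(sxi, syi), at(sxi, syi + 1))
  peak_norm <- at(sxi, syi) / sqrt(sum(ref^2) * sum(mov^2))
  # the peak s satisfies mov(x + s) ~ ref(x), i.e. moving content sits at -s;
  # applying +s to the moving channel superimposes it on the reference... the
  # content offset t of moving relative to reference is +s_peak measured in the
  # mov(x) = ref(x - t) sense, so the correcting translation is -t.
  structure(list(dx = -(sxi + fx) * bin, dy = -(syi + fy) * bin,
                 peak_correlation = peak_norm, subpixel = TRUE,
                 max_shift = max_shift),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("Shift estimate: dx = %.2f nm, dy = %.2f nm (peak correlation %.3f)\n",
              x$dx, x$dy, x$peak_correlation))
  invisible(x)
}

#' Align sequential imaging rounds to a common reference
#'
#' Re-implements the round-alignment postprocessing step of multiplexed
#' DNA-PAINT: every channel is rendered on a common grid, its rigid shift
#' relative to the reference channel's render is estimated by image
#' cross-correlation, and the estimated correction is applied to its
#' coordinates. Input tables are not modified.
#'
#' @param dataset named list of [localization_table]s (one per round/target),
#'   or a `paint_experiment`.
#' @param reference channel id used as the fixed frame; defaults to the first.
#' @param bin_size render bin size in nm.
#' @param max_shift largest correction searched, in nm.
#' @return list with `aligned` (translated tables) and `registration`, a
#'   `registration_result` recording per-round estimates; the reference
#'   round's estimate is exactly `(0, 0)`.
#' @examples
#' ex <- simulate_experiment(default_golgi_model(3),
#'                           acquisition_config(c("GM130", "TGN46")))
#' al <- align_rounds(ex$tables)
#' al$registration
#' @export
align_rounds <- function(dataset, reference = NULL, bin_size = 10,
                         max_shift = 500) {
  if (inherits(dataset, "paint_experiment")) dataset <- dataset$tables
  if (!is.list(dataset) || is.null(names(dataset)) || !length(dataset)) {
    abort_config("dataset must be a named list of localization tables")
  }
  if (is.null(reference)) reference <- names(dataset)[1]
  if (!reference %in% names(dataset)) {
    abort_lookup(sprintf("reference channel '%s' not in dataset", reference))
  }
  # common extent over all channels, padded so shifted content stays inside
  xr <- range(unlist(lapply(dataset, `[[`, "x_nm")))
  yr <- range(unlist(lapply(dataset, `[[`, "y_nm")))
  extent <- c(floor((xr[1] - max_shift) / bin_size) * bin_size,
              floor((yr[1] - max_shift) / bin_size) * bin_size,
              ceiling((xr[2] + max_shift) / bin_size + 1) * bin_size,
              ceiling((yr[2] + max_shift) / bin_size + 1) * bin_size)
  ref_grid <- render_density(dataset[[reference]], bin_size, extent)
  est <- vector("list", length(dataset))
  names(est) <- names(dataset)
  aligned <- dataset
  for (id in names(dataset)) {
    if (id == reference) {
      est[[id]] <- structure(list(dx = 0, dy = 0, peak_correlation = 1,
                                  subpixel = FALSE, max_shift = max_shift),
                             class = "shift_estimate")
      next
    }
    g <- render_density(dataset[[id]], bin_size, extent)
    est[[id]] <- estimate_shift(ref_grid, g, max_shift)
    aligned[[id]] <- translate_table(dataset[[id]], est[[id]]$dx, est[[id]]$dy)
  }
  reg <- structure(
    list(reference = reference, estimates = est, bin_size = bin_size,
         max_shift = max_shift),
    class = "registration_result")
  list(aligned = aligned, registration = reg)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("Round registration (reference: %s, bin %.0f nm)\n",
              x$reference, x$bin_size))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.registration_result <- function(x, ...) {
  data.frame(
    round = names(x$estimates),
    dx_nm = vapply(x$estimates, `[[`, numeric(1), "dx"),
    dy_nm = vapply(x$estimates, `[[`, numeric(1), "dy"),
    peak_correlation = vapply(x$estimates, `[[`, numeric(1), "peak_correlation"),
    row.names = NULL)
}

#' @export
summary.registration_result <- function(object, ...) {
  df <- as.data.frame(object)
  mags <- sqrt(df$dx_nm^2 + df$dy_nm^2)
  cat(sprintf("Registration of %d rounds to '%s': shift magnitudes %.1f-%.1f nm (median %.1f)\n",
              nrow(df), object$reference, min(mags), max(mags),
              stats::median(mags)))
  invisible(df)
}
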