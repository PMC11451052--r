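#' Estimate localization precision from within-channel repeats
#'
#' NeNA-style estimator: the same labeled site is localized many times, and in
#' consecutive camera frames the same bound imager yields two independent
#' estimates of one position. The displacement between a localization and its
#' nearest neighbor in the next frame is therefore, for true repeats, the
#' difference of two isotropic Gaussian errors — a Rayleigh distribution
#' `p(d) = d/(2*sigma^2) * exp(-d^2/(4*sigma^2))` — while chance pairs from
#' unrelated sites contribute an approximately linear background `2d/R^2` on
#' the fit window `[0, R]`. The mixture of the two is fitted by maximum
#' likelihood and the Rayleigh component's `sigma` is reported as the
#' per-coordinate localization precision.
#'
#' @param table a [localization_table] with at least 100 rows and a usable
#'   `frame` column.
#' @param fit_range upper end `R` of the fitted distance window, nm.
#' @return an object of class `precision_estimate`: list with `channel`,
#'   `sigma` (nm), `method`, `n_used` (number of adjacent-frame pair distances
#'   fitted), `background_weight`.
#' @examples
#' ex <- simulate_experiment(default_golgi_model(5),
#'                           acquisition_config(c("GM130", "TGN46")))
#' estimate_precision(ex$tables$GM130)
#' @export
estimate_precision <- function(table, fit_range = 100) {
  check_scalar(fit_range, "fit_range", min = 1e-9)
  if (nrow(table) < 100L) {
    abort_data(sprintf(
      "insufficient data: %d localizations (at least 100 required)",
      nrow(table)))
  }
  d <- adjacent_frame_nn(table, fit_range)
  if (length(d) < 30L) {
    abort_data(sprintf(
      "insufficient data: only %d adjacent-frame pairs within %g nm",
      length(d), fit_range))
  }
  # degenerate limit: repeats coincide exactly (zero localization error)
  if (stats::median(d) < 1e-6) {
    return(new_precision_estimate(attr(table, "channel"), 0, length(d), NA_real_))
  }
  fit <- fit_nena_mixture(d, fit_range)
  new_precision_estimate(attr(table, "channel"), fit$sigma, length(d),
                         fit$background_weight)
}

new_precision_estimate <- function(channel, sigma, n_used, bg) {
  structure(list(channel = channel, sigma = sigma,
                 method = "nena_adjacent_frame_nn", n_used = n_used,
                 background_weight = bg),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("Localization precision (%s): sigma = %.2f nm from %d pairs [%s]\n",
              x$channel %||% "?", x$sigma, x$n_used, x$method))
  invisible(x)
}

# distance from each localization in frame f to its nearest neighbor in
# frame f + 1, truncated at fit_range
adjacent_frame_nn <- function(table, fit_range) {
  xy <- cbind(table$x_nm, table$y_nm)
  by_frame <- split(seq_len(nrow(xy)), table$frame)
  frames <- as.integer(names(by_frame))
  nxt <- match(frames + 1L, frames)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    j <- nxt[i]
    if (is.na(j)) next
    q <- xy[by_frame[[i]], , drop = FALSE]
    t <- xy[by_frame[[j]], , drop = FALSE]
    nn <- RANN::nn2(t, q, k = 1L, searchtype = "radius", radius = fit_range)
    dd <- nn$nn.dists[, 1]
    dd <- dd[nn$nn.idx[, 1] != 0L & dd < fit_range]
    out[[i]] <- dd
  }
  unlist(out) %||% numeric(0)
}

# maximum-likelihood fit of w * Rayleigh(sigma*sqrt(2)) + (1 - w) * 2d/R^2,
# both truncated to [0, R]
fit_nena_mixture <- function(d, R) {
  d <- d[d > 0 & d < R]
  nll <- function(par) {
    sigma <- exp(par[1])
    w <- stats::plogis(par[2])
    norm1 <- 1 - exp(-R^2 / (4 * sigma^2))
    f1 <- d / (2 * sigma^2) * exp(-d^2 / (4 * sigma^2)) / norm1
    f2 <- 2 * d / R^2
    ll <- log(w * f1 + (1 - w) * f2)
    if (any(!is.finite(ll))) return(1e12)
    -sum(ll)
  }
  init <- c(log(stats::median(d) / (2 * sqrt(log(2)))), stats::qlogis(0.8))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(sigma = exp(opt$par[1]),
       background_weight = 1 - stats::plogis(opt$par[2]))
}

#' Precision table for a multichannel dataset
#'
#' Runs [estimate_precision()] on every channel, returning the per-channel
#' precision table that accompanies a proximity heatmap. Channels with too few
#' localizations or too few adjacent-frame repeats are reported with `NA`.
#'
#' @param dataset named list of [localization_table]s or a `paint_experiment`.
#' @param fit_range fit window in nm, passed through.
#' @return data frame with columns `channel`, `sigma_nm`, `method`, `n_used`.
#' @export
precision_table <- function(dataset, fit_range = 100) {
  if (inherits(dataset, "paint_experiment")) dataset <- dataset$tables
  rows <- lapply(names(dataset), function(id) {
    est <- tryCatch(estimate_precision(dataset[[id]], fit_range),
                    proximap_data_error = function(e) NULL)
    data.frame(channel = id,
               sigma_nm = if (is.null(est)) NA_real_ else est$sigma,
               method = if (is.null(est)) NA_character_ else est$method,
               n_used = if (is.null(est)) 0L else est$n_used)
  })
  do.call(rbind, rows)
}
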