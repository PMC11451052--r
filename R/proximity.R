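#' Directed nearest-neighbor distances between two channels
#'
#' For every localization in the source channel, the Euclidean distance to its
#' nearest neighbor in the target channel; distances at or beyond the cutoff
#' are discarded. This is the elementary quantity behind the proximity heatmap:
#' only signals closer than the cutoff (default 500 nm) are considered.
#' Distances are directed — source to target generally differs from target to
#' source when the two channels have different densities or geometries.
#'
#' @param source,target [localization_table]s in the same (aligned) frame.
#' @param cutoff distance cutoff in nm; retained distances are strictly below
#'   it.
#' @return an object of class `distance_sample`: list with `source_channel`,
#'   `target_channel`, `distances` (nm, in source row order), `n_source`,
#'   `n_kept`.
#' @examples
#' a <- localization_table(0, 0, channel = "A")
#' b <- localization_table(30, 40, channel = "B")
#' nn_distances(a, b)$distances  # 50: the 3-4-5 triangle
#' @export
nn_distances <- function(source, target, cutoff = 500) {
  check_scalar(cutoff, "cutoff", min = 1e-12)
  src <- cbind(source$x_nm, source$y_nm)
  tgt <- cbind(target$x_nm, target$y_nm)
  n_source <- nrow(src)
  d <- if (n_source == 0L || nrow(tgt) == 0L) {
    numeric(0)
  } else {
    nn <- RANN::nn2(tgt, src, k = 1L, searchtype = "radius", radius = cutoff)
    dd <- nn$nn.dists[, 1]
    dd[nn$nn.idx[, 1] == 0L] <- Inf   # no neighbor within the search radius
    dd[dd < cutoff]
  }
  structure(list(source_channel = attr(source, "channel"),
                 target_channel = attr(target, "channel"),
                 distances = d, n_source = n_source, n_kept = length(d),
                 cutoff = cutoff),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("NN distances %s -> %s: %d of %d kept (< %.0f nm), median %.1f nm\n",
              x$source_channel, x$target_channel, x$n_kept, x$n_source,
              x$cutoff, if (x$n_kept) stats::median(x$distances) else NA))
  invisible(x)
}

#' Median nearest-neighbor distance matrix across channels
#'
#' The pipeline's core statistic: for every ordered channel pair, the distance
#' from each source localization to its nearest neighbor in the target channel
#' is computed, distances beyond the cutoff are discarded, and the median of
#' the retained distances fills the matrix entry — the quantity displayed as a
#' proximity heatmap in multiplexed super-resolution studies. Entries backed by
#' fewer than `min_pair_count` retained distances are reported as `NA`.
#'
#' @param dataset named list of aligned [localization_table]s (at least two),
#'   or a `paint_experiment` (its tables are used unaligned; align first with
#'   [align_rounds()] if round shifts are present).
#' @param cutoff distance cutoff in nm (strictly-closer-than).
#' @param symmetrize if `TRUE`, each unordered pair's entry is the median of
#'   the pooled source-to-target and target-to-source distances (the matrix
#'   becomes symmetric); if `FALSE` (default) the matrix is directed.
#' @param min_pair_count smallest retained sample size considered reliable.
#' @param sources optional subset of channel names to use as source channels;
#'   rows of the matrix outside the subset stay `NA`. Useful when only one
#'   channel's proximity profile is of interest.
#' @return an object of class `proximity_map`: fields `channels`,
#'   `median_matrix` (directed K x K, nm), `n_matrix` (retained counts),
#'   `samples` (all [nn_distances()] results, keyed `"A->B"`), `config`.
#' @seealso [rank_partners()], [as.data.frame.proximity_map()],
#'   [plot.proximity_map()]
#' @examples
#' ex <- simulate_experiment(default_golgi_model(4),
#'                           acquisition_config(c("GM130", "GRASP65", "TGN46")))
#' pm <- proximity_map(ex$tables)
#' pm
#' @export
proximity_map <- function(dataset, cutoff = 500, symmetrize = FALSE,
                          min_pair_count = 50, sources = NULL) {
  if (inherits(dataset, "paint_experiment")) dataset <- dataset$tables
  if (!is.list(dataset) || is.null(names(dataset))) {
    abort_config("dataset must be a named list of localization tables")
  }
  if (length(dataset) < 2L) {
    abort_config("a proximity map needs at least two channels")
  }
  check_scalar(cutoff, "cutoff", min = 1e-12)
  check_scalar(min_pair_count, "min_pair_count", min = 1)
  channels <- names(dataset)
  if (is.null(sources)) sources <- channels
  if (length(setdiff(sources, channels))) {
    abort_lookup("sources must name channels present in the dataset")
  }
  if (symmetrize && !setequal(sources, channels)) {
    abort_config("symmetrize requires all channels as sources")
  }
  k <- length(channels)
  med <- matrix(NA_real_, k, k, dimnames = list(channels, channels))
  nk <- matrix(0L, k, k, dimnames = list(channels, channels))
  samples <- list()
  for (i in which(channels %in% sources)) {
    for (j in seq_len(k)) {
      ds <- nn_distances(dataset[[i]], dataset[[j]], cutoff)
      ds$source_channel <- channels[i]
      ds$target_channel <- channels[j]
      samples[[paste0(channels[i], "->", channels[j])]] <- ds
      nk[i, j] <- ds$n_kept
      if (ds$n_kept >= min_pair_count) {
        med[i, j] <- stats::median(ds$distances)
      }
    }
  }
  if (symmetrize) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (j <= i) next
        pooled <- c(samples[[paste0(channels[i], "->", channels[j])]]$distances,
                    samples[[paste0(channels[j], "->", channels[i])]]$distances)
        val <- if (length(pooled) >= min_pair_count) stats::median(pooled) else NA_real_
        med[i, j] <- med[j, i] <- val
      }
    }
  }
  structure(list(channels = channels, median_matrix = med, n_matrix = nk,
                 samples = samples,
                 config = list(cutoff = cutoff, symmetrize = symmetrize,
                               min_pair_count = min_pair_count)),
            class = "proximity_map")
}

#' @export
print.proximity_map <- function(x, digits = 1, ...) {
  cat(sprintf("Proximity map: %d channels, cutoff %.0f nm%s\n",
              length(x$channels), x$config$cutoff,
              if (x$config$symmetrize) " (symmetrized)" else " (directed)"))
  cat("Median NN distances (nm), source rows -> target columns:\n")
  print(round(x$median_matrix, digits))
  invisible(x)
}

#' @export
summary.proximity_map <- function(object, ...) {
  print(object)
  off <- object$median_matrix[row(object$median_matrix) !=
                              col(object$median_matrix)]
  cat(sprintf("\nOff-diagonal medians: %d computed, %d below min_pair_count\n",
              sum(!is.na(off)), sum(is.na(off))))
  if (any(!is.na(off))) {
    cat(sprintf("Range %.1f-%.1f nm\n", min(off, na.rm = TRUE),
                max(off, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
as.matrix.proximity_map <- function(x, ...) x$median_matrix

#' Long-format export of all retained pair distances
#'
#' One row per retained nearest-neighbor distance — the table behind
#' violin-plot summaries of per-pair distance distributions. Recomputing the
#' per-pair medians from this export reproduces the median matrix exactly.
#'
#' @param x a [proximity_map].
#' @param row.names,optional,... ignored (method signature only).
#' @return data frame with columns `source_channel`, `target_channel`,
#'   `distance_nm`.
#' @export
as.data.frame.proximity_map <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  parts <- lapply(x$samples, function(s) {
    if (!s$n_kept) return(NULL)
    data.frame(source_channel = s$source_channel,
               target_channel = s$target_channel,
               distance_nm = s$distances)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    return(data.frame(source_channel = character(0),
                      target_channel = character(0),
                      distance_nm = numeric(0)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Heatmap of the median-distance matrix
#'
#' Base-graphics heatmap of the median NN distance matrix, source channels as
#' rows, annotated with the distances in nm. Shorter distances (closer
#' proximity) are drawn darker.
#'
#' @param x a [proximity_map].
#' @param main plot title.
#' @param annotate write the numeric value in each cell.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.proximity_map <- function(x, main = "Median NN distance (nm)",
                               annotate = TRUE, ...) {
  m <- x$median_matrix
  k <- length(x$channels)
  pal <- grDevices::hcl.colors(64, "YlOrRd")   # dark = close
  old <- graphics::par(mar = c(1.5, 6, 6, 1.5))
  on.exit(graphics::par(old))
  # image() draws rows of the matrix along x; transpose so sources are rows,
  # and flip so the first channel is the top row
  z <- t(m[k:1, , drop = FALSE])
  graphics::image(seq_len(k), seq_len(k), z, col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main,
                  zlim = c(0, max(m, na.rm = TRUE)), ...)
  graphics::axis(3, at = seq_len(k), labels = x$channels, las = 2, tick = FALSE,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(x$channels), las = 1,
                 tick = FALSE, cex.axis = 0.8)
  graphics::mtext("target", side = 3, line = 4.5)
  graphics::mtext("source", side = 2, line = 4.5)
  if (annotate) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        v <- m[i, j]
        graphics::text(j, k - i + 1,
                       if (is.na(v)) "-" else sprintf("%.0f", v), cex = 0.7)
      }
    }
  }
  invisible(x)
}

#' Rank a channel's proximity partners
#'
#' Orders every other channel by its directed median NN distance from the
#' query channel, closest first — the computation behind statements like
#' "closest to the cis-Golgi markers". Missing entries (below
#' `min_pair_count`) are omitted; ties are broken alphabetically.
#'
#' @param result a [proximity_map].
#' @param query channel to rank partners for.
#' @return data frame with columns `target_id` and `median_nm`, ascending.
#' @export
rank_partners <- function(result, query) {
  if (!inherits(result, "proximity_map")) {
    abort_config("result must be a proximity_map")
  }
  if (!query %in% result$channels) {
    abort_lookup(sprintf("unknown query channel '%s'", query))
  }
  med <- result$median_matrix[query, ]
  med <- med[names(med) != query]
  med <- med[!is.na(med)]
  ord <- order(med, names(med))
  data.frame(target_id = names(med)[ord], median_nm = unname(med[ord]))
}
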