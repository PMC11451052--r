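#' Localization tables
#'
#' A localization table holds one channel's super-resolved detections: one row
#' per blink, with coordinates in nanometres, the camera frame the blink was
#' fitted in, and (optionally) a per-localization precision estimate. Synthetic
#' tables additionally carry an `origin_flag` column recording whether each row
#' came from a labeled site, a false localization, or carryover from an
#' incompletely erased previous imaging round; real-data tables never have it.
#'
#' @param x,y numeric coordinates in nm.
#' @param frame non-negative integer frame index (recycled; default 0).
#' @param precision optional per-localization precision in nm (NA allowed).
#' @param origin_flag optional character vector, each element one of
#'   `"true_site"`, `"false_positive"`, `"carryover"`. Only present on
#'   synthetic data.
#' @param channel target identifier this table belongs to (e.g. `"GM130"`).
#' @param round_index integer imaging-round index, or NA when unknown.
#'
#' @return A data frame of class `localization_table` with columns `x_nm`,
#'   `y_nm`, `frame`, and optionally `precision_nm` and `origin_flag`;
#'   attributes `channel` and `round_index` identify its provenance.
#' @examples
#' tab <- localization_table(c(0, 30), c(0, 40), channel = "GM130")
#' nrow(tab)
#' @export
localization_table <- function(x, y, frame = 0L, precision = NULL,
                               origin_flag = NULL, channel = NA_character_,
                               round_index = NA_integer_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort_data("x and y must have equal length")
  }
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y)))) {
    abort_data("localization coordinates must be finite")
  }
  n <- length(x)
  frame <- rep_len(as.integer(frame), n)
  if (n && any(frame < 0L, na.rm = TRUE)) {
    abort_data("frame indices must be non-negative")
  }
  df <- data.frame(x_nm = x, y_nm = y, frame = frame)
  if (!is.null(precision)) df$precision_nm <- rep_len(as.numeric(precision), n)
  if (!is.null(origin_flag)) {
    origin_flag <- rep_len(as.character(origin_flag), n)
    bad <- setdiff(unique(origin_flag), c("true_site", "false_positive", "carryover"))
    if (length(bad)) {
      abort_data(sprintf("unknown origin_flag value(s): %s",
                         paste(bad, collapse = ", ")))
    }
    df$origin_flag <- origin_flag
  }
  structure(df,
            channel = as.character(channel),
            round_index = as.integer(round_index),
            class = c("localization_table", "data.frame"))
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("Localization table: channel %s, %d localizations",
              attr(x, "channel"), nrow(x)))
  ri <- attr(x, "round_index")
  if (!is.na(ri)) cat(sprintf(" (round %d)", ri))
  cat("\n")
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  }
  invisible(x)
}

# Translate a table rigidly; used by alignment and the invariance tests.
translate_table <- function(table, dx, dy) {
  table$x_nm <- table$x_nm + dx
  table$y_nm <- table$y_nm + dy
  table
}

#' Read a localization table from disk
#'
#' Reads one channel's localization table from delimited text (CSV) or from an
#' HDF5 file holding one table per channel under `/channels/<target_id>`.
#' Coordinates are returned in nm; tables recorded in camera pixels are
#' converted with `pixel_size` (the study's effective pixel size, 108 nm, is
#' the default).
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"hdf5"`.
#' @param unit `"nm"` (default) or `"pixel"`; pixel coordinates are multiplied
#'   by `pixel_size`.
#' @param pixel_size camera pixel size in nm, used only when `unit = "pixel"`.
#' @param channel channel name; required for the HDF5 dialect (selects the
#'   table under `/channels/`), used as metadata for CSV.
#' @param col_map optional named character vector mapping the canonical column
#'   names (`x_nm`, `y_nm`, `frame`, `precision_nm`, `origin_flag`) to the
#'   names used in the file, e.g. `c(x_nm = "x [nm]")`.
#'
#' @return a [localization_table].
#' @seealso [write_localizations()]
#' @export
read_localizations <- function(path, dialect = c("csv", "hdf5"),
                               unit = c("nm", "pixel"), pixel_size = 108,
                               channel = NA_character_, col_map = NULL) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  check_scalar(pixel_size, "pixel_size", min = 1e-9)
  if (!file.exists(path)) {
    stop(sprintf("cannot read localizations: no such file '%s'", path))
  }
  raw <- switch(dialect,
    csv = utils::read.csv(path, check.names = FALSE),
    hdf5 = {
      require_rhdf5()
      if (is.na(channel)) abort_config("hdf5 dialect requires a channel name")
      rhdf5::h5read(path, paste0("channels/", channel))
    }
  )
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  for (col in c("x_nm", "y_nm")) {
    if (!col %in% names(raw)) {
      abort_data(sprintf("localization file '%s' lacks required column '%s'",
                         path, col))
    }
  }
  scale <- if (unit == "pixel") pixel_size else 1
  localization_table(
    x = raw$x_nm * scale,
    y = raw$y_nm * scale,
    frame = if ("frame" %in% names(raw)) raw$frame else 0L,
    precision = if ("precision_nm" %in% names(raw)) raw$precision_nm * scale,
    origin_flag = if ("origin_flag" %in% names(raw)) raw$origin_flag,
    channel = channel
  )
}

#' Write a localization table to disk
#'
#' Lossless counterpart of [read_localizations()]: both dialects round-trip
#' coordinates, frames, and the optional precision and origin-flag columns.
#'
#' @param table a [localization_table].
#' @param path output file. For the HDF5 dialect an existing file gains a new
#'   channel; the table is stored under `/channels/<channel>`.
#' @param dialect `"csv"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(table)
  if (dialect == "csv") {
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  } else {
    require_rhdf5()
    channel <- attr(table, "channel")
    if (is.na(channel)) abort_config("hdf5 dialect requires the table's channel attribute")
    if (!file.exists(path)) rhdf5::h5createFile(path)
    if (!"channels" %in% rhdf5::h5ls(path, recursive = FALSE)$name) {
      rhdf5::h5createGroup(path, "channels")
    }
    target <- paste0("channels/", channel)
    existing <- rhdf5::h5ls(path)
    if (nrow(existing) && target %in% sub("^/", "", file.path(existing$group, existing$name))) {
      rhdf5::h5delete(path, target)
    }
    rhdf5::h5write(df, path, target)
    rhdf5::h5closeAll()
  }
  invisible(path)
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the hdf5 dialect requires the 'rhdf5' package")
  }
}
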