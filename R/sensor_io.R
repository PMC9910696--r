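# Epoch grids, acceleration / posture containers, and CSV I/O.

#' Define the epoch grid shared across measurement days
#'
#' All cross-day alignment is by epoch index within the 24-h clock. Epochs
#' are half-open intervals `[start, start + epoch_length)` anchored at local
#' midnight.
#'
#' @param epoch_length epoch duration in seconds; must divide 86400.
#'   Default 60 s, i.e. a posture sampling rate of 1/min.
#' @return an object of class `epoch_grid` with fields `epoch_length`
#'   (seconds), `epochs_per_day`, and `day_start` (`"00:00"`).
#' @export
#' @examples
#' epoch_grid()               # 1440 one-minute epochs
#' epoch_grid(600)            # 144 ten-minute epochs
epoch_grid <- function(epoch_length = 60) {
  stopifnot(is.numeric(epoch_length), length(epoch_length) == 1,
            epoch_length > 0)
  epoch_length <- as.integer(epoch_length)
  if (86400L %% epoch_length != 0L)
    stop("epoch_length must divide 86400 seconds", call. = FALSE)
  structure(list(epoch_length = epoch_length,
                 epochs_per_day = 86400L %/% epoch_length,
                 day_start = "00:00"),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d epochs/day of %d s, anchored at %s\n",
              x$epochs_per_day, x$epoch_length, x$day_start))
  invisible(x)
}

grids_identical <- function(a, b) {
  inherits(a, "epoch_grid") && inherits(b, "epoch_grid") &&
    a$epoch_length == b$epoch_length
}

# "HH:MM:SS" time-of-day label for each epoch start.
epoch_start_labels <- function(grid) {
  s <- (seq_len(grid$epochs_per_day) - 1L) * grid$epoch_length
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

#' Construct a per-epoch posture label series for one measurement day
#'
#' @param day_id identifier of the measurement day.
#' @param labels character vector with one label per epoch, each one of
#'   `posture_levels(with_missing = TRUE)`.
#' @param grid an [epoch_grid()].
#' @return object of class `posture_day`.
#' @export
posture_day <- function(day_id, labels, grid = epoch_grid()) {
  stopifnot(inherits(grid, "epoch_grid"))
  labels <- as.character(labels)
  if (length(labels) != grid$epochs_per_day)
    stop(sprintf("expected %d labels, got %d", grid$epochs_per_day,
                 length(labels)), call. = FALSE)
  bad <- setdiff(unique(labels), posture_levels(with_missing = TRUE))
  if (length(bad))
    stop("unknown posture label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(day_id = day_id, grid = grid, labels = labels),
            class = "posture_day")
}

#' @export
print.posture_day <- function(x, ...) {
  tab <- table(factor(x$labels, levels = posture_levels(TRUE)))
  cat(sprintf("<posture_day> %s: %d epochs (%s)\n", x$day_id,
              x$grid$epochs_per_day,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Construct a tri-axial acceleration series for one measurement day
#'
#' Components are in units of g (gravity ~ 1 g at rest); timestamps are
#' naive local clock times and must all fall on one calendar day.
#'
#' @param day_id identifier of the measurement day.
#' @param time `POSIXct` timestamps, strictly increasing.
#' @param ax,ay,az acceleration components in g.
#' @param nominal_rate nominal sampling rate in Hz (default 25).
#' @return object of class `accel_series`; the samples live in
#'   `$samples`, a data.frame with columns `time, ax, ay, az`.
#' @export
accel_series <- function(day_id, time, ax, ay, az, nominal_rate = 25) {
  stopifnot(inherits(time, "POSIXct"),
            length(time) == length(ax), length(ax) == length(ay),
            length(ay) == length(az), nominal_rate > 0)
  if (length(time) == 0L)
    stop("empty acceleration series", call. = FALSE)
  if (!all(is.finite(ax) & is.finite(ay) & is.finite(az)))
    stop("acceleration components must be finite", call. = FALSE)
  o <- order(time)
  time <- time[o]; ax <- ax[o]; ay <- ay[o]; az <- az[o]
  if (any(diff(as.numeric(time)) <= 0)) {
    keep <- c(TRUE, diff(as.numeric(time)) > 0)
    warning(sprintf("dropped %d duplicate timestamp(s)", sum(!keep)),
            call. = FALSE)
    time <- time[keep]; ax <- ax[keep]; ay <- ay[keep]; az <- az[keep]
  }
  if (length(unique(format(time, "%Y-%m-%d"))) > 1L)
    stop("samples span more than one calendar day; split day files first",
         call. = FALSE)
  structure(list(day_id = day_id,
                 samples = data.frame(time = time, ax = ax, ay = ay, az = az),
                 nominal_rate = nominal_rate),
            class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %s: %d samples at nominal %g Hz (%s - %s)\n",
              x$day_id, nrow(x$samples), x$nominal_rate,
              format(min(x$samples$time), "%H:%M:%OS1"),
              format(max(x$samples$time), "%H:%M:%OS1")))
  invisible(x)
}

# Seconds since local midnight for each sample.
seconds_of_day <- function(time) {
  as.numeric(time) - as.numeric(as.POSIXct(format(time[1], "%Y-%m-%d"),
                                           tz = attr(time, "tzone") %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-open epoch index in 1..epochs_per_day for each sample.
epoch_index <- function(series, grid) {
  sod <- seconds_of_day(series$samples$time)
  pmin(grid$epochs_per_day, floor(sod / grid$epoch_length) + 1L)
}

#' Euclidean norm of acceleration samples
#'
#' The norm of the acceleration vector, `sqrt(ax^2 + ay^2 + az^2)`, in g.
#'
#' @param ax,ay,az acceleration components in g (vectorised), or `ax` may
#'   be an `accel_series`.
#' @return non-negative numeric vector.
#' @export
#' @examples
#' accel_norm(0, 0, 1)   # 1
#' accel_norm(3, 4, 0)   # 5
accel_norm <- function(ax, ay = NULL, az = NULL) {
  if (inherits(ax, "accel_series")) {
    s <- ax$samples
    return(sqrt(s$ax^2 + s$ay^2 + s$az^2))
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Flag epochs with too few samples as missing
#'
#' An epoch counts as missing when the number of observed samples falls
#' below `min_fraction` of the expected `nominal_rate * epoch_length`.
#'
#' @param series an [accel_series()].
#' @param grid an [epoch_grid()].
#' @param min_fraction required fraction of expected samples, in (0, 1].
#'   Default 0.5.
#' @return logical vector, one element per epoch, `TRUE` = missing.
#' @export
flag_missing_epochs <- function(series, grid = epoch_grid(),
                                min_fraction = 0.5) {
  stopifnot(inherits(series, "accel_series"), inherits(grid, "epoch_grid"),
            min_fraction > 0, min_fraction <= 1)
  counts <- tabulate(epoch_index(series, grid), nbins = grid$epochs_per_day)
  expected <- series$nominal_rate * grid$epoch_length
  counts / expected < min_fraction
}

#' Read a tri-axial acceleration CSV
#'
#' Expects header `timestamp,ax,ay,az` with ISO 8601 local timestamps and
#' components in g. Malformed rows (unparsable timestamp or non-numeric
#' component) are skipped with a message stating the count.
#'
#' @param path file path.
#' @param day_id identifier for the resulting series; defaults to the file
#'   name without extension.
#' @param nominal_rate nominal sampling rate in Hz.
#' @return an [accel_series()], time-sorted.
#' @export
read_accel_csv <- function(path, day_id = NULL, nominal_rate = 25) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(day_id))
    day_id <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("timestamp", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("acceleration CSV must have columns timestamp,ax,ay,az",
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("empty acceleration file: ", path, call. = FALSE)
  tm <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = ""))
  alt <- is.na(tm)
  if (any(alt))
    tm[alt] <- as.POSIXct(strptime(df$timestamp[alt],
                                   "%Y-%m-%d %H:%M:%OS", tz = ""))
  ax <- suppressWarnings(as.numeric(df$ax))
  ay <- suppressWarnings(as.numeric(df$ay))
  az <- suppressWarnings(as.numeric(df$az))
  ok <- !is.na(tm) & !is.na(ax) & !is.na(ay) & !is.na(az)
  if (!any(ok))
    stop("no parsable rows in ", path, call. = FALSE)
  if (any(!ok))
    message(sprintf("read_accel_csv: skipped %d malformed row(s) in %s",
                    sum(!ok), basename(path)))
  accel_series(day_id, tm[ok], ax[ok], ay[ok], az[ok],
               nominal_rate = nominal_rate)
}

#' Write / read a per-epoch posture CSV
#'
#' The on-disk format is `epoch_start,label` with `epoch_start` as
#' `HH:MM:SS` time of day and labels drawn from
#' `posture_levels(with_missing = TRUE)`. Writing then reading is the
#' identity on labels and grid.
#'
#' @param series a [posture_day()].
#' @param path file path.
#' @return `write_posture_csv` returns `path` invisibly;
#'   `read_posture_csv` returns a [posture_day()].
#' @export
write_posture_csv <- function(series, path) {
  stopifnot(inherits(series, "posture_day"))
  utils::write.csv(data.frame(epoch_start = epoch_start_labels(series$grid),
                              label = series$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posture_csv
#' @param day_id identifier for the read series; defaults to file name.
#' @export
read_posture_csv <- function(path, day_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(day_id))
    day_id <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("epoch_start", "label") %in% names(df)))
    stop("posture CSV must have columns epoch_start,label", call. = FALSE)
  n <- nrow(df)
  if (n == 0L) stop("empty posture file: ", path, call. = FALSE)
  if (86400L %% n != 0L)
    stop("row count ", n, " does not tile 24 h", call. = FALSE)
  bad <- setdiff(unique(df$label), posture_levels(with_missing = TRUE))
  if (length(bad))
    stop("unknown posture label(s) in ", basename(path), ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  posture_day(day_id, df$label, epoch_grid(86400L %/% n))
}
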