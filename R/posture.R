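# Trunk angle, walking detection, posture classification, and
# histogram-valley threshold estimation.

#' Trunk declination angle from tri-axial acceleration
#'
#' The angle of the sensor against the measured acceleration direction in
#' the sagittal plane:
#' `theta = (180/pi) * acos(az / |a|)`, negated when `ay < 0`. At rest the
#' acceleration is gravity, so `theta` is 0 deg lying flat on the back,
#' about 90 deg upright, and approaches 180 deg supine head-down; the sign
#' distinguishes the prone side.
#'
#' @param ax,ay,az acceleration components in g (vectorised).
#' @param zero handling of zero-norm samples, for which the angle is
#'   undefined: `"error"` (default) or `"na"`.
#' @return angles in degrees, each in \[-180, 180\].
#' @export
#' @examples
#' trunk_angle(0, 0, 1)    # 0: flat on the back
#' trunk_angle(0, 1, 0)    # 90: upright
#' trunk_angle(0, -1, 0)   # -90: prone side
trunk_angle <- function(ax, ay, az, zero = c("error", "na")) {
  zero <- match.arg(zero)
  nrm <- sqrt(ax^2 + ay^2 + az^2)
  if (any(nrm == 0, na.rm = TRUE)) {
    if (zero == "error")
      stop("zero-norm sample: trunk angle undefined", call. = FALSE)
    nrm[nrm == 0] <- NA_real_
  }
  th <- 180 / pi * acos(pmin(1, pmax(-1, az / nrm)))
  ifelse(ay >= 0, th, -th)
}

#' Angle thresholds separating the three postures
#'
#' Defaults are 35 deg (prone/upright boundary) and 143 deg
#' (upright/supine boundary), estimated for elderly stroke inpatients from
#' valleys in trunk-angle occurrence histograms; healthy wearers may need
#' per-session estimates (see [estimate_thresholds()]).
#'
#' @param prone_upright lower bound of the upright band, degrees.
#' @param upright_supine upper bound of the upright band, degrees.
#' @return object of class `posture_thresholds`.
#' @export
posture_thresholds <- function(prone_upright = 35, upright_supine = 143) {
  stopifnot(is.numeric(prone_upright), is.numeric(upright_supine),
            -180 < prone_upright, prone_upright < upright_supine,
            upright_supine < 180)
  structure(list(prone_upright = prone_upright,
                 upright_supine = upright_supine),
            class = "posture_thresholds")
}

#' @export
print.posture_thresholds <- function(x, ...) {
  cat(sprintf("<posture_thresholds> upright band [%g, %g] deg\n",
              x$prone_upright, x$upright_supine))
  invisible(x)
}

#' Rules for step-based walking detection
#'
#' Walking is detected from peaks of the detrended acceleration norm: a
#' span counts as walking when at least `min_consecutive_steps` peaks
#' exceed `peak_threshold` above a moving-average baseline with successive
#' inter-peak intervals inside `[min_interval, max_interval]` (the human
#' cadence range).
#'
#' @param peak_threshold minimum peak height above baseline, g.
#' @param min_interval,max_interval allowed inter-peak interval, seconds.
#' @param min_consecutive_steps minimum run length of valid steps (>= 2).
#' @param baseline_window moving-average baseline window, seconds.
#' @return object of class `walking_rule`.
#' @export
walking_rule <- function(peak_threshold = 0.1, min_interval = 0.3,
                         max_interval = 2.0, min_consecutive_steps = 4,
                         baseline_window = 1.0) {
  stopifnot(peak_threshold > 0, min_interval > 0,
            min_interval < max_interval, min_consecutive_steps >= 2,
            baseline_window > 0)
  structure(list(peak_threshold = peak_threshold,
                 min_interval = min_interval,
                 max_interval = max_interval,
                 min_consecutive_steps = as.integer(min_consecutive_steps),
                 baseline_window = baseline_window),
            class = "walking_rule")
}

# Centered moving average with edge padding (no NA at the borders).
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  h <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    (h + 1L):(h + length(x))]
}

# Indices of strict-left / weak-right local maxima of x exceeding thr.
find_peaks <- function(x, thr) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > thr]
}

#' Detect walking samples from the acceleration norm
#'
#' @param series an [accel_series()].
#' @param rule a [walking_rule()].
#' @return logical vector, one element per sample; `TRUE` inside spans of
#'   at least `min_consecutive_steps` valid step peaks.
#' @export
detect_walking <- function(series, rule = walking_rule()) {
  stopifnot(inherits(series, "accel_series"), inherits(rule, "walking_rule"))
  s <- series$samples
  n <- nrow(s)
  nrm <- accel_norm(series)
  win <- round(rule$baseline_window * series$nominal_rate)
  detr <- nrm - moving_average(nrm, win)
  pk <- find_peaks(detr, rule$peak_threshold)
  walking <- logical(n)
  if (length(pk) < rule$min_consecutive_steps) return(walking)
  tsec <- as.numeric(s$time)
  gaps <- diff(tsec[pk])
  valid <- gaps >= rule$min_interval & gaps <= rule$max_interval
  # Runs of consecutive valid gaps; a run of k valid gaps spans k+1 peaks.
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] + 1L >= rule$min_consecutive_steps) {
      from <- pk[starts[j]]
      to <- pk[ends[j] + 1L]
      walking[from:to] <- TRUE
    }
  }
  walking
}

#' Classify samples into the three-posture scheme
#'
#' Upright (`sitting_or_standing`) when the trunk angle lies inside the
#' upright band `[prone_upright, upright_supine]`; everything outside the
#' band -- prone, supine, and negative (prone-side) angles -- is
#' `reclining`. A walking flag upgrades upright samples to `walking`;
#' walking detected while the trunk is outside the upright band is ignored.
#'
#' @param theta trunk angle(s) in degrees, in \[-180, 180\].
#' @param walking logical walking flag(s), recycled to `length(theta)`.
#' @param thresholds a [posture_thresholds()].
#' @return character vector of labels; `NA` angles give `NA` labels.
#' @export
#' @examples
#' classify_posture(90, FALSE)  # sitting_or_standing
#' classify_posture(90, TRUE)   # walking
#' classify_posture(170, TRUE)  # reclining: walking outside band ignored
classify_posture <- function(theta, walking = FALSE,
                             thresholds = posture_thresholds()) {
  stopifnot(inherits(thresholds, "posture_thresholds"))
  if (any(abs(theta) > 180, na.rm = TRUE))
    stop("trunk angle outside [-180, 180]", call. = FALSE)
  walking <- rep_len(as.logical(walking), length(theta))
  upright <- theta >= thresholds$prone_upright &
    theta <= thresholds$upright_supine
  out <- ifelse(upright,
                ifelse(walking, "walking", "sitting_or_standing"),
                "reclining")
  out[is.na(theta)] <- NA_character_
  out
}

#' Classify a full measurement day into per-epoch posture labels
#'
#' Each sample gets a trunk angle and walking flag; per epoch the label is
#' the plurality of sample labels, with ties broken by specificity
#' (walking > sitting_or_standing > reclining). Epochs with fewer than
#' `min_fraction` of the expected samples, or with no valid samples, are
#' `missing`.
#'
#' @param accel an [accel_series()].
#' @param grid an [epoch_grid()].
#' @param thresholds a [posture_thresholds()].
#' @param rule a [walking_rule()].
#' @param min_fraction epoch completeness requirement, see
#'   [flag_missing_epochs()].
#' @return a [posture_day()] on `grid`.
#' @export
classify_day <- function(accel, grid = epoch_grid(),
                         thresholds = posture_thresholds(),
                         rule = walking_rule(), min_fraction = 0.5) {
  stopifnot(inherits(accel, "accel_series"))
  s <- accel$samples
  theta <- trunk_angle(s$ax, s$ay, s$az, zero = "na")
  walking <- detect_walking(accel, rule)
  lab <- classify_posture(theta, walking, thresholds)
  ep <- epoch_index(accel, grid)
  miss <- flag_missing_epochs(accel, grid, min_fraction)

  ok <- !is.na(lab)
  counts <- matrix(0L, nrow = grid$epochs_per_day, ncol = 3,
                   dimnames = list(NULL, .posture_priority))
  tb <- table(factor(ep[ok], levels = seq_len(grid$epochs_per_day)),
              factor(lab[ok], levels = .posture_priority))
  counts[] <- as.integer(tb)

  labels <- rep("missing", grid$epochs_per_day)
  has <- rowSums(counts) > 0 & !miss
  # which.max over priority-ordered columns: ties go to the more specific
  # activity.
  labels[has] <- .posture_priority[apply(counts[has, , drop = FALSE],
                                         1, which.max)]
  posture_day(accel$day_id, labels, grid)
}

#' Histogram of trunk-angle occurrences
#'
#' Counts trunk angles over \[-180, 180\] deg in bins of `bin_width`; the
#' valleys of this histogram between postural modes are used to place
#' classification thresholds.
#'
#' @param angles numeric vector of angles in degrees, or a list of such
#'   vectors (e.g. one per day); non-finite values are dropped.
#' @param bin_width bin width in degrees; must divide 360.
#' @return object of class `angle_histogram` with fields `bin_edges`,
#'   `counts`, `bin_width`, and `mids`.
#' @export
angle_histogram <- function(angles, bin_width = 1) {
  if (is.list(angles)) angles <- unlist(angles, use.names = FALSE)
  angles <- angles[is.finite(angles)]
  if (!length(angles))
    stop("no finite angles to histogram", call. = FALSE)
  if (any(abs(angles) > 180))
    stop("angles outside [-180, 180]", call. = FALSE)
  stopifnot(bin_width > 0, 360 %% bin_width == 0)
  edges <- seq(-180, 180, by = bin_width)
  # Half-open bins [e, e + w); +180 folded into the last bin so the total
  # count equals the input length.
  idx <- pmin(length(edges) - 1L, floor((angles + 180) / bin_width) + 1L)
  structure(list(bin_edges = edges,
                 counts = tabulate(idx, nbins = length(edges) - 1L),
                 bin_width = bin_width,
                 mids = edges[-length(edges)] + bin_width / 2),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("<angle_histogram> %d bins of %g deg, %d angles\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Export an angle histogram as CSV
#'
#' @param hist an [angle_histogram()].
#' @param path file path; written with header `bin_center,count`.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "angle_histogram"))
  utils::write.csv(data.frame(bin_center = hist$mids, count = hist$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate posture thresholds from histogram valleys
#'
#' Places each threshold at the center of the minimum-count bin of the
#' smoothed histogram within its search range (the valley between postural
#' modes). Ties go to the lowest angle; a flat histogram within a range
#' yields the range midpoint with a warning.
#'
#' @param hist an [angle_histogram()].
#' @param search_low degree range `c(lo, hi)` searched for the
#'   prone/upright valley. Default `c(15, 60)`, bracketing the published
#'   35 deg estimate with margin.
#' @param search_high range for the upright/supine valley; default
#'   `c(120, 165)` around 143 deg.
#' @param smooth_window centered moving-average window, in bins.
#' @return a [posture_thresholds()].
#' @export
estimate_thresholds <- function(hist, search_low = c(15, 60),
                                search_high = c(120, 165),
                                smooth_window = 5) {
  stopifnot(inherits(hist, "angle_histogram"),
            length(search_low) == 2, length(search_high) == 2,
            search_low[1] < search_low[2],
            search_high[1] < search_high[2],
            search_low[2] <= search_high[1])
  sm <- moving_average(as.numeric(hist$counts), smooth_window)
  valley <- function(range, what) {
    in_range <- hist$mids >= range[1] & hist$mids <= range[2]
    if (!any(in_range))
      stop("no histogram bins inside the ", what, " search range",
           call. = FALSE)
    v <- sm[in_range]
    m <- hist$mids[in_range]
    if (diff(range(v)) == 0) {
      warning("flat histogram in the ", what,
              " search range; using its midpoint", call. = FALSE)
      return(mean(range))
    }
    m[which.min(v)]  # first minimum = lowest angle on ties
  }
  posture_thresholds(valley(search_low, "prone/upright"),
                     valley(search_high, "upright/supine"))
}
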