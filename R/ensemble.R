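# Ensemble averaging across measurement days: the categorical posture
# ensemble, the quantitative (heart-rate style) ensemble, daily totals,
# the conventional day-selection baseline, and missing-rate metrics.

#' Categorical ensemble averaging of posture days
#'
#' Pools measurement days by time of day. At each epoch `t`, let `N(t)` be
#' the number of days with valid (non-missing) data and `N_i(t)` the number
#' of those showing posture `i`; the ensemble-averaged period of posture
#' `i` is
#' \deqn{P_i(t) = N_i(t) / (f N(t))}
#' with `f` the posture sampling rate (so `f^{-1}` is the epoch length;
#' 1 min by default, giving periods in minutes). When a single day is
#' valid at `t` that day's posture is passed through (`P_i` is 0 or
#' `f^{-1}`); the epoch is undefined (missing) only when data at `t` were
#' lost on *all* days. This is the imputation: the ensemble's missing set
#' is the intersection of the days' missing sets.
#'
#' @param days list of [posture_day()] objects sharing one grid.
#' @return object of class `categorical_ensemble`: a data.frame with one
#'   row per epoch and columns `epoch_start`, `n_valid`,
#'   `n_<posture>`, `p_<posture>` (minutes; `NA` where `n_valid` is 0),
#'   carrying the grid and the total day count as attributes.
#' @export
#' @examples
#' g <- epoch_grid(86400 / 3)  # toy 3-epoch day
#' d1 <- posture_day("d1", c("reclining", "walking", "missing"), g)
#' d2 <- posture_day("d2", c("reclining", "sitting_or_standing", "missing"), g)
#' ensemble_categorical(list(d1, d2))
ensemble_categorical <- function(days) {
  if (!length(days)) stop("no measurement days supplied", call. = FALSE)
  stopifnot(all(vapply(days, inherits, logical(1), "posture_day")))
  grid <- days[[1]]$grid
  for (d in days)
    if (!grids_identical(d$grid, grid))
      stop("all days must share one epoch grid", call. = FALSE)
  lab <- vapply(days, function(d) d$labels,
                character(grid$epochs_per_day))
  lab <- matrix(lab, nrow = grid$epochs_per_day)
  lv <- posture_levels()
  n_i <- vapply(lv, function(l) rowSums(lab == l),
                numeric(grid$epochs_per_day))
  n_valid <- rowSums(n_i)
  minutes_per_epoch <- grid$epoch_length / 60  # f^{-1} in minutes
  p_i <- n_i / n_valid * minutes_per_epoch     # NaN where n_valid = 0
  p_i[n_valid == 0, ] <- NA_real_
  out <- data.frame(epoch_start = epoch_start_labels(grid),
                    n_valid = as.integer(n_valid))
  for (l in lv) out[[paste0("n_", l)]] <- as.integer(n_i[, l])
  for (l in lv) out[[paste0("p_", l)]] <- p_i[, l]
  structure(out, grid = grid, n_total = length(days),
            class = c("categorical_ensemble", "data.frame"))
}

#' Quantitative ensemble averaging (heart-rate style)
#'
#' Per-epoch mean of a numeric variable over the days on which it was
#' measured; with a single valid day the measured value is substituted
#' unchanged, and the epoch is missing only when all days are.
#'
#' @param days list of numeric vectors (one value per epoch, `NA` =
#'   missing), all of one length, or a matrix with one column per day.
#' @param grid an [epoch_grid()]; defaults to a grid with
#'   `length(days[[1]])` epochs.
#' @return object of class `quantitative_ensemble`: data.frame with
#'   columns `epoch_start`, `n_valid`, `mean`.
#' @export
ensemble_quantitative <- function(days, grid = NULL) {
  if (is.matrix(days)) days <- asplit(days, 2)
  if (!length(days)) stop("no measurement days supplied", call. = FALSE)
  n <- unique(lengths(days))
  if (length(n) != 1)
    stop("all days must share one epoch grid", call. = FALSE)
  if (is.null(grid)) grid <- epoch_grid(86400 / n)
  stopifnot(grid$epochs_per_day == n)
  m <- matrix(unlist(days), nrow = n)
  n_valid <- rowSums(!is.na(m))
  avg <- rowMeans(m, na.rm = TRUE)
  avg[n_valid == 0] <- NA_real_
  structure(data.frame(epoch_start = epoch_start_labels(grid),
                       n_valid = as.integer(n_valid), mean = avg),
            grid = grid, n_total = length(days),
            class = c("quantitative_ensemble", "data.frame"))
}

#' Total period of each posture over 24 h
#'
#' Sums the ensemble-averaged periods over the day,
#' `T_i = sum_t P_i(t)`, skipping epochs missing on all days. The ratios
#' are taken over the total measured period `sum_i T_i`.
#'
#' @param ens a [ensemble_categorical()] result.
#' @return data.frame with columns `posture`, `minutes`, `ratio`.
#' @export
total_periods <- function(ens) {
  stopifnot(inherits(ens, "categorical_ensemble"))
  lv <- posture_levels()
  mins <- vapply(lv, function(l) sum(ens[[paste0("p_", l)]], na.rm = TRUE),
                 numeric(1))
  data.frame(posture = lv, minutes = as.numeric(mins),
             ratio = as.numeric(mins) / sum(mins), row.names = NULL)
}

#' Hard-label view of a categorical ensemble
#'
#' Collapses the fractional periods to one label per epoch by day-count
#' plurality (`argmax_i N_i(t)`), ties broken by specificity
#' (walking > sitting_or_standing > reclining); all-days-missing epochs
#' stay `missing`. Intended for CSV export and plotting, not analysis.
#'
#' @param ens a [ensemble_categorical()] result.
#' @param day_id identifier for the resulting series.
#' @return a [posture_day()].
#' @export
hard_labels <- function(ens, day_id = "ensemble") {
  stopifnot(inherits(ens, "categorical_ensemble"))
  counts <- as.matrix(ens[paste0("n_", .posture_priority)])
  labels <- rep("missing", nrow(ens))
  has <- ens$n_valid > 0
  labels[has] <- .posture_priority[apply(counts[has, , drop = FALSE],
                                         1, which.max)]
  posture_day(day_id, labels, attr(ens, "grid"))
}

#' Conventional imputation baseline: keep the best day
#'
#' Returns the measurement day with the fewest missing epochs, discarding
#' the rest (ties go to the earliest day). This is the baseline the
#' ensemble method is compared against.
#'
#' @param days list of [posture_day()] objects.
#' @return the selected [posture_day()].
#' @export
conventional_select_day <- function(days) {
  if (!length(days)) stop("no measurement days supplied", call. = FALSE)
  stopifnot(all(vapply(days, inherits, logical(1), "posture_day")))
  miss <- vapply(days, function(d) sum(d$labels == "missing"), numeric(1))
  days[[which.min(miss)]]
}

#' Missing-data rate over the 24-h epoch grid
#'
#' Percentage of the day's epochs with no usable data. For a single day or
#' ensemble this is `100 * missing / epochs_per_day`; for a multi-day raw
#' session (a list of days) it is the mean of the per-day rates -- the
#' reference rate "without imputation".
#'
#' @param x a [posture_day()], a [ensemble_categorical()] result, or a
#'   list of posture days.
#' @param ... unused.
#' @return percentage in \[0, 100\].
#' @export
missing_rate <- function(x, ...) UseMethod("missing_rate")

#' @export
missing_rate.posture_day <- function(x, ...) {
  100 * sum(x$labels == "missing") / x$grid$epochs_per_day
}

#' @export
missing_rate.categorical_ensemble <- function(x, ...) {
  100 * sum(x$n_valid == 0) / attr(x, "grid")$epochs_per_day
}

#' @export
missing_rate.quantitative_ensemble <- function(x, ...) {
  100 * sum(x$n_valid == 0) / attr(x, "grid")$epochs_per_day
}

#' @export
missing_rate.list <- function(x, ...) {
  mean(vapply(x, missing_rate, numeric(1)))
}

#' Write a categorical ensemble or its daily totals as CSV
#'
#' The ensemble CSV has columns
#' `epoch_start,P_reclining,P_sitting_or_standing,P_walking,N_valid_days`;
#' epochs missing on all days get empty period fields. The totals CSV has
#' columns `posture,minutes,ratio`.
#'
#' @param ens a [ensemble_categorical()] result.
#' @param path file path.
#' @export
write_ensemble_csv <- function(ens, path) {
  stopifnot(inherits(ens, "categorical_ensemble"))
  df <- data.frame(epoch_start = ens$epoch_start,
                   P_reclining = ens$p_reclining,
                   P_sitting_or_standing = ens$p_sitting_or_standing,
                   P_walking = ens$p_walking,
                   N_valid_days = ens$n_valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @param totals a [total_periods()] result.
#' @export
write_totals_csv <- function(totals, path) {
  stopifnot(is.data.frame(totals),
            all(c("posture", "minutes", "ratio") %in% names(totals)))
  utils::write.csv(totals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
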