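# Artificial block-loss injection and the validation experiments:
# imputation-method comparison and posture-ratio stability vs. loss rate.

#' Specification of artificial MCAR block losses
#'
#' Losses are injected as fixed-length blocks of epochs placed uniformly
#' at random, independent of posture and time of day (missing completely
#' at random).
#'
#' @param target_rate fraction of the day's epochs to mask, in \[0, 1).
#' @param block_length loss block length in epochs (default 1, i.e. 1 min
#'   on the default grid).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return object of class `loss_spec`.
#' @export
loss_spec <- function(target_rate, block_length = 1, seed = NULL) {
  stopifnot(is.numeric(target_rate), target_rate >= 0, target_rate < 1,
            block_length >= 1)
  structure(list(target_rate = target_rate,
                 block_length = as.integer(block_length),
                 seed = seed),
            class = "loss_spec")
}

#' Inject artificial block losses into a posture day
#'
#' Masks `floor(target_rate * epochs_per_day / block_length)` blocks of
#' `block_length` consecutive epochs, chosen uniformly without overlap
#' among the injected blocks. Pre-existing missing epochs stay missing;
#' injection never unmasks data. Deterministic given `spec$seed`.
#'
#' @param day a [posture_day()].
#' @param spec a [loss_spec()].
#' @return the masked [posture_day()].
#' @export
inject_losses <- function(day, spec) {
  stopifnot(inherits(day, "posture_day"), inherits(spec, "loss_spec"))
  E <- day$grid$epochs_per_day
  bl <- spec$block_length
  if (bl > E)
    stop("target_rate/block_length combination infeasible: block of ", bl,
         " epochs exceeds the ", E, "-epoch day", call. = FALSE)
  n_blocks <- floor(spec$target_rate * E / bl)
  if (n_blocks == 0L) return(day)
  starts <- with_seed(spec$seed, {
    chosen <- integer(0)
    covered <- logical(E)
    tries <- 0L
    while (length(chosen) < n_blocks) {
      cand <- sample.int(E - bl + 1L, 1L)
      span <- cand:(cand + bl - 1L)
      if (!any(covered[span])) {
        chosen <- c(chosen, cand)
        covered[span] <- TRUE
      }
      tries <- tries + 1L
      if (tries > 1000L * n_blocks)
        stop("could not place non-overlapping loss blocks; ",
             "lower target_rate or block_length", call. = FALSE)
    }
    chosen
  })
  labels <- day$labels
  for (st in starts) labels[st:(st + bl - 1L)] <- "missing"
  posture_day(day$day_id, labels, day$grid)
}

#' Compare imputation methods across measurement sessions
#'
#' For each multi-day session computes the 24-h missing-data rate of three
#' methods: `none` (reference: mean of the per-day rates), `conventional`
#' (keep the day with fewer missing epochs), and `ensemble` (categorical
#' ensemble averaging). Sessions are then grouped by their reference rate
#' and summarised by median and quartiles per method and group.
#'
#' @param sessions list of sessions, each a list of [posture_day()]
#'   objects sharing one grid.
#' @param rate_groups numeric vector of interior bin edges (%) used to
#'   group sessions by reference rate; `NULL` (default) uses the 25th,
#'   50th and 75th percentiles of the observed reference rates.
#' @return object of class `imputation_comparison` with components
#'   `per_session` (data.frame `session, method, missing_rate, group`) and
#'   `summary` (median and quartiles per group and method).
#' @export
run_imputation_comparison <- function(sessions, rate_groups = NULL) {
  if (!length(sessions)) stop("no sessions supplied", call. = FALSE)
  ids <- names(sessions) %||% as.character(seq_along(sessions))
  if (is.null(names(sessions))) names(sessions) <- ids
  rates <- do.call(rbind, lapply(ids, function(id) {
    days <- sessions[[id]]
    data.frame(session = id,
               method = c("none", "conventional", "ensemble"),
               missing_rate = c(missing_rate(days),
                                missing_rate(conventional_select_day(days)),
                                missing_rate(ensemble_categorical(days))))
  }))
  ref <- rates$missing_rate[rates$method == "none"]
  if (is.null(rate_groups))
    rate_groups <- unname(stats::quantile(ref, c(0.25, 0.5, 0.75)))
  edges <- unique(c(-Inf, sort(rate_groups), Inf))
  grp <- cut(ref, breaks = edges)
  rates$group <- rep(grp, each = 3)

  present <- table(grp)
  if (any(present == 0))
    warning("empty missing-rate group(s) omitted: ",
            paste(names(present)[present == 0], collapse = ", "),
            call. = FALSE)
  smry <- do.call(rbind, lapply(split(rates, list(rates$group, rates$method),
                                      drop = TRUE), function(d) {
    q <- stats::quantile(d$missing_rate, c(0.25, 0.5, 0.75))
    data.frame(group = d$group[1], method = d$method[1], n = nrow(d),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
  rownames(smry) <- NULL
  structure(list(per_session = rates, summary = smry,
                 rate_groups = rate_groups),
            class = "imputation_comparison")
}

#' @export
print.imputation_comparison <- function(x, ...) {
  cat("<imputation_comparison>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Posture-ratio stability under increasing artificial loss
#'
#' Starting from near-complete sessions, injects MCAR block losses at each
#' target rate into every day of every session, re-runs the ensemble
#' imputation, and records the per-posture total periods and their ratios
#' over the total measured period. Replicated loss draws quantify the
#' sampling variability; the experiment is reproducible bit-for-bit given
#' the seed.
#'
#' @param sessions list of sessions (lists of [posture_day()]), each with
#'   under `max_native_missing` percent natively missing epochs.
#' @param rates numeric vector of target loss rates (fractions per day).
#' @param replicates loss draws per session and rate.
#' @param seed integer base seed.
#' @param block_length loss block length in epochs.
#' @param max_native_missing maximum tolerated native missing rate (%).
#' @return object of class `ratio_stability` with components `results`
#'   (data.frame `rate, replicate, session, posture, period_min, ratio`),
#'   `baseline` (no-loss periods and ratios per session), and `medians`
#'   (per rate and posture, across sessions and replicates).
#' @export
run_ratio_stability <- function(sessions, rates, replicates = 50,
                                seed = 1, block_length = 1,
                                max_native_missing = 1) {
  if (!length(sessions)) stop("no sessions supplied", call. = FALSE)
  if (is.null(names(sessions)))
    names(sessions) <- as.character(seq_along(sessions))
  for (id in names(sessions)) {
    nat <- missing_rate(sessions[[id]])
    if (nat >= max_native_missing)
      stop(sprintf("session %s has %.2f%% native missing (limit %g%%)",
                   id, nat, max_native_missing), call. = FALSE)
  }
  baseline <- do.call(rbind, lapply(names(sessions), function(id) {
    tp <- total_periods(ensemble_categorical(sessions[[id]]))
    cbind(session = id, tp)
  }))
  rows <- vector("list", length(rates) * replicates * length(sessions))
  k <- 0L
  for (ri in seq_along(rates)) {
    for (rep_i in seq_len(replicates)) {
      for (si in seq_along(sessions)) {
        days <- sessions[[si]]
        lost <- lapply(seq_along(days), function(di)
          inject_losses(days[[di]],
                        loss_spec(rates[ri], block_length,
                                  seed = child_seed(seed, ri, rep_i,
                                                    si, di))))
        tp <- total_periods(ensemble_categorical(lost))
        k <- k + 1L
        rows[[k]] <- data.frame(rate = rates[ri], replicate = rep_i,
                                session = names(sessions)[si],
                                posture = tp$posture,
                                period_min = tp$minutes, ratio = tp$ratio)
      }
    }
  }
  results <- do.call(rbind, rows)
  medians <- stats::aggregate(cbind(period_min, ratio) ~ rate + posture,
                              data = results, FUN = stats::median)
  structure(list(results = results, baseline = baseline, medians = medians,
                 rates = rates, replicates = replicates, seed = seed),
            class = "ratio_stability")
}

#' @export
print.ratio_stability <- function(x, ...) {
  cat(sprintf("<ratio_stability> %d rates x %d replicates\n",
              length(x$rates), x$replicates))
  print(x$medians, digits = 3)
  invisible(x)
}

#' Write experiment results as tidy CSVs
#'
#' `write_comparison_csv` writes `session_id,method,missing_rate`;
#' `write_stability_csv` writes
#' `rate,replicate,posture,period_min,ratio` (session-level rows).
#'
#' @param x an experiment result.
#' @param path file path.
#' @export
write_comparison_csv <- function(x, path) {
  stopifnot(inherits(x, "imputation_comparison"))
  df <- x$per_session[c("session", "method", "missing_rate")]
  names(df)[1] <- "session_id"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
write_stability_csv <- function(x, path) {
  stopifnot(inherits(x, "ratio_stability"))
  utils::write.csv(x$results[c("rate", "replicate", "posture",
                               "period_min", "ratio")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
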