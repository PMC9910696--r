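# Shared fixtures and independent oracles. Short label aliases keep the
# toy-day constructions readable.
REC <- "reclining"
SIT <- "sitting_or_standing"
WLK <- "walking"
MIS <- "missing"

toy_grid <- function(n_epochs) epoch_grid(86400 / n_epochs)

toy_day <- function(labels, id = "day", grid = toy_grid(length(labels))) {
  posture_day(id, labels, grid)
}

# The five-day worked-example session: a full default (1440-epoch) grid,
# all reclining except epoch 5 (per-day labels REC,SIT,SIT,WLK,WLK; all 5
# days valid) and epoch 6 (MIS,SIT,SIT,WLK,MIS; 3 days valid).
worked_example_days <- function() {
  at5 <- c(REC, SIT, SIT, WLK, WLK)
  at6 <- c(MIS, SIT, SIT, WLK, MIS)
  lapply(1:5, function(d) {
    v <- rep(REC, 1440)
    v[5] <- at5[d]
    v[6] <- at6[d]
    posture_day(paste0("d", d), v, epoch_grid())
  })
}

# Random posture days on a shared grid, with missing epochs at rate p_miss.
random_days <- function(n_days, n_epochs, p_miss = 0.2, seed = 1) {
  g <- toy_grid(n_epochs)
  set.seed(seed)
  lapply(seq_len(n_days), function(d) {
    lab <- sample(c(REC, SIT, WLK), n_epochs, replace = TRUE)
    lab[stats::runif(n_epochs) < p_miss] <- MIS
    posture_day(paste0("d", d), lab, g)
  })
}

# Independent brute-force oracle for categorical ensemble averaging:
# explicit double loop over epochs and labels.
oracle_ensemble <- function(days) {
  g <- days[[1]]$grid
  mins <- g$epoch_length / 60
  lv <- c(REC, SIT, WLK)
  out <- matrix(NA_real_, nrow = g$epochs_per_day, ncol = 3,
                dimnames = list(NULL, lv))
  n_valid <- integer(g$epochs_per_day)
  for (t in seq_len(g$epochs_per_day)) {
    labs <- vapply(days, function(d) d$labels[t], character(1))
    labs <- labs[labs != MIS]
    n_valid[t] <- length(labs)
    if (length(labs))
      for (l in lv) out[t, l] <- sum(labs == l) / length(labs) * mins
  }
  list(p = out, n_valid = n_valid)
}

# Independent brute-force walking oracle: locate peaks by direct
# neighbour comparison, then union the spans of every contiguous peak
# subsequence whose gaps all fall inside the rule's interval band.
oracle_walking <- function(series, rule) {
  s <- series$samples
  nrm <- sqrt(s$ax^2 + s$ay^2 + s$az^2)
  w <- round(rule$baseline_window * series$nominal_rate)
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  # baseline with edge-value padding, computed sample by sample
  basep <- vapply(seq_along(nrm), function(i) {
    lo <- i - h; hi <- i + h
    xs <- nrm[pmax(1, pmin(length(nrm), lo:hi))]
    mean(xs)
  }, numeric(1))
  d <- nrm - basep
  pk <- integer(0)
  for (i in 2:(length(d) - 1))
    if (d[i] > d[i - 1] && d[i] >= d[i + 1] && d[i] > rule$peak_threshold)
      pk <- c(pk, i)
  walking <- logical(length(d))
  tsec <- as.numeric(s$time)
  if (length(pk) >= rule$min_consecutive_steps) {
    for (i in seq_along(pk)) for (j in seq_along(pk)) {
      if (j - i + 1 < rule$min_consecutive_steps) next
      gaps <- diff(tsec[pk[i:j]])
      if (all(gaps >= rule$min_interval & gaps <= rule$max_interval))
        walking[pk[i]:pk[j]] <- TRUE
    }
  }
  walking
}

# Acceleration series from a raw norm signal (oriented along z).
norm_series <- function(norm, rate = 25, id = "sig") {
  t0 <- as.POSIXct("2000-01-01 12:00:00", tz = "")
  accel_series(id, t0 + (seq_along(norm) - 1) / rate,
               ax = rep(0, length(norm)), ay = rep(0, length(norm)),
               az = norm, nominal_rate = rate)
}
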