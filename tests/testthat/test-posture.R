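test_that("trunk angle matches the signed-arccos geometry", {
  expect_equal(trunk_angle(0, 0, 1), 0)
  expect_equal(trunk_angle(0, 1, 0), 90)
  expect_equal(trunk_angle(0, -1, 0), -90)
  expect_equal(trunk_angle(0, 0, -1), 180)
  expect_equal(trunk_angle(0, sin(pi / 6), cos(pi / 6)), 30)
  expect_error(trunk_angle(0, 0, 0), "zero-norm")
  expect_true(is.na(trunk_angle(0, 0, 0, zero = "na")))
})

test_that("trunk angle is scale-invariant and antisymmetric in ay", {
  set.seed(2)
  a <- matrix(rnorm(60), ncol = 3)
  th <- trunk_angle(a[, 1], a[, 2], a[, 3])
  expect_true(all(abs(th) <= 180))
  for (k in c(0.1, 1, 7)) {
    expect_equal(trunk_angle(k * a[, 1], k * a[, 2], k * a[, 3]), th)
  }
  flip <- trunk_angle(a[, 1], -a[, 2], a[, 3])
  interior <- abs(th) > 1e-9 & abs(abs(th) - 180) > 1e-9
  expect_equal(flip[interior], -th[interior])
})

test_that("sample classification is total and walking only overlays the upright band", {
  thr <- posture_thresholds()
  expect_equal(classify_posture(90, FALSE, thr), SIT)
  expect_equal(classify_posture(90, TRUE, thr), WLK)
  expect_equal(classify_posture(c(10, 170, -90), FALSE, thr),
               rep(REC, 3))
  expect_equal(classify_posture(170, TRUE, thr), REC)
  expect_equal(classify_posture(-90, TRUE, thr), REC)
  # band edges are inclusive
  expect_equal(classify_posture(c(35, 143), FALSE, thr), c(SIT, SIT))
  expect_error(classify_posture(181, FALSE, thr), "outside")
  # totality: exactly one valid label for any angle/flag combination
  th <- seq(-180, 180, by = 0.5)
  for (wf in c(TRUE, FALSE)) {
    lab <- classify_posture(th, wf, thr)
    expect_true(all(lab %in% posture_levels()))
  }
})

test_that("walking detection matches the brute-force rule oracle", {
  rule <- walking_rule()
  # steady 1 g: no peaks, no walking
  expect_false(any(detect_walking(norm_series(rep(1, 200)), rule)))
  # 2 Hz oscillation for 10 s flanked by rest: the oscillation is found
  t <- (0:749) / 25
  osc <- ifelse(t >= 10 & t < 20, 0.3 * sin(2 * pi * 2 * t), 0)
  s <- norm_series(1 + osc)
  got <- detect_walking(s, rule)
  expect_true(any(got))
  expect_true(all(which(got) >= 10 * 25 & which(got) <= 20 * 25 + 1))
  expect_identical(got, oracle_walking(s, rule))
  # two isolated peaks 10 s apart: interval exceeds max_interval
  spike <- rep(1, 750)
  spike[c(100, 350)] <- 1.5
  s2 <- norm_series(spike)
  expect_false(any(detect_walking(s2, rule)))
  expect_identical(detect_walking(s2, rule), oracle_walking(s2, rule))
  # randomized signals agree with the oracle
  set.seed(5)
  for (i in 1:4) {
    sig <- 1 + 0.25 * sin(2 * pi * runif(1, 0.4, 3) * (0:599) / 25) +
      rnorm(600, 0, 0.05)
    s3 <- norm_series(sig)
    expect_identical(detect_walking(s3, rule), oracle_walking(s3, rule))
  }
})

test_that("day classification aggregates by plurality and propagates missing epochs", {
  g <- epoch_grid()
  t0 <- as.POSIXct("2000-01-01 00:00:00", tz = "")
  # epoch 1: all flat (theta 0); epoch 2: 70% upright / 30% flat;
  # epoch 3: only 10 samples (under min_fraction); epoch 4+: empty
  ep1 <- data.frame(t = (0:1499) / 25, th = 0)
  ep2 <- data.frame(t = 60 + (0:1499) / 25, th = rep(c(90, 0), c(1050, 450)))
  ep3 <- data.frame(t = 120 + (0:9) / 25, th = 90)
  d <- rbind(ep1, ep2, ep3)
  rad <- d$th * pi / 180
  s <- accel_series("mix", t0 + d$t, rep(0, nrow(d)), sin(rad), cos(rad))
  day <- classify_day(s, g)
  expect_equal(day$labels[1], REC)
  expect_equal(day$labels[2], SIT)
  expect_equal(day$labels[3], MIS)
  expect_true(all(day$labels[4:1440] == MIS))
})

test_that("angle histograms conserve counts and locate valleys", {
  h <- angle_histogram(rep(0.2, 100), bin_width = 1)
  expect_equal(length(h$counts), 360)
  expect_equal(sum(h$counts), 100)
  expect_equal(h$counts[h$mids == 0.5], 100)
  expect_equal(sum(angle_histogram(c(-180, 0, 180, 42.3))$counts), 4)
  expect_error(angle_histogram(numeric(0)), "no finite angles")

  # trimodal histogram with deep valleys at 40 and 140 degrees
  set.seed(3)
  angs <- c(rnorm(4000, 10, 9), rnorm(3000, 90, 15), rnorm(2000, 170, 9))
  angs <- angs[abs(angs) <= 180]
  est <- estimate_thresholds(angle_histogram(angs))
  # crossing points of the component densities, found numerically
  dens <- function(x) 4 * dnorm(x, 10, 9) + 3 * dnorm(x, 90, 15) +
    2 * dnorm(x, 170, 9)
  lo <- optimize(dens, c(15, 60))$minimum
  hi <- optimize(dens, c(120, 165))$minimum
  expect_lt(abs(est$prone_upright - lo), 5)
  expect_lt(abs(est$upright_supine - hi), 5)
})

test_that("threshold search handles unique minima, ties, and flat ranges", {
  counts <- rep(100L, 360)
  mids <- seq(-179.5, 179.5)
  counts[mids == 35.5] <- 0L   # unique zero bin in the low range
  h <- structure(list(bin_edges = seq(-180, 180), counts = counts,
                      bin_width = 1, mids = mids),
                 class = "angle_histogram")
  est <- suppressWarnings(estimate_thresholds(h, smooth_window = 1))
  expect_equal(est$prone_upright, 35.5)
  # flat high range: midpoint with a warning
  expect_warning(estimate_thresholds(h, smooth_window = 1),
                 "flat histogram")
  expect_equal(suppressWarnings(
    estimate_thresholds(h, smooth_window = 1))$upright_supine, 142.5)
  # ties go to the lowest angle
  counts2 <- rep(100L, 360)
  counts2[mids %in% c(40.5, 50.5)] <- 0L
  h2 <- h; h2$counts <- counts2
  expect_equal(suppressWarnings(
    estimate_thresholds(h2, smooth_window = 1))$prone_upright, 40.5)
})

test_that("threshold and rule constructors validate their invariants", {
  expect_error(posture_thresholds(143, 35))
  expect_error(posture_thresholds(-181, 0))
  expect_error(walking_rule(min_interval = 2, max_interval = 1))
  expect_error(walking_rule(min_consecutive_steps = 1))
})
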