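test_that("the five-day worked example yields the published periods", {
  e <- ensemble_categorical(worked_example_days())
  # epoch 5: counts (1, 2, 2) over N(t) = 5, one-minute epochs
  expect_equal(e$n_valid[5], 5L)
  expect_equal(e$p_reclining[5], 0.2)
  expect_equal(e$p_sitting_or_standing[5], 0.4)
  expect_equal(e$p_walking[5], 0.4)
  # epoch 6: two days lost, counts (0, 2, 1) over N(t) = 3
  expect_equal(e$n_valid[6], 3L)
  expect_equal(e$p_reclining[6], 0)
  expect_equal(round(e$p_sitting_or_standing[6], 2), 0.67)
  expect_equal(round(e$p_walking[6], 2), 0.33)
})

test_that("categorical ensemble matches the brute-force counting oracle", {
  set.seed(10)
  for (i in 1:6) {
    n_days <- sample(1:10, 1)
    n_epochs <- sample(c(10, 32, 96, 100), 1)
    days <- random_days(n_days, n_epochs, p_miss = runif(1, 0, 0.5),
                        seed = 100 + i)
    e <- ensemble_categorical(days)
    o <- oracle_ensemble(days)
    expect_equal(e$n_valid, o$n_valid)
    expect_equal(e$p_reclining, unname(o$p[, REC]))
    expect_equal(e$p_sitting_or_standing, unname(o$p[, SIT]))
    expect_equal(e$p_walking, unname(o$p[, WLK]))
  }
})

test_that("per-epoch counts and periods are conserved on arbitrary inputs", {
  for (i in 1:5) {
    days <- random_days(sample(2:8, 1), 90, p_miss = 0.3, seed = 40 + i)
    e <- ensemble_categorical(days)
    mins <- attr(e, "grid")$epoch_length / 60
    n_i <- e$n_reclining + e$n_sitting_or_standing + e$n_walking
    expect_equal(n_i, e$n_valid)
    expect_true(all(e$n_valid <= attr(e, "n_total")))
    ok <- e$n_valid > 0
    p_sum <- e$p_reclining + e$p_sitting_or_standing + e$p_walking
    expect_equal(p_sum[ok], rep(mins, sum(ok)))
    expect_true(all(is.na(p_sum[!ok])))
  }
})

test_that("ensembling copies of one complete day reproduces its indicators", {
  d <- random_days(1, 120, p_miss = 0, seed = 3)[[1]]
  for (n in c(1, 4)) {
    e <- ensemble_categorical(rep(list(d), n))
    mins <- d$grid$epoch_length / 60
    expect_true(all(unlist(e[paste0("p_", posture_levels())]) %in%
                      c(0, mins)))
    expect_identical(hard_labels(e)$labels, d$labels)
  }
})

test_that("the ensemble is missing only where all days are missing", {
  days <- random_days(4, 200, p_miss = 0.4, seed = 9)
  e <- ensemble_categorical(days)
  all_missing <- Reduce(`&`, lapply(days, function(d) d$labels == MIS))
  expect_identical(e$n_valid == 0, all_missing)
  expect_equal(missing_rate(e), 100 * mean(all_missing))
})

test_that("mismatched grids and empty day lists are rejected", {
  expect_error(ensemble_categorical(list()), "no measurement days")
  d1 <- toy_day(rep(REC, 100))
  d2 <- toy_day(rep(REC, 200))
  expect_error(ensemble_categorical(list(d1, d2)), "one epoch grid")
})

test_that("quantitative ensemble averages valid days and substitutes singletons", {
  g <- toy_grid(4)
  e <- ensemble_quantitative(list(c(60, NA, NA, 70), c(80, 55, NA, 74)), g)
  expect_equal(e$mean, c(70, 55, NA, 72))
  expect_equal(e$n_valid, c(2L, 1L, 0L, 2L))
  expect_equal(missing_rate(e), 25)
  # bounded by the per-day extremes wherever defined
  set.seed(6)
  m <- matrix(rnorm(5 * 40, 70, 10), ncol = 5)
  m[sample(length(m), 60)] <- NA
  eq <- ensemble_quantitative(m, toy_grid(40))
  ok <- eq$n_valid > 0
  lo <- apply(m, 1, min, na.rm = TRUE)[ok]
  hi <- apply(m, 1, max, na.rm = TRUE)[ok]
  expect_true(all(eq$mean[ok] >= lo - 1e-12 & eq$mean[ok] <= hi + 1e-12))
})

test_that("daily totals equal the brute-force double loop and conserve time", {
  days <- random_days(5, 144, p_miss = 0.25, seed = 12)
  e <- ensemble_categorical(days)
  tp <- total_periods(e)
  o <- oracle_ensemble(days)
  for (l in posture_levels())
    expect_equal(tp$minutes[tp$posture == l], sum(o$p[, l], na.rm = TRUE))
  mins <- days[[1]]$grid$epoch_length / 60
  expect_equal(sum(tp$minutes), mins * sum(e$n_valid > 0))
  expect_equal(sum(tp$ratio), 1)
})

test_that("the conventional baseline keeps the day with fewest missing epochs", {
  g <- toy_grid(100)
  d5 <- posture_day("a", replace(rep(REC, 100), 1:5, MIS), g)
  d3 <- posture_day("b", replace(rep(REC, 100), 1:3, MIS), g)
  expect_identical(conventional_select_day(list(d5, d3))$day_id, "b")
  expect_identical(conventional_select_day(list(d3, d5, d3))$day_id, "b")
  expect_identical(conventional_select_day(list(d5))$day_id, "a")
  expect_error(conventional_select_day(list()), "no measurement days")
})

test_that("missing rates cover the reference, day, and ensemble views", {
  g <- toy_grid(1440)
  full <- posture_day("f", rep(SIT, 1440), g)
  holey <- posture_day("h", replace(rep(SIT, 1440), 1:144, MIS), g)
  expect_equal(missing_rate(full), 0)
  expect_equal(missing_rate(holey), 10)
  expect_equal(missing_rate(list(full, holey)), 5)
})

test_that("dominance: ensemble <= best day <= conventional <= reference", {
  for (i in 1:8) {
    days <- random_days(sample(2:6, 1), 150, p_miss = runif(1, 0.05, 0.6),
                        seed = 70 + i)
    r_days <- vapply(days, missing_rate, numeric(1))
    r_ens <- missing_rate(ensemble_categorical(days))
    r_conv <- missing_rate(conventional_select_day(days))
    r_ref <- missing_rate(days)
    expect_lte(r_ens, min(r_days))
    expect_equal(r_conv, min(r_days))
    expect_lte(r_conv, r_ref)
  }
})

test_that("ensemble and totals CSV exports carry the published layout", {
  days <- worked_example_days()
  e <- ensemble_categorical(days)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(e, f)
  df <- read.csv(f)
  expect_named(df, c("epoch_start", "P_reclining", "P_sitting_or_standing",
                     "P_walking", "N_valid_days"))
  expect_equal(nrow(df), 1440)
  write_totals_csv(total_periods(e), f)
  expect_named(read.csv(f), c("posture", "minutes", "ratio"))
})
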