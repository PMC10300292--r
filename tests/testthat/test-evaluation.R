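test_that("time-in-warning AUC matches brute-force enumeration", {
  # hand series: events at steps 2 and 4
  lik <- c(0.1, 0.9, 0.2, 0.8, 0.1, 0.3)
  lab <- c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(lik, lab), oracle_auc(lik, lab))
  expect_equal(roc_auc(lik, lab), 5 / 6)
  # random short series, including heavy ties
  set.seed(11)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    lik <- sample(round(runif(n, 0, 1), sample(c(1, 2), 1)), n)
    lab <- runif(n) < 0.3
    if (!any(lab) || all(lab)) next
    expect_equal(roc_auc(lik, lab), oracle_auc(lik, lab), tolerance = 1e-12)
  }
})

test_that("AUC anchors: constant forecasts 0.5, indicator forecasts near 1", {
  lab <- rep(FALSE, 200); lab[c(17, 60, 150)] <- TRUE
  expect_equal(roc_auc(rep(0.3, 200), lab), 0.5)
  expect_equal(roc_auc(as.numeric(lab), lab), 1 - sum(lab) / 200 / 2)
  expect_gt(roc_auc(as.numeric(lab), lab), 0.99)
  expect_error(roc_auc(rep(0.3, 10), rep(FALSE, 10)), "no event steps")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(12)
  lik <- runif(500)
  lab <- runif(500) < 0.1
  a <- roc_auc(lik, lab)
  expect_equal(roc_auc(qlogis(lik), lab), a)
  expect_equal(roc_auc(lik^3, lab), a)
  expect_equal(roc_auc(5 * lik - 2, lab), a)
})

test_that("AUC of labels independent of the forecast converges to 1/2", {
  set.seed(13)
  aucs <- vapply(1:20, function(i) {
    lik <- runif(10000)
    lab <- runif(10000) < 0.05
    roc_auc(lik, lab)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("operating point counts sensitivity and time in high directly", {
  risk <- factor(c("high", "low", "high", "medium", "low", "high", "low",
                   "low", "high", "low"),
                 levels = c("low", "medium", "high"))
  lab <- c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE)
  op <- operating_point(risk, lab)
  expect_equal(op[["sensitivity"]], 2 / 4)
  expect_equal(op[["time_in_high"]], 4 / 10)
  all_high <- factor(rep("high", 10), levels = levels(risk))
  expect_equal(unname(operating_point(all_high, lab)), c(1, 1))
  none <- factor(rep("low", 10), levels = levels(risk))
  expect_equal(unname(operating_point(none, lab)), c(0, 0))
})

test_that("Brier skill score anchors and hand arithmetic", {
  lab <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  # perfect forecast
  expect_equal(brier_skill_score(as.numeric(lab), lab), 1)
  # forecast equal to the reference scores exactly 0
  ref <- rep(mean(lab), length(lab))
  expect_equal(brier_skill_score(ref, lab), 0)
  # 4-step hand example: BS = 0.25, BS_ref = 0.1875, BSS = -1/3
  lab4 <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(brier_skill_score(rep(0.5, 4), lab4), -1 / 3)
  expect_lte(brier_skill_score(runif(8), lab), 1)
  expect_error(brier_skill_score(rep(0, 4), rep(FALSE, 4)), "zero Brier")
})

test_that("surrogate test ranks the observed AUC against shuffled event times", {
  set.seed(14)
  n <- 800
  lab <- rep(FALSE, n); lab[sample(n, 25)] <- TRUE
  lik <- as.numeric(lab) * 0.5 + runif(n) * 0.1   # strongly informative
  st <- surrogate_test(lik, lab, n_shuffles = 200, seed = 1)
  expect_true(st$significant)
  expect_equal(st$p_value, 1 / 201)
  expect_length(st$surrogate_auc, 200)
  # reproducible under the same seed
  st2 <- surrogate_test(lik, lab, n_shuffles = 200, seed = 1)
  expect_identical(st$surrogate_auc, st2$surrogate_auc)
  # an uninformative forecast sits centrally in its own null
  st3 <- surrogate_test(runif(n), lab, n_shuffles = 200, seed = 2)
  expect_false(st3$p_value < 0.01 && st3$significant && st3$observed_auc > 0.6)
  expect_error(surrogate_test(lik, rep(TRUE, n + 1)[1:(n + 1)] , 10),
               "length|more events")
})

test_that("surrogate type-I error is near the nominal 5%", {
  set.seed(15)
  n <- 600
  lik <- runif(n)
  rejections <- vapply(1:200, function(i) {
    lab <- rep(FALSE, n); lab[sample.int(n, 12)] <- TRUE
    surrogate_test(lik, lab, n_shuffles = 100, seed = 1000 + i)$significant
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("time-of-day baseline repeats the clock-hour event profile", {
  train <- event_diary(T0 + rep(9, 8) * 3600 + (0:7) * 86400)  # all at 09:00
  grid <- T0 + 20 * 86400 + 3600 * (0:47)
  base <- time_of_day_baseline(train, grid, training_days = 8)
  expect_equal(sum(base > 0), 2)                 # hour 9 on both days
  expect_equal(max(base), 1)                     # 8 events / 8 days
  expect_equal(which(base > 0), c(10, 34))
  # uniform clock profile gives a constant baseline -> chance AUC
  train_u <- event_diary(T0 + (0:23) * 3600)
  base_u <- time_of_day_baseline(train_u, grid, training_days = 1)
  expect_equal(length(unique(base_u)), 1)
  # daily averaging of any time-of-day baseline is constant
  dd <- daily_average(list(times = grid, likelihood = base,
                           events = event_diary()))
  expect_equal(length(unique(dd$likelihood)), 1)
})

test_that("evaluate_forecast bundles the scores consistently", {
  set.seed(16)
  n <- 24 * 30
  times <- T0 + 3600 * (seq_len(n) - 1)
  ev_idx <- sample(n, 10)
  events <- event_diary(times[ev_idx] + 60)
  lik <- pmin(1, pmax(0, as.numeric(event_labels(times, events)) * 0.4 +
                        runif(n) * 0.1))
  series <- list(times = times, likelihood = lik,
                 risk = classify_risk(lik, fit_thresholds(
                   lik, event_labels(times, events))),
                 events = events)
  rep_h <- evaluate_forecast(series, n_shuffles = 100, seed = 3)
  expect_equal(rep_h$resolution, "hourly")
  expect_equal(rep_h$n_events, 10)
  expect_equal(rep_h$auc, roc_auc(lik, event_labels(times, events)))
  expect_true(rep_h$significant)
  dd <- daily_average(series)
  rep_d <- evaluate_forecast(dd, n_shuffles = 100, seed = 3)
  expect_equal(rep_d$resolution, "daily")
  expect_true(is.na(rep_d$sensitivity))
})
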