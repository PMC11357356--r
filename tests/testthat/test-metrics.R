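# Escape-sequence metrics.

trial <- trial_design()   # 45 s pre, windows (45,75) and (105,135), 10 fps

# population of k rollers and n-k crawlers, one bout each in window 1
roller_population <- function(k, n) {
  dplyr::bind_rows(
    if (k > 0) tibble::tibble(
      larva_id = sprintf("r%03d", seq_len(k)), behavior = "roll",
      start_s = 46, end_s = 48),
    if (n - k > 0) tibble::tibble(
      larva_id = sprintf("c%03d", seq_len(n - k)), behavior = "crawl",
      start_s = 45, end_s = 75))
}

test_that("binned probability reproduces the printed group percentages", {
  bp <- binned_probability(roller_population(54, 81), trial)
  expect_equal(bp$proportion * 100, 66.7, tolerance = 0.01)
  expect_equal(bp$k, 54); expect_equal(bp$n, 81)
  expect_lt(bp$conf_low, bp$proportion); expect_gt(bp$conf_high, bp$proportion)

  bp2 <- binned_probability(roller_population(26, 110), trial)
  expect_equal(bp2$proportion * 100, 23.6, tolerance = 0.05)

  bp0 <- binned_probability(roller_population(0, 100), trial)
  expect_equal(bp0$proportion, 0)
  expect_equal(bp0$conf_low, 0)
})

test_that("probability time series equals a brute-force recount with a sane CI band", {
  etho <- shared_ethogram()
  ts <- probability_timeseries(etho, "roll")
  expect_true(all(ts$proportion >= 0 & ts$proportion <= 1))
  expect_true(all(ts$conf_low <= ts$proportion + 1e-12 &
                  ts$proportion <= ts$conf_high + 1e-12))
  # independent recount at a handful of frames (times taken off the grid)
  for (tt in sort(unique(etho$t))[c(461, 504, 701, 1001)]) {
    sub <- etho[etho$t == tt, ]
    expect_equal(ts$proportion[ts$t == tt],
                 sum(sub$label == "roll") / nrow(sub))
  }
  # all larvae rolling at a frame -> proportion 1
  all_roll <- tibble::tibble(larva_id = letters[1:5], t = 0, label = "roll")
  expect_equal(probability_timeseries(all_roll, "roll")$proportion, 1)
  # CI width shrinks roughly as 1/sqrt(n)
  w10 <- diff(wilson_ci(3, 10)); w1000 <- diff(wilson_ci(300, 1000))
  expect_equal(w10 / w1000, sqrt(1000 / 10), tolerance = 0.25)
})

test_that("escape metrics read latencies off the bout list with the 30-s default", {
  # roll 2-5 s into the window, crawl from 6 s: direct read-off
  b <- tibble::tibble(larva_id = "a",
                      behavior = c("crawl", "roll", "stop", "crawl"),
                      start_s = c(45, 47, 50, 51),
                      end_s = c(47, 50, 51, 65))
  m <- escape_metrics(b, trial)
  expect_equal(m$first_roll_onset_s, 2)
  expect_equal(m$first_roll_offset_s, 5)
  expect_equal(m$first_crawl_after_roll_s, 6)
  expect_equal(m$roll_to_crawl_gap_s, 1)
  expect_equal(m$total_roll_s, 3)
  expect_true(m$is_roller && m$is_roller_5s)

  # rolled but never crawled again: the window length is the default
  b2 <- tibble::tibble(larva_id = "b", behavior = c("roll", "stop"),
                       start_s = c(47, 50), end_s = c(50, 75))
  m2 <- escape_metrics(b2, trial)
  expect_equal(m2$first_crawl_after_roll_s, 30)

  # non-roller: roll-derived fields missing
  b3 <- tibble::tibble(larva_id = "c", behavior = "crawl",
                       start_s = 45, end_s = 75)
  m3 <- escape_metrics(b3, trial)
  expect_false(m3$is_roller)
  expect_true(is.na(m3$first_roll_onset_s))
  expect_true(is.na(m3$first_crawl_after_roll_s))
  expect_equal(m3$total_roll_s, 0)
})

test_that("latency ordering holds and roll occupancy matches ground truth", {
  pop <- shared_pop()
  bouts <- shared_bouts()
  m <- escape_metrics(bouts, pop$config$trial)
  r <- m[m$is_roller, ]
  expect_true(all(r$first_roll_onset_s <= r$first_roll_offset_s))
  expect_true(all(r$first_roll_offset_s <= r$first_crawl_after_roll_s + 1e-9))
  expect_true(all(r$total_roll_s <= 30 + 1e-9))
  # detected roll occupancy matches the scripts
  w <- pop$config$trial$stim_windows[[1]]
  gt_roll <- pop$scripts |>
    dplyr::filter(behavior == "roll", end_s > w[1], start_s < w[2]) |>
    dplyr::mutate(ov = pmin(end_s, w[2]) - pmax(start_s, w[1]))
  expect_equal(sum(m$total_roll_s), sum(gt_roll$ov), tolerance = 0.05)
})

test_that("cumulative duration distribution is a proper ECDF with the gamma median", {
  cdf <- cumulative_duration_distribution(c(3, 1, 2))
  expect_equal(cdf$duration_s, c(1, 2, 3))
  expect_equal(cdf$cumulative_fraction, c(1, 2, 3) / 3)
  expect_true(all(diff(cdf$cumulative_fraction) >= 0))
  expect_equal(dplyr::last(cdf$cumulative_fraction), 1)
  expect_error(cumulative_duration_distribution(numeric(0)), "no durations")

  # sample median of a gamma(mean 1.4 s) within CI of the analytic median
  shape <- 3; mean_s <- 1.4
  withr::with_seed(101, {
    x <- rgamma(4000, shape = shape, scale = mean_s / shape)
  })
  cdf2 <- cumulative_duration_distribution(x)
  med <- cdf2$duration_s[which.max(cdf2$cumulative_fraction >= 0.5)]
  true_med <- qgamma(0.5, shape = shape, scale = mean_s / shape)
  se_med <- 1 / (2 * sqrt(length(x)) *
                   dgamma(true_med, shape, scale = mean_s / shape))
  expect_lt(abs(med - true_med), 4 * se_med)
})

test_that("speed time series matches a brute-force average, SE 0 for clones", {
  feats <- shared_features()
  sts <- speed_timeseries(feats)
  tt <- 60
  sub <- feats[feats$t == tt & !is.na(feats$speed), ]
  expect_equal(sts$mean_speed[sts$t == tt], mean(sub$speed))
  expect_equal(sts$se_speed[sts$t == tt], sd(sub$speed) / sqrt(nrow(sub)))
  # identical larvae -> zero SE
  clones <- dplyr::bind_rows(
    make_straight_track(id = "c1"), make_straight_track(id = "c2"))
  f <- compute_features(clones)
  expect_true(all(speed_timeseries(f)$se_speed < 1e-12))
})
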