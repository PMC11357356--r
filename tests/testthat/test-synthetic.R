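# The synthetic larva and GCaMP generators.

test_that("behavior scripts tile the trial exactly and tracks have the full frame count", {
  pop <- shared_pop()
  trial <- pop$config$trial
  n_frames <- round(trial$total_s * trial$frame_rate_hz)
  for (id in unique(pop$scripts$larva_id)[1:10]) {
    sc <- pop$scripts[pop$scripts$larva_id == id, ]
    expect_equal(sc$start_s[1], 0)
    expect_equal(sc$end_s[nrow(sc)], trial$total_s)
    expect_equal(sc$start_s[-1], sc$end_s[-nrow(sc)])   # no gaps, no overlap
    expect_true(all(sc$end_s > sc$start_s))
  }
  frames_per_larva <- table(pop$tracks$larva_id)
  expect_true(all(frames_per_larva == n_frames))
})

test_that("simulation is bit-reproducible for a fixed seed and stable under n", {
  cfg <- sim_config(n_larvae = 3, seed = 77)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$scripts, b$scripts)
  # per-larva streams: the first larvae are unchanged when n grows
  big <- simulate_population(sim_config(n_larvae = 5, seed = 77))
  expect_identical(a$scripts,
                   big$scripts[big$scripts$larva_id %in% a$scripts$larva_id, ])
})

test_that("degenerate probabilities behave: p_roll = 0 never rolls, n = 0 is empty", {
  pop0 <- simulate_population(sim_config(n_larvae = 15, p_roll = 0, seed = 9))
  expect_false(any(pop0$scripts$behavior == "roll"))
  empty <- simulate_population(sim_config(n_larvae = 0, seed = 1))
  expect_equal(nrow(empty$tracks), 0)
  expect_equal(nrow(empty$scripts), 0)
})

test_that("invalid simulator parameters are rejected", {
  expect_error(sim_config(p_roll = 1.5), "p_roll")
  expect_error(sim_config(roll_bout_mean_s = -1), "roll_bout_mean_s")
  expect_error(sim_config(roll_bout_mean_s = NaN), "roll_bout_mean_s")
  expect_error(sim_config(n_spine_points = 3), "n_spine_points")
})

test_that("script-level roller fraction converges to p_roll (binomial 99% CI)", {
  n <- 1000; p <- 0.6
  cfg <- sim_config(n_larvae = n, p_roll = p, seed = 5)
  w <- cfg$trial$stim_windows[[1]]
  rollers <- 0
  for (i in seq_len(n)) {
    withr::with_seed(larvaquant:::larva_seed(5, i), {
      s <- larvaquant:::generate_script(cfg)
    })
    if (any(s$behavior == "roll" & s$start_s < w[2] & s$end_s > w[1]))
      rollers <- rollers + 1
  }
  half <- 2.576 * sqrt(p * (1 - p) / n)
  expect_gt(rollers / n, p - half)
  expect_lt(rollers / n, p + half)
})

test_that("mean roll occupancy matches an independent simulation of the chain", {
  # single 30-s window, every larva rolls, long bouts
  trial <- trial_design(pre_stim_s = 5, stim_windows = list(c(5, 35)),
                        total_s = 40)
  cfg <- sim_config(n_larvae = 500, p_roll = 1, roll_bout_mean_s = 7.2,
                    trial = trial, seed = 31)
  total_roll <- numeric(cfg$n_larvae)
  for (i in seq_len(cfg$n_larvae)) {
    withr::with_seed(larvaquant:::larva_seed(31, i), {
      s <- larvaquant:::generate_script(cfg)
    })
    r <- s[s$behavior == "roll", ]
    total_roll[i] <- sum(r$end_s - r$start_s)
  }

  # oracle: plain transcription of the documented chain rules, script level
  oracle_one <- function() {
    wlen <- 30
    cur <- min(runif(1, cfg$roll_latency_range_s[1], cfg$roll_latency_range_s[2]),
               wlen - cfg$min_roll_bout_s)
    tot <- 0
    repeat {
      if (wlen - cur < cfg$min_roll_bout_s) break
      repeat {
        d <- rgamma(1, shape = cfg$roll_bout_shape,
                    scale = cfg$roll_bout_mean_s / cfg$roll_bout_shape)
        if (d >= cfg$min_roll_bout_s) break
      }
      d <- min(d, wlen - cur)
      tot <- tot + d; cur <- cur + d
      if (runif(1) >= cfg$p_rebout) break
      repeat {
        g <- rgamma(1, shape = 2, scale = cfg$inter_bout_gap_mean_s / 2)
        if (g >= 0.2) break
      }
      cur <- cur + min(g, wlen - cur)
    }
    tot
  }
  withr::with_seed(555, {
    oracle <- replicate(4000, oracle_one())
  })
  se <- sqrt(sd(oracle)^2 / length(oracle) + sd(total_roll)^2 / length(total_roll))
  expect_lt(abs(mean(total_roll) - mean(oracle)), 4 * se + 0.15)  # + grid snap
})

test_that("crawl during stimulation runs at the configured speed multiplier", {
  pop <- shared_pop()
  feats <- shared_features()
  sc <- pop$scripts[pop$scripts$behavior == "crawl", ]
  state_means <- purrr::pmap_dbl(
    list(sc$larva_id, sc$start_s, sc$end_s), function(id, s, e) {
      f <- feats[feats$larva_id == id & feats$t >= s + 0.5 & feats$t < e - 0.5, ]
      if (nrow(f) == 0) NA_real_ else mean(f$speed)
    })
  stim <- in_stimulation(sc$start_s, pop$config$trial)
  ratio <- mean(state_means[stim], na.rm = TRUE) /
    mean(state_means[!stim], na.rm = TRUE)
  expect_equal(ratio, pop$config$stim_crawl_multiplier, tolerance = 0.05)
})

test_that("rendered behaviors satisfy their kinematic definitions", {
  cfg <- sim_config(noise_sd_mm = 0)
  # roll: centroid displacement orthogonal to the tail->head chord
  roll <- render_behavior("roll", 3, cfg, seed = 2)
  sp <- larvaquant:::spine_matrices(roll)
  cx <- rowMeans(sp$x); cy <- rowMeans(sp$y)
  vx <- diff(cx); vy <- diff(cy)
  ax <- (sp$x[, 11] - sp$x[, 1])[-1]; ay <- (sp$y[, 11] - sp$y[, 1])[-1]
  an <- sqrt(ax^2 + ay^2); vn <- sqrt(vx^2 + vy^2)
  perp_frac <- abs(vx * ay - vy * ax) / (an * vn)
  expect_true(all(perp_frac >= 0.8))
  # stop with zero noise: identical spine across frames
  stop_fr <- render_behavior("stop", 1, cfg, seed = 3)
  expect_true(all(apply(stop_fr[-(1:2)], 2, function(col) diff(range(col)) == 0)))
  # hunch: body contracts by >= 15%
  hunch <- render_behavior("hunch", 1, cfg, seed = 4)
  hs <- larvaquant:::spine_matrices(hunch)
  lens <- colSums(sqrt(diff(t(hs$x))^2 + diff(t(hs$y))^2))
  expect_lte(min(lens), 0.85 * lens[1])
  expect_error(render_behavior("moonwalk", 1, cfg), "unknown behavior")
})

test_that("GCaMP ground truth is exact: null response, kernel peak, linear dose", {
  null_cfg <- gcamp_config(amplitude_slope = 0, noise_sd = 0, irradiances = 0.5)
  sim0 <- simulate_gcamp(null_cfg)
  expect_true(all(abs(sim0$traces[[1]]$data$f - null_cfg$baseline_f) < 1e-12))
  expect_equal(sim0$truth$peak_dff, 0)

  # closed-form maximum of the double exponential lands at peak_delay_s
  cfg <- gcamp_config(noise_sd = 0, irradiances = 1)
  kfun <- function(s) larvaquant:::gcamp_kernel(s, cfg$rise_tau_s,
                                                cfg$decay_tau_s, cfg$peak_delay_s)
  opt <- optimize(kfun, c(0, 10), maximum = TRUE)
  expect_equal(opt$maximum, cfg$peak_delay_s, tolerance = 1e-4)
  expect_equal(opt$objective, 1, tolerance = 1e-9)
  single <- gcamp_config(noise_sd = 0, irradiances = 1, n_trials = 1)
  sim1 <- simulate_gcamp(single)
  expect_equal(max(sim1$traces[[1]]$data$f),
               single$baseline_f * (1 + single$amplitude_slope),
               tolerance = 1e-6)

  # truth peaks exactly linear in irradiance
  sim <- simulate_gcamp(gcamp_config(noise_sd = 0))
  expect_equal(sim$truth$peak_dff,
               sim$config$amplitude_slope * sim$config$irradiances)

  expect_error(gcamp_config(rise_tau_s = 5, decay_tau_s = 2), "rise_tau")
  a <- simulate_gcamp(gcamp_config(seed = 8))
  b <- simulate_gcamp(gcamp_config(seed = 8))
  expect_identical(a$traces[["1.4"]]$data, b$traces[["1.4"]]$data)
})
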