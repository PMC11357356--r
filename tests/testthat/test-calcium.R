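# Stimulation-locked dF/F analysis.

test_that("downsampling is block averaging with onsets preserved", {
  tt <- (0:299) / 30
  const <- calcium_trace(tt, rep(5, 300), 5, native_rate_hz = 30)
  d <- downsample_trace(const, 6)
  expect_true(all(d$data$f == 5))
  expect_equal(nrow(d$data), ceiling(300 / 5))
  expect_equal(d$stim_onsets, 5)
  expect_equal(d$native_rate_hz, 6)

  withr::with_seed(3, {
    f <- runif(300, 10, 20)
  })
  tr <- calcium_trace(tt, f, 5, native_rate_hz = 30)
  d2 <- downsample_trace(tr, 6)
  hand <- colMeans(matrix(f, nrow = 5))
  expect_equal(d2$data$f, hand, tolerance = 1e-12)
  expect_error(downsample_trace(d2, 30), "exceeds")
})

test_that("dF/F self-normalizes: constant trace, clean step, gain invariance", {
  rate <- 6
  tt <- (seq_len(40 * rate) - 0.5) / rate
  onset <- 20
  # constant fluorescence: dF/F identically zero
  c0 <- calcium_trace(tt, rep(80, length(tt)), onset, native_rate_hz = rate)
  d0 <- compute_dff(c0)
  expect_true(all(abs(d0$mean$dff) < 1e-12))
  # f doubles at onset: post-onset bins all 1.0
  f <- ifelse(tt < onset, 100, 200)
  d1 <- compute_dff(calcium_trace(tt, f, onset, native_rate_hz = rate))
  post <- d1$mean$dff[d1$mean$t_rel_s > 0.5]
  pre <- d1$mean$dff[d1$mean$t_rel_s < -0.5]
  expect_true(all(abs(post - 1) < 1e-12))
  expect_true(all(abs(pre) < 1e-12))
  # multiplicative gain leaves dF/F unchanged
  d2 <- compute_dff(calcium_trace(tt, 3.7 * f, onset, native_rate_hz = rate))
  expect_equal(d2$mean$dff, d1$mean$dff, tolerance = 1e-12)
})

test_that("noiseless synthetic kernel reproduces the bin-averaged analytic kernel", {
  cfg <- gcamp_config(noise_sd = 0, n_trials = 1, irradiances = 1.4)
  sim <- simulate_gcamp(cfg)
  got <- compute_dff(downsample_trace(sim$traces[[1]]))

  # oracle: closed-form kernel at the native 30-fps sample times, averaged
  # through the same 30->6 fps and 5-frame binning topology
  t30 <- seq(0, cfg$lead_in_s + cfg$inter_trial_s, by = 1 / 30)
  onset <- cfg$lead_in_s
  k <- larvaquant:::gcamp_kernel(t30 - onset, cfg$rise_tau_s, cfg$decay_tau_s,
                                 cfg$peak_delay_s)
  f30 <- cfg$baseline_f * (1 + cfg$amplitude_slope * 1.4 * k)
  n6 <- floor(length(f30) / 5)
  f6 <- colMeans(matrix(f30[seq_len(n6 * 5)], nrow = 5))
  t6 <- (seq_len(n6) - 0.5) / 6
  i_on <- which(t6 >= onset)[1]
  f0 <- mean(f6[(i_on - 10):(i_on - 1)])
  i_s <- which(t6 >= onset - 5)[1]
  fb <- colMeans(matrix(f6[i_s:(i_s + 24 * 5 - 1)], nrow = 5))
  oracle <- (fb - f0) / f0
  expect_lt(max(abs(got$trials$dff - oracle)), 1e-9)
})

test_that("the peak search finds the right bin", {
  rate <- 6
  tt <- (seq_len(40 * rate) - 0.5) / rate
  onset <- 20
  # monotone decay from onset: peak at the first post-onset bin
  f <- ifelse(tt < onset, 100, 100 + 50 * exp(-(tt - onset)))
  d <- compute_dff(calcium_trace(tt, f, onset, native_rate_hz = rate))
  pk <- peak_dff(d)
  first_bin <- min(d$mean$t_rel_s[d$mean$t_rel_s >= 0])
  expect_equal(pk$peak_time_s, first_bin)
  # all-zero dff: peak 0
  dz <- compute_dff(calcium_trace(tt, rep(7, length(tt)), onset,
                                  native_rate_hz = rate))
  expect_equal(peak_dff(dz)$peak_dff, 0)
  # simulated peak delay recovered within one bin (5/6 s)
  sim <- simulate_gcamp(gcamp_config(noise_sd = 0, irradiances = 1))
  pk2 <- peak_dff(compute_dff(downsample_trace(sim$traces[[1]])))
  expect_lt(abs(pk2$peak_time_s - 3), 5 / 6)
})

test_that("dropped trials are reported, never imputed", {
  rate <- 6
  tt <- (seq_len(40 * rate) - 0.5) / rate
  # second onset too close to the trace end
  expect_warning(
    d <- compute_dff(calcium_trace(tt, rep(10, length(tt)), c(20, 39),
                                   native_rate_hz = rate)),
    "insufficient")
  expect_equal(unique(d$trials$trial), 1)
  # onset with too few preceding frames
  expect_warning(
    expect_error(
      compute_dff(calcium_trace(tt, rep(10, length(tt)), 0.5,
                                native_rate_hz = rate)),
      "no usable trials"),
    "pre-onset")
})

test_that("trial averaging shrinks peak noise by about 1/sqrt(3)", {
  pk1 <- numeric(40); pk3 <- numeric(40)
  for (r in 1:40) {
    sim <- simulate_gcamp(gcamp_config(irradiances = 0.5, noise_sd = 3,
                                       seed = 1000 + r))
    d <- compute_dff(downsample_trace(sim$traces[[1]]))
    pk3[r] <- peak_dff(d)$peak_dff
    t1 <- d$trials[d$trials$trial == 1, ]
    pk1[r] <- max(t1$dff[t1$t_rel_s >= 0 & t1$t_rel_s <= 15])
  }
  ratio <- sd(pk3) / sd(pk1)
  expect_gt(ratio, 1 / sqrt(3) - 0.2)
  expect_lt(ratio, 1 / sqrt(3) + 0.2)
})

test_that("dose-response fits recover slope and fit quality", {
  # exactly linear peaks: R^2 = 1 and slope = the generating slope
  peaks <- tibble::tibble(irradiance = c(0.04, 0.1, 0.3, 0.5, 1.4),
                          peak_dff = 0.9 * c(0.04, 0.1, 0.3, 0.5, 1.4))
  fit <- dose_response(peaks)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.9, tolerance = 1e-12)
  expect_equal(glance(fit)$r.squared, 1)
  expect_equal(nrow(suppressWarnings(tidy(fit))), 2)
  # constant peaks: slope 0
  flat <- tibble::tibble(irradiance = c(0.1, 0.5, 1.4), peak_dff = 0.2)
  expect_equal(dose_response(flat)$slope, 0)
  expect_error(dose_response(peaks[1:2, ]), "3 distinct")
})
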