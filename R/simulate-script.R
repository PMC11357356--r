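# Ground-truth behavior scripts: a stimulus-gated semi-Markov chain.
#
# Outside stimulation larvae alternate crawl with brief turn/stop/hunch
# episodes; at each stimulation onset a larva rolls with probability p_roll.
# A roller crawls for a short uniform latency, then emits roll bouts with
# gamma durations (truncated below at min_roll_bout_s); after each bout it
# starts another with probability p_rebout, separated by a gamma crawl gap,
# otherwise it crawls fast for the rest of the window. All state boundaries
# are snapped to the frame grid so scripts tile the trial exactly.

# Draw a gamma variate (mean/shape parameterization) resampled above a floor.
rgamma_floor <- function(n, mean, shape, floor = 0) {
  scale <- mean / shape
  x <- rgamma(n, shape = shape, scale = scale)
  bad <- x < floor
  while (any(bad)) {
    x[bad] <- rgamma(sum(bad), shape = shape, scale = scale)
    bad <- x < floor
  }
  x
}

# Baseline chain over [a, b): crawl dwells interleaved with interruptions.
baseline_states <- function(a, b, cfg) {
  beh <- character(0); s <- numeric(0); e <- numeric(0)
  cur <- a
  while (cur < b) {
    d <- min(rgamma_floor(1, cfg$baseline_dwell_mean_s, 3), b - cur)
    beh <- c(beh, "crawl"); s <- c(s, cur); e <- c(e, cur + d)
    cur <- cur + d
    if (cur >= b) break
    kind <- sample(c("turn", "stop", "hunch"), 1, prob = c(0.5, 0.35, 0.15))
    d <- switch(kind,
      turn = rgamma_floor(1, 1, 2, floor = 0.4),
      stop = rgamma_floor(1, 1.5, 2, floor = 0.3),
      hunch = 0.6)
    d <- min(d, b - cur)
    beh <- c(beh, kind); s <- c(s, cur); e <- c(e, cur + d)
    cur <- cur + d
  }
  list(behavior = beh, start = s, end = e)
}

# Roller program over one stimulation window [a, b).
roller_states <- function(a, b, cfg) {
  beh <- character(0); s <- numeric(0); e <- numeric(0)
  lat <- runif(1, cfg$roll_latency_range_s[1], cfg$roll_latency_range_s[2])
  lat <- min(lat, b - a - cfg$min_roll_bout_s)  # first bout must fit
  if (lat > 0) { beh <- "crawl"; s <- a; e <- a + lat }
  cur <- a + max(lat, 0)
  rolling <- TRUE
  while (rolling && (b - cur) >= cfg$min_roll_bout_s) {
    d <- rgamma_floor(1, cfg$roll_bout_mean_s, cfg$roll_bout_shape,
                      floor = cfg$min_roll_bout_s)
    d <- min(d, b - cur)
    beh <- c(beh, "roll"); s <- c(s, cur); e <- c(e, cur + d)
    cur <- cur + d
    if (!cfg$inter_bout_crawl || runif(1) >= cfg$p_rebout) {
      rolling <- FALSE
    } else {
      g <- min(rgamma_floor(1, cfg$inter_bout_gap_mean_s, 2, floor = 0.2), b - cur)
      if (g > 0) { beh <- c(beh, "crawl"); s <- c(s, cur); e <- c(e, cur + g) }
      cur <- cur + g
    }
  }
  if (cur < b) { beh <- c(beh, "crawl"); s <- c(s, cur); e <- c(e, b) }
  list(behavior = beh, start = s, end = e)
}

# One larva's full script; boundaries snapped to the frame grid.
generate_script <- function(cfg) {
  tr <- cfg$trial
  dt <- 1 / tr$frame_rate_hz
  segs <- list()
  cur <- 0
  windows <- tr$stim_windows
  rolls <- if (length(windows)) runif(length(windows)) < cfg$p_roll else logical(0)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (w[1] > cur) segs <- c(segs, list(baseline_states(cur, w[1], cfg)))
    segs <- c(segs, list(
      if (rolls[i]) roller_states(w[1], w[2], cfg) else baseline_states(w[1], w[2], cfg)
    ))
    cur <- w[2]
  }
  if (cur < tr$total_s) segs <- c(segs, list(baseline_states(cur, tr$total_s, cfg)))

  beh <- unlist(lapply(segs, `[[`, "behavior"))
  start <- unlist(lapply(segs, `[[`, "start"))
  end <- unlist(lapply(segs, `[[`, "end"))

  # snap to frame grid; drop empties; merge adjacent identical behaviors
  fs <- round(start / dt); fe <- round(end / dt)
  fe[length(fe)] <- round(tr$total_s / dt)
  keep <- fe > fs
  beh <- beh[keep]; fs <- fs[keep]; fe <- fe[keep]
  # guard: a roll clipped under the floor by snapping becomes crawl
  beh[beh == "roll" & (fe - fs) * dt < cfg$min_roll_bout_s] <- "crawl"
  if (length(beh) > 1) {
    same <- c(FALSE, beh[-1] == beh[-length(beh)] & fs[-1] == fe[-length(fe)])
    grp <- cumsum(!same)
    fs <- tapply(fs, grp, min); fe <- tapply(fe, grp, max)
    beh <- beh[!same]
  }
  tibble::tibble(behavior = beh, start_s = as.numeric(fs) * dt,
                 end_s = as.numeric(fe) * dt)
}
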