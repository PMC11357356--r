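# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A mid-sized default-noise population reused across feature/classifier/
# metric tests.
shared_pop <- function() {
  if (is.null(.fixture_env$pop)) {
    .fixture_env$pop <- simulate_population(
      sim_config(n_larvae = 40, p_roll = 0.6, seed = 4242))
  }
  .fixture_env$pop
}

shared_features <- function() {
  if (is.null(.fixture_env$feats)) {
    .fixture_env$feats <- compute_features(shared_pop()$tracks)
  }
  .fixture_env$feats
}

shared_ethogram <- function() {
  if (is.null(.fixture_env$etho)) {
    .fixture_env$etho <- classify_frames(shared_features())
  }
  .fixture_env$etho
}

shared_bouts <- function() {
  if (is.null(.fixture_env$bouts)) {
    .fixture_env$bouts <- segment_bouts(shared_ethogram())
  }
  .fixture_env$bouts
}

# Straight-spine track builder: heading and velocity in mm and mm/s, frames
# at `fr` Hz. Spine length `len`, `n` points, tail first.
make_straight_track <- function(n_frames = 50, v = c(1, 0), heading = c(1, 0),
                                len = 4, n = 11, fr = 10, start = c(0, 0),
                                id = "L1") {
  dt <- 1 / fr
  tt <- (seq_len(n_frames) - 1) * dt
  h <- heading / sqrt(sum(heading^2))
  frac <- seq(-0.5, 0.5, length.out = n)
  rows <- lapply(seq_len(n_frames), function(i) {
    c0 <- start + v * tt[i]
    px <- c0[1] + frac * len * h[1]
    py <- c0[2] + frac * len * h[2]
    c(rbind(px, py))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0(rep(c("x", "y"), n), rep(seq_len(n), each = 2))
  tibble::as_tibble(m) |>
    tibble::add_column(t = tt, .before = 1) |>
    tibble::add_column(larva_id = id, .before = 1)
}

# Ethogram builder from a run-length description, 10 fps.
make_ethogram <- function(labels, reps, id = "L1", fr = 10) {
  lab <- rep(labels, reps)
  tibble::tibble(larva_id = id, t = (seq_along(lab) - 1) / fr, label = lab)
}
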