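# Spine-frame rendering for the synthetic larva.
#
# Each behavior is rendered with kinematics chosen to satisfy its operational
# definition: crawl translates a straight spine along its own axis with a
# peristaltic length oscillation; roll holds a C-shaped (semicircular) spine
# that rotates while translating perpendicular to its tail->head chord; turn
# deflects the head quarter with slow forward translation; hunch contracts
# body length by >= 15% in place; stop is stationary; backup reverses crawl.

unit_vec <- function(theta) cbind(cos(theta), sin(theta))

# Straight spine rows: centroid pos (k x 2), heading theta (k), length L (k).
straight_spine <- function(pos, theta, L, n) {
  frac <- seq(-0.5, 0.5, length.out = n)
  u <- unit_vec(theta)
  x <- pos[, 1] + outer(L, frac) * u[, 1]
  y <- pos[, 2] + outer(L, frac) * u[, 2]
  list(x = x, y = y)
}

# C-shaped (semicircular) spine with chord orientation psi (k), centered on
# its own centroid at pos. Returns spine plus the chord direction.
c_spine <- function(pos, psi, L, n) {
  phi <- seq(0, pi, length.out = n)   # arc parameter, tail -> head
  R <- L / pi
  # base arc in local coords, tail at angle 0
  bx <- outer(R, cos(phi)); by <- outer(R, sin(phi))
  bx <- bx - rowMeans(bx); by <- by - rowMeans(by)
  # chord (tail->head) of the base arc points along -x; rotate so chord = psi
  rot <- psi - pi
  cr <- cos(rot); sr <- sin(rot)
  x <- pos[, 1] + bx * cr - by * sr
  y <- pos[, 2] + bx * sr + by * cr
  list(x = x, y = y)
}

# Render one state occupying frame times tt (absolute, length k >= 1).
# `pose` carries pos (length-2), heading (rad). Returns spine block + pose.
render_state <- function(behavior, tt, pose, speed_mm_s, cfg) {
  k <- length(tt)
  n <- cfg$n_spine_points
  L0 <- cfg$body_length_mm
  dt <- 1 / cfg$trial$frame_rate_hz
  peristalsis <- 1 + 0.04 * sin(2 * pi * 1.5 * tt)

  if (behavior %in% c("crawl", "backup")) {
    sgn <- if (behavior == "backup") -1 else 1
    jit <- rnorm(k, 0, 2 * pi / 180)            # heading random walk, 2 deg/frame
    theta <- pose$heading + cumsum(jit)
    step <- sgn * speed_mm_s * dt
    px <- pose$pos[1] + cumsum(step * cos(theta))
    py <- pose$pos[2] + cumsum(step * sin(theta))
    sp <- straight_spine(cbind(px, py), theta, L0 * peristalsis, n)
    pose <- list(pos = c(px[k], py[k]), heading = theta[k])
  } else if (behavior == "roll") {
    omega <- cfg$roll_omega_deg_s * pi / 180
    side <- sample(c(-1, 1), 1)
    psi <- pose$heading + omega * side * (seq_len(k) - 1) * dt
    perp <- psi + pi / 2 * side
    step <- cfg$roll_speed * dt
    px <- pose$pos[1] + cumsum(step * cos(perp))
    py <- pose$pos[2] + cumsum(step * sin(perp))
    sp <- c_spine(cbind(px, py), psi, rep(L0, k), n)
    pose <- list(pos = c(px[k], py[k]), heading = psi[k])
  } else if (behavior == "turn") {
    side <- sample(c(-1, 1), 1)
    # head deflection ramps up over 0.2 s, holds at 60 deg, ramps down
    rel <- tt - tt[1]; Tt <- (k - 1) * dt
    amp <- 60 * pi / 180
    alpha <- amp * pmin(1, rel / 0.2, pmax(0, (Tt - rel) / 0.2)) * side
    theta <- rep(pose$heading, k)
    step <- 0.2 * dt                             # slow forward creep
    px <- pose$pos[1] + cumsum(step * cos(theta))
    py <- pose$pos[2] + cumsum(step * sin(theta))
    sp <- straight_spine(cbind(px, py), theta, L0 * peristalsis * 0 + L0, n)
    # re-bend the head quarter about the 3/4 point
    pivot <- ceiling(3 * (n - 1) / 4) + 1
    for (j in seq(pivot + 1, n)) {
      dx <- sp$x[, j] - sp$x[, pivot]; dy <- sp$y[, j] - sp$y[, pivot]
      ca <- cos(alpha); sa <- sin(alpha)
      sp$x[, j] <- sp$x[, pivot] + dx * ca - dy * sa
      sp$y[, j] <- sp$y[, pivot] + dx * sa + dy * ca
    }
    pose <- list(pos = c(px[k], py[k]),
                 heading = pose$heading + side * 30 * pi / 180 * min(1, Tt / 1))
  } else if (behavior == "hunch") {
    rel <- (tt - tt[1]) / max((k - 1) * dt, dt)
    Lh <- L0 * (1 - 0.2 * sin(pi * pmin(pmax(rel, 0), 1)))
    pos <- cbind(rep(pose$pos[1], k), rep(pose$pos[2], k))
    sp <- straight_spine(pos, rep(pose$heading, k), Lh, n)
  } else {                                        # stop / unknown
    pos <- cbind(rep(pose$pos[1], k), rep(pose$pos[2], k))
    sp <- straight_spine(pos, rep(pose$heading, k), rep(L0, k), n)
  }
  list(spine = sp, pose = pose)
}

#' Render one behavior episode as spine frames
#'
#' Low-level access to the simulator's kinematic repertoire: renders a single
#' behavior of a given duration from a standard start pose. Mainly useful for
#' inspecting or testing the per-behavior kinematics; [simulate_population()]
#' renders full trials.
#'
#' @param behavior One of `"roll"`, `"crawl"`, `"turn"`, `"hunch"`, `"stop"`,
#'   `"backup"`.
#' @param duration_s Episode duration, seconds.
#' @param config A [sim_config()].
#' @param seed Seed for the episode's random draws.
#' @return A tibble with columns `t`, `x1`, `y1`, ..., one row per frame.
#' @examples
#' render_behavior("roll", 2, sim_config(), seed = 1)
#' @export
render_behavior <- function(behavior, duration_s, config, seed = 1L) {
  if (!behavior %in% setdiff(BEHAVIORS, "unknown"))
    abort(paste0("unknown behavior: ", behavior))
  dt <- 1 / config$trial$frame_rate_hz
  k <- max(1L, round(duration_s / dt))
  tt <- seq(0, by = dt, length.out = k)
  withr::with_seed(seed, {
    st <- render_state(behavior, tt, list(pos = c(0, 0), heading = 0),
                       config$baseline_crawl_speed, config)
    x <- st$spine$x; y <- st$spine$y
    if (config$noise_sd_mm > 0) {
      x <- x + rnorm(length(x), 0, config$noise_sd_mm)
      y <- y + rnorm(length(y), 0, config$noise_sd_mm)
    }
    spine_block_to_tibble(tt, x, y)
  })
}

spine_block_to_tibble <- function(tt, x, y, larva_id = NULL) {
  n <- ncol(x)
  m <- matrix(0, nrow(x), 2 * n)
  m[, seq(1, 2 * n, 2)] <- x
  m[, seq(2, 2 * n, 2)] <- y
  colnames(m) <- paste0(rep(c("x", "y"), n), rep(seq_len(n), each = 2))
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, t = tt, .before = 1)
  if (!is.null(larva_id)) out <- tibble::add_column(out, larva_id = larva_id, .before = 1)
  out
}

# Render a full script for one larva (rng already seeded).
render_script <- function(script, cfg) {
  tr <- cfg$trial
  dt <- 1 / tr$frame_rate_hz
  n_frames <- round(tr$total_s * tr$frame_rate_hz)
  n <- cfg$n_spine_points
  X <- matrix(0, n_frames, n); Y <- matrix(0, n_frames, n)
  pose <- list(pos = c(runif(1, 0, 50), runif(1, 0, 50)),
               heading = runif(1, 0, 2 * pi))
  for (i in seq_len(nrow(script))) {
    f0 <- round(script$start_s[i] / dt) + 1
    f1 <- round(script$end_s[i] / dt)
    if (f1 < f0) next
    tt <- (seq(f0, f1) - 1) * dt
    v <- cfg$baseline_crawl_speed *
      ifelse(in_stimulation(tt[1], tr), cfg$stim_crawl_multiplier, 1)
    st <- render_state(script$behavior[i], tt, pose, v, cfg)
    X[f0:f1, ] <- st$spine$x; Y[f0:f1, ] <- st$spine$y
    pose <- st$pose %||% list(pos = c(st$spine$x[length(tt), (n + 1) %/% 2],
                                      st$spine$y[length(tt), (n + 1) %/% 2]),
                              heading = pose$heading)
  }
  if (cfg$noise_sd_mm > 0) {
    X <- X + rnorm(length(X), 0, cfg$noise_sd_mm)
    Y <- Y + rnorm(length(Y), 0, cfg$noise_sd_mm)
  }
  list(t = (seq_len(n_frames) - 1) * dt, x = X, y = Y)
}

#' Simulate a tracked larval population
#'
#' Draws one behavior script per larva from the stimulus-gated semi-Markov
#' chain and renders it as a spine track at the trial frame rate. Each larva
#' uses its own random stream derived from `config$seed`, so the population
#' is reproducible and stable under reordering.
#'
#' @param config A [sim_config()].
#' @return A list with components:
#'   * `tracks`: tibble of spine frames (`larva_id`, `t`, `x1`, `y1`, ...);
#'   * `scripts`: tibble of ground-truth states
#'     (`larva_id`, `behavior`, `start_s`, `end_s`);
#'   * `config`: the generating configuration.
#' @examples
#' pop <- simulate_population(sim_config(n_larvae = 3, seed = 42))
#' dplyr::count(pop$scripts, behavior)
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config")
  n <- config$n_larvae
  if (n == 0)
    return(list(tracks = spine_block_to_tibble(numeric(0),
                  matrix(0, 0, config$n_spine_points),
                  matrix(0, 0, config$n_spine_points), character(0)),
                scripts = tibble::tibble(larva_id = character(0),
                  behavior = character(0), start_s = numeric(0),
                  end_s = numeric(0)),
                config = config))
  ids <- sprintf("larva_%04d", seq_len(n))
  tracks <- vector("list", n); scripts <- vector("list", n)
  for (i in seq_len(n)) {
    withr::with_seed(larva_seed(config$seed, i), {
      sc <- generate_script(config)
      fr <- render_script(sc, config)
    })
    scripts[[i]] <- tibble::add_column(sc, larva_id = ids[i], .before = 1)
    tracks[[i]] <- spine_block_to_tibble(fr$t, fr$x, fr$y, ids[i])
  }
  list(tracks = dplyr::bind_rows(tracks), scripts = dplyr::bind_rows(scripts),
       config = config)
}

#' Ground-truth ethogram from behavior scripts
#'
#' Expands script states to per-frame labels on the trial's frame grid, for
#' scoring classifier output against ground truth.
#'
#' @param scripts Script tibble from [simulate_population()].
#' @param trial A [trial_design()].
#' @return Tibble `larva_id`, `t`, `truth`.
#' @export
script_ethogram <- function(scripts, trial) {
  dt <- 1 / trial$frame_rate_hz
  scripts %>%
    mutate(n_frames = round((.data$end_s - .data$start_s) / dt)) %>%
    group_by(.data$larva_id) %>%
    reframe(t = (round(first(.data$start_s) / dt) +
                   seq_len(sum(.data$n_frames)) - 1) * dt,
            truth = rep(.data$behavior, .data$n_frames))
}
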