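# Choreography-style per-frame kinematics from spine tracks.

# Centered moving average with window shrinking at the edges.
smooth_ma <- function(x, w) {
  if (w <= 1 || length(x) < 3) return(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - half, 1); hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Central-difference derivative; one-sided at the endpoints.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n == 1) return(0)
  d <- numeric(n)
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

angle_between_deg <- function(ax, ay, bx, by) {
  dot <- ax * bx + ay * by
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  ok <- na > 0 & nb > 0
  out <- rep(NA_real_, length(ax))
  cth <- pmin(pmax(dot[ok] / (na[ok] * nb[ok]), -1), 1)
  out[ok] <- acos(cth) * 180 / pi
  out
}

spine_matrices <- function(df) {
  nms <- names(df)
  xs <- sort(nms[grepl("^x\\d+$", nms)])
  n <- length(xs)
  idx <- order(as.integer(sub("x", "", xs)))
  xcols <- paste0("x", seq_len(n)); ycols <- paste0("y", seq_len(n))
  list(x = as.matrix(df[xcols]), y = as.matrix(df[ycols]), n = n)
}

features_one <- function(df, smooth_w, bias_w, dt, stop_speed_max, width_mm) {
  sp <- spine_matrices(df)
  X <- sp$x; Y <- sp$y; n <- sp$n
  k <- nrow(X)
  cx <- rowMeans(X); cy <- rowMeans(Y)
  scx <- smooth_ma(cx, smooth_w); scy <- smooth_ma(cy, smooth_w)
  vx <- central_diff(scx, dt); vy <- central_diff(scy, dt)
  speed <- sqrt(vx^2 + vy^2)

  axx <- X[, n] - X[, 1]; axy <- Y[, n] - Y[, 1]          # tail -> head chord
  an <- sqrt(axx^2 + axy^2)
  degenerate <- an < 1e-9
  ux <- ifelse(degenerate, NA_real_, axx / an)
  uy <- ifelse(degenerate, NA_real_, axy / an)
  proj <- vx * ux + vy * uy                                # forward velocity
  crab <- pmin(abs(vx * uy - vy * ux), speed)              # perpendicular comp.

  mid <- (n + 1) %/% 2
  curvature <- angle_between_deg(X[, mid] - X[, 1], Y[, mid] - Y[, 1],
                                 X[, n] - X[, mid], Y[, n] - Y[, mid])
  hq <- n - floor((n - 1) / 4)                             # head-quarter base
  head_angle <- angle_between_deg(X[, n] - X[, hq], Y[, n] - Y[, hq], ux, uy)

  seglen <- sqrt(diff(t(X))^2 + diff(t(Y))^2)              # (n-1) x k
  len <- colSums(seglen)

  moving <- speed > stop_speed_max & !is.na(proj)
  fwd <- as.numeric(moving & proj > 0); bwd <- as.numeric(moving & proj < 0)
  wsum <- function(z) {
    cs <- cumsum(c(0, z)); i <- seq_along(z); half <- bias_w %/% 2
    lo <- pmax(i - half, 1); hi <- pmin(i + half, length(z))
    cs[hi + 1] - cs[lo]
  }
  nf <- wsum(fwd); nb <- wsum(bwd)
  bias <- ifelse(nf + nb > 0, (nf - nb) / (nf + nb), 0)

  out <- tibble::tibble(
    t = df$t, speed = speed, crabspeed = crab, curvature = curvature,
    head_angle = head_angle, length = len, width = width_mm,
    area = len * width_mm, bias = bias, cx = cx, cy = cy,
    forward_speed = proj, degenerate = degenerate)
  if (any(degenerate)) {
    out[degenerate, c("speed", "crabspeed", "curvature", "head_angle",
                      "bias", "forward_speed")] <- NA_real_
  }
  out
}

#' Compute per-frame kinematic features from spine tracks
#'
#' For every larva and frame, computes the Choreography-style parameter set:
#' centroid `speed` (mm/s, from a smoothed centroid), `crabspeed` (the
#' component of centroid velocity perpendicular to the tail->head body axis,
#' mm/s), body `curvature` (degrees; the angle between the tail->midpoint and
#' midpoint->head chords, 0 for a straight body, 90 for a semicircular
#' C-shape), `head_angle` (degrees between the head-quarter segment and the
#' body axis), body `length` (spine arclength, mm), `width`/`area` (from the
#' configured width; no contours are used), and `bias` (fractional excess of
#' time moving forward within a sliding window, in [-1, 1]).
#'
#' Smoothing is a centered moving average of the centroid (default 0.3 s);
#' time derivatives are central differences, one-sided at track endpoints.
#' Frames with a degenerate spine (all points coincident) are flagged and
#' their motion features set to missing.
#'
#' @param tracks Spine-track tibble (`larva_id`, `t`, `x1`, `y1`, ...), as
#'   produced by [simulate_population()] or [read_spine_table()].
#' @param smooth_window_s Centroid smoothing window, seconds.
#' @param bias_window_s Sliding window for `bias`, seconds.
#' @param stop_speed_max Speed threshold (mm/s) below which frames are
#'   excluded from `bias`.
#' @param width_mm Assumed body width (mm) when no contour is available.
#' @return A tibble with one row per (`larva_id`, `t`).
#' @examples
#' pop <- simulate_population(sim_config(n_larvae = 2, seed = 1))
#' feats <- compute_features(pop$tracks)
#' head(feats)
#' @export
compute_features <- function(tracks, smooth_window_s = 0.3, bias_window_s = 1,
                             stop_speed_max = 0.1, width_mm = 0.6) {
  if (!all(c("larva_id", "t") %in% names(tracks)))
    abort("tracks must have larva_id and t columns")
  if (nrow(tracks) == 0) abort("tracks is empty")
  split_tracks <- split(tracks, factor(tracks$larva_id, unique(tracks$larva_id)))
  out <- purrr::map(split_tracks, function(df) {
    if (nrow(df) < 3) abort("each track needs at least 3 frames")
    dt <- median(diff(df$t))
    smooth_w <- max(1L, 2L * (round(smooth_window_s / dt) %/% 2L) + 1L)
    bias_w <- max(1L, 2L * (round(bias_window_s / dt) %/% 2L) + 1L)
    tibble::add_column(
      features_one(df, smooth_w, bias_w, dt, stop_speed_max, width_mm),
      larva_id = df$larva_id[1], .before = 1)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "feature_meta") <- list(
    smoothing = "centered moving average of centroid",
    smooth_window_s = smooth_window_s, bias_window_s = bias_window_s,
    derivative = "central difference, one-sided endpoints",
    curvature = "three-chord angle tail-mid-head",
    body_length_filter = "max excursion of smoothed centroid vs median length")
  res
}

#' Reject short or stationary tracks
#'
#' Applies the standard track-quality filter: a track is kept only if it was
#' followed for at least `min_duration_s` seconds AND its centroid moved at
#' least one body length (maximum excursion of the smoothed centroid from its
#' starting point, against the track's median spine length — the median makes
#' the body-length yardstick robust to hunches).
#'
#' @param tracks Spine-track tibble.
#' @param min_duration_s Minimum tracked duration, seconds.
#' @param min_body_lengths Required excursion in units of median body length.
#' @param smooth_window_s Centroid smoothing window, seconds.
#' @return The retained rows of `tracks`, original order preserved, with a
#'   `"rejections"` attribute tabulating per-larva decisions.
#' @examples
#' pop <- simulate_population(sim_config(n_larvae = 3, seed = 7))
#' kept <- filter_tracks(pop$tracks)
#' attr(kept, "rejections")
#' @export
filter_tracks <- function(tracks, min_duration_s = 5, min_body_lengths = 1,
                          smooth_window_s = 0.3) {
  if (nrow(tracks) == 0) return(tracks)
  ids <- unique(tracks$larva_id)
  log <- purrr::map(ids, function(id) {
    df <- tracks[tracks$larva_id == id, ]
    sp <- spine_matrices(df)
    dur <- max(df$t) - min(df$t)
    dt <- if (nrow(df) > 1) median(diff(df$t)) else 1
    w <- max(1L, 2L * (round(smooth_window_s / dt) %/% 2L) + 1L)
    cx <- smooth_ma(rowMeans(sp$x), w); cy <- smooth_ma(rowMeans(sp$y), w)
    excursion <- max(sqrt((cx - cx[1])^2 + (cy - cy[1])^2))
    bl <- median(colSums(sqrt(diff(t(sp$x))^2 + diff(t(sp$y))^2)))
    tibble::tibble(larva_id = id, duration_s = dur, excursion_mm = excursion,
                   body_length_mm = bl,
                   kept = dur >= min_duration_s & excursion >= min_body_lengths * bl)
  })
  log <- dplyr::bind_rows(log)
  out <- tracks[tracks$larva_id %in% log$larva_id[log$kept], ]
  attr(out, "rejections") <- log
  out
}
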