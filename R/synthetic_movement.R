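#' Generate correlated-random-walk movement tracks
#'
#' Emulates scan-sampled tamarin tracks: each day is a correlated random walk
#' with wrapped-normal turning angles (sd `cfg$turn_sd_rad`) and gamma step
#' lengths, sampled every `scan_interval_min` over `activity_hours`. The
#' walk is reflected at the home-range boundary. Step lengths are calibrated
#' by moment matching: a day's target path length `L` is drawn from a gamma
#' distribution with mean `daily_path_m["mean"]` (sd 500 m), rejected outside
#' `[min, max]`; the per-step gamma then has shape `cfg$step_shape` and scale
#' `L / n_steps / step_shape`, so the expected sum of steps equals `L`.
#'
#' @param cfg A [scenario_config()].
#' @param n_days Number of days (default `cfg$n_days`).
#' @param boundary `c(xmin, xmax, ymin, ymax)`; defaults to the square home
#'   range implied by `cfg$home_range_area_ha`.
#' @param seed Integer seed.
#' @return Data frame `day,scan_index,minutes_since_start,x,y`; 9 h at 30 min
#'   gives 19 scans per day.
#' @export
generate_tracks <- function(cfg, n_days = cfg$n_days, boundary = NULL,
                            seed = child_seed(cfg$seed, "tracks")) {
  stopifnot(inherits(cfg, "scenario_config"), n_days >= 1)
  if (is.null(boundary)) {
    side <- sqrt(cfg$home_range_area_ha * 1e4)
    boundary <- c(xmin = 0, xmax = side, ymin = 0, ymax = side)
  }
  set.seed(seed)
  n_scans <- as.integer(round(cfg$activity_hours * 60 / cfg$scan_interval_min)) + 1L
  n_steps <- n_scans - 1L
  dp <- cfg$daily_path_m
  shape_day <- (dp[["mean"]] / 500)^2
  rate_day <- shape_day / dp[["mean"]]
  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    repeat {
      L <- stats::rgamma(1L, shape = shape_day, rate = rate_day)
      if (L >= dp[["min"]] && L <= dp[["max"]]) break
    }
    steps <- stats::rgamma(n_steps, shape = cfg$step_shape,
                           scale = L / n_steps / cfg$step_shape)
    turns <- stats::rnorm(n_steps, 0, cfg$turn_sd_rad)
    heading <- stats::runif(1L, 0, 2 * pi) + cumsum(turns)
    x <- cumsum(c(stats::runif(1L, boundary["xmin"], boundary["xmax"]),
                  steps * cos(heading)))
    y <- cumsum(c(stats::runif(1L, boundary["ymin"], boundary["ymax"]),
                  steps * sin(heading)))
    days[[d]] <- data.frame(
      day = d,
      scan_index = seq_len(n_scans),
      minutes_since_start = (seq_len(n_scans) - 1L) * cfg$scan_interval_min,
      x = reflect_into(x, boundary["xmin"], boundary["xmax"]),
      y = reflect_into(y, boundary["ymin"], boundary["ymax"])
    )
  }
  out <- do.call(rbind, days)
  rownames(out) <- NULL
  out
}

# fold coordinates into [lo, hi] by repeated reflection (triangle wave)
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  u <- (v - lo) %% (2 * w)
  lo + pmin(u, 2 * w - u)
}

# linear interpolation of a day's track at time t (minutes); t beyond the
# last scan returns the last scan position
track_position_at <- function(track, t) {
  tt <- track$minutes_since_start
  x <- stats::approx(tt, track$x, xout = pmin(pmax(t, tt[1]), tt[length(tt)]))$y
  y <- stats::approx(tt, track$y, xout = pmin(pmax(t, tt[1]), tt[length(tt)]))$y
  cbind(x = x, y = y)
}

#' Generate ground-truth dispersal events along movement tracks
#'
#' Feeding events are placed at randomly chosen scan points (the number per
#' day is Poisson with mean `cfg$trees_visited_per_day`, at least one); the
#' source tree is the adult nearest to the scan location and the feeding
#' location is that tree's location. Each event's seed receives a gut passage
#' time drawn uniformly on the species gut window and is deposited at the
#' track position (linearly interpolated) that much later. Seeds whose gut
#' timer outlasts the activity period are deposited at the day's final scan
#' (the sleeping site) and flagged.
#'
#' @param tracks Track table from [generate_tracks()].
#' @param adults Adult table from [generate_landscape()].
#' @param cfg A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `events` (one row per event: day, source, feeding scan
#'   time, gut time, deposition location and `flagged_day_end`), `records`
#'   (OSD-style [dispersal_records()]) and `truth` (source id + true SDD per
#'   event).
#' @export
generate_dispersal_events <- function(tracks, adults, cfg,
                                      seed = child_seed(cfg$seed, "events")) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(seed)
  gw <- cfg$gut_window_min
  days <- split(tracks, tracks$day)
  rows <- vector("list", length(days))
  for (k in seq_along(days)) {
    tr <- days[[k]]
    n_scans <- nrow(tr)
    n_feed <- min(max(1L, stats::rpois(1L, cfg$trees_visited_per_day)), n_scans - 1L)
    scans <- sort(sample.int(n_scans - 1L, n_feed))
    d2 <- outer(tr$x[scans], adults$x, "-")^2 + outer(tr$y[scans], adults$y, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    gut <- stats::runif(n_feed, gw[1], gw[2])
    t_feed <- tr$minutes_since_start[scans]
    t_dep <- t_feed + gut
    t_end <- tr$minutes_since_start[n_scans]
    flagged <- t_dep > t_end
    pos <- track_position_at(tr, t_dep)
    rows[[k]] <- data.frame(
      day = tr$day[1],
      source_id = adults$id[nearest],
      feed_x = adults$x[nearest], feed_y = adults$y[nearest],
      t_feed_min = t_feed, gut_min = gut, t_dep_min = pmin(t_dep, t_end),
      dep_x = pos[, "x"], dep_y = pos[, "y"],
      flagged_day_end = flagged,
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  records <- dispersal_records(events$source_id,
                               cbind(x = events$feed_x, y = events$feed_y),
                               cbind(x = events$dep_x, y = events$dep_y),
                               method = "OSD", species = cfg$species_name)
  truth <- data.frame(
    event = seq_len(nrow(events)),
    source_id = events$source_id,
    true_distance_m = records$distance_m,
    stringsAsFactors = FALSE
  )
  list(events = events, records = records, truth = truth)
}
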