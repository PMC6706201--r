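#' Interval distances between all scan-point pairs of each day
#'
#' The phenomenological movement x gut-passage model starts from the linear
#' (Euclidean) distances between every ordered pair of scan points within a
#' daily travel path, together with the time lag between them — from one scan
#' interval up to the full activity period. All scans enter, not only those
#' after feeding visits, so the method also applies to remotely tracked
#' animals. Pairs never span days.
#'
#' @param tracks Data frame `day,scan_index,minutes_since_start,x,y` (one or
#'   several days); days with fewer than 2 scans are skipped.
#' @param day Optional day id(s) to restrict to.
#' @return Data frame `day,lag_min,distance_m`, one row per within-day pair;
#'   a day with `n` scans contributes `choose(n, 2)` rows.
#' @export
interval_distances <- function(tracks, day = NULL) {
  need <- c("day", "minutes_since_start", "x", "y")
  if (!all(need %in% names(tracks))) {
    stop("tracks need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is.null(day)) tracks <- tracks[tracks$day %in% day, , drop = FALSE]
  out <- lapply(split(tracks, tracks$day), function(tr) {
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    tt <- tr$minutes_since_start
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("timestamps must be strictly increasing within a day", call. = FALSE)
    }
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
    data.frame(day = tr$day[1],
               lag_min = tt[j] - tt[i],
               distance_m = sqrt((tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(day = numeric(0), lag_min = numeric(0), distance_m = numeric(0)))
  }
  rownames(out) <- NULL
  out
}

#' Estimate a gut-passage-time window from a sample
#'
#' Resting can lengthen gut passage without adding displacement, so the
#' window is conservative: for samples of at least `small_n` observations it
#' spans the empirical 5% and 80% sample quantiles (order-statistic quantiles
#' with linear interpolation, configurable via `lower_q`/`upper_q`); smaller
#' samples fall back on the observed minimum and maximum, the only defensible
#' bounds at n of a few.
#'
#' @param sample Numeric vector of gut passage times (minutes), `n >= 2`.
#' @param lower_q,upper_q Quantiles used for large samples (defaults 0.05 and
#'   0.80).
#' @param small_n Below this sample size the min-max rule is used (default 10).
#' @return List of class `gut_window`: `lower_min`, `upper_min`,
#'   `n_source_obs`, `rule` (`"quantile"` or `"minmax"`).
#' @export
gut_passage_window <- function(sample, lower_q = 0.05, upper_q = 0.80,
                               small_n = 10L) {
  sample <- as.numeric(sample)
  if (length(sample) < 2L || anyNA(sample)) {
    stop("gut_passage_window(): need >= 2 non-missing observations", call. = FALSE)
  }
  stopifnot(lower_q > 0 || lower_q == 0, lower_q < upper_q, upper_q <= 1)
  if (length(sample) >= small_n) {
    q <- stats::quantile(sample, c(lower_q, upper_q), names = FALSE, type = 7)
    rule <- "quantile"
  } else {
    q <- range(sample)
    rule <- "minmax"
  }
  if (q[1] >= q[2]) {
    stop(sprintf("degenerate gut window (lower %.1f >= upper %.1f): sample has no spread",
                 q[1], q[2]), call. = FALSE)
  }
  structure(list(lower_min = q[1], upper_min = q[2],
                 n_source_obs = length(sample), rule = rule),
            class = "gut_window")
}

#' @export
print.gut_window <- function(x, ...) {
  cat(sprintf("<gut_window> %.0f-%.0f min (%s rule, n = %d)\n",
              x$lower_min, x$upper_min, x$rule, x$n_source_obs))
  invisible(x)
}

#' Seed dispersal distances from movement and gut passage (CMG)
#'
#' Pools the interval distances whose time lag falls inside the gut-passage
#' window (optionally widened by `lag_tolerance_min` on each side to absorb
#' field jitter around the nominal 30-min scans): each qualifying scan-point
#' pair is one potential seed dispersal distance.
#'
#' @param tracks Track table (`day,scan_index,minutes_since_start,x,y`) or a
#'   precomputed [interval_distances()] table.
#' @param window A [gut_passage_window()] or `c(lower, upper)` in minutes.
#' @param lag_tolerance_min Tolerance added to both window edges (default 5;
#'   use 0 for exact synthetic scan grids).
#' @param species Species label.
#' @return A [distance_sample()] with method `"CMG"`; attribute `n_pairs_total`
#'   records the number of candidate pairs before the lag filter.
#' @export
estimate_cmg <- function(tracks, window, lag_tolerance_min = 5,
                         species = "unknown") {
  if (inherits(window, "gut_window")) {
    lo <- window$lower_min; hi <- window$upper_min
  } else {
    stopifnot(is.numeric(window), length(window) == 2L)
    lo <- window[1]; hi <- window[2]
  }
  if (!(lo > 0 && lo < hi)) stop("invalid gut window", call. = FALSE)
  pairs <- if (all(c("lag_min", "distance_m") %in% names(tracks))) tracks
           else interval_distances(tracks)
  keep <- pairs$lag_min >= (lo - lag_tolerance_min) &
          pairs$lag_min <= (hi + lag_tolerance_min)
  if (!any(keep)) {
    stop(sprintf(
      "no scan-point pairs with lags inside the gut window %.0f-%.0f min (available lags: %s min)",
      lo, hi, paste(sort(unique(pairs$lag_min)), collapse = ", ")), call. = FALSE)
  }
  out <- distance_sample("CMG", species, pairs$distance_m[keep])
  attr(out, "n_pairs_total") <- nrow(pairs)
  out
}
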