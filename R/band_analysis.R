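#' Kernel-smoothed daily interval density
#'
#' Gaussian kernel density estimate of a day's retained interval values,
#' evaluated on a fixed 1 ms grid over the distribution's range (0-350 ms by
#' default). The smoothing is fit to the raw retained values rather than to
#' the 10 ms histogram, which avoids double-binning artifacts. Local maxima
#' of this curve are the day's rhythm "bands".
#'
#' @param dist an `ioi_distribution` from [daily_distribution()], or a bare
#'   numeric vector of values.
#' @param bandwidth `"sj"` (Sheather-Jones, default), `"scott"`,
#'   `"nrd"`, or a fixed bandwidth in ms. Sheather-Jones adapts to
#'   multimodal daily samples where global scale rules oversmooth and merge
#'   neighbouring bands.
#' @param grid_step evaluation grid step in ms (default 1).
#' @return object of class `band_density`: list with `grid`, `density`,
#'   `bw` (ms), `n`, `day`.
#' @export
smooth_distribution <- function(dist, bandwidth = "sj", grid_step = 1) {
  if (inherits(dist, "ioi_distribution")) {
    v <- dist$values
    rng <- range(dist$breaks)
    day <- dist$day
  } else {
    v <- as.numeric(dist)
    rng <- c(0, 350)
    day <- NA_integer_
  }
  if (length(v) < 2) stop("kernel smoothing needs at least 2 values")
  bw <- .resolve_bw(v, bandwidth)
  d <- stats::density(v, bw = bw, kernel = "gaussian",
                      from = rng[1], to = rng[2],
                      n = as.integer(diff(rng) / grid_step) + 1L)
  structure(list(grid = d$x, density = d$y, bw = bw, n = length(v),
                 day = day),
            class = "band_density")
}

.resolve_bw <- function(v, bandwidth) {
  if (is.numeric(bandwidth)) {
    stopifnot(bandwidth > 0)
    return(bandwidth)
  }
  bw <- switch(match.arg(bandwidth, c("sj", "scott", "nrd")),
    sj = tryCatch(stats::bw.SJ(v), error = function(e) stats::bw.nrd0(v)),
    # Scott's factor as used in common KDE implementations: sd * n^(-1/5)
    scott = stats::sd(v) * length(v)^(-1/5),
    nrd = stats::bw.nrd(v))
  # degenerate samples (near-zero spread): fall back to the grid scale
  if (!is.finite(bw) || bw <= 0) bw <- 1
  bw
}

#' @export
print.band_density <- function(x, ...) {
  cat(sprintf("<band_density> day %s: n = %d, bw = %.2f ms, grid %g-%g ms\n",
              x$day, x$n, x$bw, min(x$grid), max(x$grid)))
  invisible(x)
}

# topographic prominence of peaks at grid indices `loc` on curve y:
# height minus the higher of the two key saddles (lowest point on the way
# to the nearest higher ground on each side; range minimum if none).
.peak_prominence <- function(y, loc) {
  n <- length(y)
  vapply(loc, function(i) {
    h <- y[i]
    key <- function(step) {
      j <- i + step; lo <- h
      while (j >= 1 && j <= n) {
        if (y[j] > h) return(lo)
        lo <- min(lo, y[j])
        j <- j + step
      }
      NA_real_  # no higher ground on this side
    }
    ks <- c(key(-1L), key(1L))
    ks <- ks[!is.na(ks)]
    h - (if (length(ks)) max(ks) else min(y))  # global max: drop to floor
  }, numeric(1))
}

#' Detect bands as local maxima of a smoothed density
#'
#' A band is a strict local maximum of the kernel-smoothed daily interval
#' density whose topographic prominence is at least `min_prominence` times
#' the curve's global maximum. Plateau maxima are reported at the plateau
#' midpoint; maxima at the grid endpoints are excluded by default as range
#' truncation artifacts.
#'
#' @param dens a `band_density` from [smooth_distribution()].
#' @param min_prominence prominence threshold as a fraction of the peak
#'   density (default 0.05).
#' @param include_endpoints also consider maxima at the first/last grid
#'   point (default FALSE).
#' @return data.frame with columns `day`, `position` (ms), `height`,
#'   `prominence`, sorted by position.
#' @export
detect_bands <- function(dens, min_prominence = 0.05,
                         include_endpoints = FALSE) {
  stopifnot(inherits(dens, "band_density"))
  y <- dens$density
  n <- length(y)
  if (n < 3 || all(y == 0)) stop("empty or degenerate density curve")
  # collapse exact plateaus to their midpoint before the slope test
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mids <- floor((starts + ends) / 2)
  yy <- r$values
  k <- length(yy)
  is_max <- logical(k)
  if (k >= 3) {
    is_max[2:(k - 1)] <- yy[2:(k - 1)] > yy[1:(k - 2)] &
      yy[2:(k - 1)] > yy[3:k]
  }
  if (include_endpoints && k >= 2) {
    is_max[1] <- yy[1] > yy[2]
    is_max[k] <- yy[k] > yy[k - 1]
  }
  loc <- mids[is_max]
  if (!length(loc)) {
    return(data.frame(day = integer(), position = numeric(),
                      height = numeric(), prominence = numeric()))
  }
  prom <- .peak_prominence(y, loc)
  keep <- prom >= min_prominence * max(y)
  out <- data.frame(day = rep(dens$day, sum(keep)),
                    position = dens$grid[loc[keep]],
                    height = y[loc[keep]], prominence = prom[keep])
  out[order(out$position), , drop = FALSE]
}

#' Bands of every recording day
#'
#' Convenience wrapper: smooths each day's pooled interval distribution and
#' detects its bands. Days with fewer than 2 retained values are skipped.
#'
#' @param ds a [song_dev()] dataset.
#' @param feature,order,range,width passed to [daily_distributions()].
#' @param bandwidth,min_prominence passed to [smooth_distribution()] /
#'   [detect_bands()].
#' @return list with `bands` (data.frame day, position, height, prominence)
#'   and `densities` (named list of `band_density` by day).
#' @export
daily_bands <- function(ds, feature = "ioi", order = 1, range = c(0, 350),
                        width = 10, bandwidth = "sj", min_prominence = 0.05) {
  dists <- daily_distributions(ds, feature = feature, order = order,
                               range = range, width = width)
  dists <- Filter(function(d) d$n >= 2, dists)
  dens <- lapply(dists, smooth_distribution, bandwidth = bandwidth)
  bands <- do.call(rbind, lapply(dens, detect_bands,
                                 min_prominence = min_prominence))
  if (is.null(bands)) {
    bands <- data.frame(day = integer(), position = numeric(),
                        height = numeric(), prominence = numeric())
  }
  rownames(bands) <- NULL
  list(bands = bands, densities = dens)
}

#' Mean band count per 10-day window
#'
#' Averages the per-day band count of each bird within consecutive windows
#' of `window` days starting at `start` days post-hatch (decades, by
#' default). Windows without any recording day are absent from the output,
#' not zero.
#'
#' @param bands data.frame with columns `bird`, `day` and one row per band
#'   (as from [daily_bands()], with a `bird` column added; a missing `bird`
#'   column is treated as one bird).
#' @param window window length in days (default 10).
#' @param start first window start, days post-hatch (default 40).
#' @return data.frame with columns `bird`, `decade` (window start day),
#'   `mean_bands`, `n_days`.
#' @export
count_bands_by_decade <- function(bands, window = 10, start = 40) {
  if (!"bird" %in% names(bands)) bands$bird <- "bird"
  bands <- bands[bands$day >= start, , drop = FALSE]
  if (!nrow(bands)) {
    return(data.frame(bird = character(), decade = numeric(),
                      mean_bands = numeric(), n_days = integer()))
  }
  per_day <- stats::aggregate(position ~ bird + day, data = bands,
                              FUN = length)
  names(per_day)[3] <- "n_bands"
  per_day$decade <- start + floor((per_day$day - start) / window) * window
  agg <- stats::aggregate(n_bands ~ bird + decade, data = per_day, FUN = mean)
  cnt <- stats::aggregate(n_bands ~ bird + decade, data = per_day, FUN = length)
  out <- data.frame(bird = agg$bird, decade = agg$decade,
                    mean_bands = agg$n_bands, n_days = cnt$n_bands)
  out[order(out$bird, out$decade), , drop = FALSE]
}

#' Track bands across recording days and flag new-band emergences
#'
#' Greedy nearest-neighbour linking between the bands of consecutive
#' recording days: candidate links (sorted by distance, ties by earlier
#' track id) are accepted while the distance is below `link_threshold` and
#' neither endpoint is taken. Bands of the first day found tracks without an
#' emergence event; an unlinked band on a later day opens a new track and
#' yields an emergence event. The stem band of each event is the local
#' maximum of the previous recording day's density nearest to the new band
#' (ties broken toward the smaller position); events on days with no
#' prior-day band are flagged unassignable.
#'
#' @param bands data.frame (day, position, ...) as from [daily_bands()],
#'   one bird.
#' @param link_threshold maximum day-to-day position change of one band
#'   (ms), default 30.
#' @return list with `tracks` (data.frame track_id, day, position) and
#'   `events` (data.frame day, track_id, new_position, stem_position,
#'   distance, unassignable).
#' @export
track_bands <- function(bands, link_threshold = 30) {
  days <- sort(unique(bands$day))
  tracks <- data.frame(track_id = integer(), day = integer(),
                       position = numeric())
  events <- data.frame(day = integer(), track_id = integer(),
                       new_position = numeric(), stem_position = numeric(),
                       distance = numeric(), unassignable = logical())
  if (!length(days)) return(list(tracks = tracks, events = events))
  next_id <- 1L
  prev <- NULL  # data.frame track_id, position
  for (d in days) {
    pos <- sort(bands$position[bands$day == d])
    cur <- data.frame(track_id = rep(NA_integer_, length(pos)),
                      position = pos)
    if (is.null(prev)) {
      cur$track_id <- seq.int(next_id, length.out = nrow(cur))
      next_id <- next_id + nrow(cur)
    } else if (nrow(cur)) {
      cand <- expand.grid(i = seq_len(nrow(cur)), j = seq_len(nrow(prev)))
      cand$dist <- abs(cur$position[cand$i] - prev$position[cand$j])
      cand <- cand[cand$dist < link_threshold, , drop = FALSE]
      cand <- cand[order(cand$dist, prev$track_id[cand$j]), , drop = FALSE]
      used_i <- logical(nrow(cur)); used_j <- logical(nrow(prev))
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (!used_i[i] && !used_j[j]) {
          cur$track_id[i] <- prev$track_id[j]
          used_i[i] <- TRUE; used_j[j] <- TRUE
        }
      }
      for (i in which(is.na(cur$track_id))) {
        cur$track_id[i] <- next_id
        next_id <- next_id + 1L
        stem <- .nearest_position(prev$position, cur$position[i])
        events <- rbind(events, data.frame(
          day = d, track_id = cur$track_id[i],
          new_position = cur$position[i],
          stem_position = stem,
          distance = abs(cur$position[i] - stem),
          unassignable = FALSE))
      }
    }
    if (nrow(cur)) {
      tracks <- rbind(tracks, data.frame(track_id = cur$track_id, day = d,
                                         position = cur$position))
    }
    if (nrow(cur)) prev <- cur
  }
  rownames(tracks) <- rownames(events) <- NULL
  list(tracks = tracks, events = events)
}

# nearest value in `candidates` to x; ties toward the smaller position
.nearest_position <- function(candidates, x) {
  d <- abs(candidates - x)
  candidates[order(d, candidates)][1]
}

#' Assign stem bands to emergence events
#'
#' Recomputes the stem of each event from the local maxima of the previous
#' recording day's smoothed density (rather than from the thresholded band
#' list): the stem is the prior-day maximum nearest to the new band, ties
#' toward the smaller position. Events with no prior-day maximum are flagged
#' `unassignable` and excluded from distance statistics.
#'
#' @param events event data.frame from [track_bands()].
#' @param densities named list of `band_density` by day (as from
#'   [daily_bands()]).
#' @param min_prominence prominence threshold used to list prior-day maxima.
#' @return the events data.frame with `stem_position`, `distance`,
#'   `unassignable` recomputed.
#' @export
assign_stem <- function(events, densities, min_prominence = 0.05) {
  if (!nrow(events)) return(events)
  days <- as.numeric(names(densities))
  for (r in seq_len(nrow(events))) {
    prior <- days[days < events$day[r]]
    if (!length(prior)) {
      events$stem_position[r] <- NA_real_
      events$distance[r] <- NA_real_
      events$unassignable[r] <- TRUE
      next
    }
    pd <- densities[[as.character(max(prior))]]
    maxima <- detect_bands(pd, min_prominence = min_prominence)$position
    if (!length(maxima)) {
      events$stem_position[r] <- NA_real_
      events$distance[r] <- NA_real_
      events$unassignable[r] <- TRUE
    } else {
      stem <- .nearest_position(maxima, events$new_position[r])
      events$stem_position[r] <- stem
      events$distance[r] <- abs(events$new_position[r] - stem)
      events$unassignable[r] <- FALSE
    }
  }
  events
}

#' Classify emergence events as branching or other
#'
#' Operationalizes the distinction between a new band that continuously
#' branches off its stem and one that appears without clear continuity: an
#' event is `branching` iff, on its emergence day, the minimum density
#' between stem and new position is at least `valley_ratio` times the lower
#' of the densities at the two positions (the new band is still connected
#' to the stem by a filled valley) AND the stem distance is at most
#' `distance_cap` ms. Everything else is `other`. Only events with
#' `day < day_limit` are classified; with intermittent recording, later
#' emergences cannot be attributed reliably.
#'
#' @param events event data.frame with stems assigned ([assign_stem()]).
#' @param densities named list of `band_density` by day.
#' @param valley_ratio fraction of the lower peak density the valley must
#'   retain (default 0.5).
#' @param distance_cap maximum stem distance of a branching event (ms),
#'   default 60.
#' @param day_limit only events before this day are classified (default 80).
#' @return the events data.frame restricted to `day < day_limit`, with a
#'   `class` column (`"branching"` / `"other"`, NA when unassignable).
#' @export
classify_emergence <- function(events, densities, valley_ratio = 0.5,
                               distance_cap = 60, day_limit = 80) {
  events <- events[events$day < day_limit, , drop = FALSE]
  events$class <- rep(NA_character_, nrow(events))
  for (r in seq_len(nrow(events))) {
    if (isTRUE(events$unassignable[r])) next
    dens <- densities[[as.character(events$day[r])]]
    lo <- min(events$new_position[r], events$stem_position[r])
    hi <- max(events$new_position[r], events$stem_position[r])
    sel <- dens$grid >= lo & dens$grid <= hi
    valley <- min(dens$density[sel])
    ref <- min(stats::approx(dens$grid, dens$density,
                             c(events$new_position[r],
                               events$stem_position[r]))$y)
    ok_valley <- valley >= valley_ratio * ref
    ok_dist <- events$distance[r] <= distance_cap
    events$class[r] <- if (ok_valley && ok_dist) "branching" else "other"
  }
  rownames(events) <- NULL
  events
}

#' Full emergence analysis of one bird
#'
#' Runs [daily_bands()], [track_bands()], [assign_stem()] and
#' [classify_emergence()] in sequence.
#'
#' @param ds a [song_dev()] dataset.
#' @param bandwidth,min_prominence see [daily_bands()].
#' @param link_threshold see [track_bands()].
#' @param valley_ratio,distance_cap,day_limit see [classify_emergence()].
#' @return list with `bands`, `densities`, `tracks`, `events` (classified).
#' @export
band_emergence <- function(ds, bandwidth = "sj", min_prominence = 0.05,
                           link_threshold = 30, valley_ratio = 0.5,
                           distance_cap = 60, day_limit = 80) {
  db <- daily_bands(ds, bandwidth = bandwidth,
                    min_prominence = min_prominence)
  tr <- track_bands(db$bands, link_threshold = link_threshold)
  ev <- assign_stem(tr$events, db$densities,
                    min_prominence = min_prominence)
  ev <- classify_emergence(ev, db$densities, valley_ratio = valley_ratio,
                           distance_cap = distance_cap,
                           day_limit = day_limit)
  list(bands = db$bands, densities = db$densities, tracks = tr$tracks,
       events = ev)
}

#' Summary statistics of classified emergence events
#'
#' Per-class counts and mean +/- sd of the emergence day and of the stem
#' distance, plus two-sample Welch t comparisons between the classes on both
#' quantities (reported only when both classes are populated with n >= 2).
#'
#' @param events classified event data.frame (possibly pooled over birds).
#' @return list with `by_class` (data.frame class, n, day_mean, day_sd,
#'   distance_mean, distance_sd) and `tests` (list with `distance` and
#'   `day` htest objects, or NULL).
#' @export
emergence_statistics <- function(events) {
  ev <- events[!is.na(events$class), , drop = FALSE]
  if (!nrow(ev)) stop("no classified events")
  by_class <- do.call(rbind, lapply(split(ev, ev$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g),
               day_mean = mean(g$day), day_sd = stats::sd(g$day),
               distance_mean = mean(g$distance),
               distance_sd = stats::sd(g$distance))
  }))
  rownames(by_class) <- NULL
  tests <- NULL
  if (all(c("branching", "other") %in% ev$class) &&
      min(table(ev$class)) >= 2) {
    b <- ev[ev$class == "branching", ]
    o <- ev[ev$class == "other", ]
    tests <- list(distance = stats::t.test(b$distance, o$distance),
                  day = stats::t.test(b$day, o$day))
  }
  list(by_class = by_class, tests = tests)
}

#' Use rate of an interval window per recording
#'
#' Fraction of order-`k` IOIs falling inside `center +/- halfwidth` ms, per
#' recording, plus per-day mean +/- sd across recordings. Developed chunks
#' and self-repetitions occupy narrow IOI windows (a self-repetition at its
#' order-1 IOI; a three-note chunk at the order-2 IOI between its first and
#' last note), so this rate traces a substring pattern's use back through
#' development.
#'
#' @param ds a [song_dev()] dataset.
#' @param center window center (ms).
#' @param halfwidth window half width (ms).
#' @param order IOI order of the pattern (1 for a two-note transition or
#'   self-repetition, 2 for a three-note chunk, ...).
#' @return data.frame with columns `recording_id`, `day`, `n` (total
#'   order-k IOIs) and `rate`; recordings with zero IOIs are excluded.
#'   Attribute `by_day`: data.frame day, mean, sd, n_recordings.
#' @export
band_usage_rate <- function(ds, center, halfwidth, order = 1) {
  stopifnot(center - halfwidth >= 0, center + halfwidth <= 350)
  iois <- compute_iois(ds, order = order)
  if (!nrow(iois)) {
    out <- data.frame(recording_id = integer(), day = integer(),
                      n = integer(), rate = numeric())
    attr(out, "by_day") <- data.frame(day = integer(), mean = numeric(),
                                      sd = numeric(),
                                      n_recordings = integer())
    return(out)
  }
  inside <- iois$value >= center - halfwidth & iois$value <= center + halfwidth
  per_rec <- do.call(rbind, lapply(split(seq_len(nrow(iois)),
                                         iois$recording_id), function(idx) {
    data.frame(recording_id = iois$recording_id[idx[1]],
               day = iois$day[idx[1]], n = length(idx),
               rate = mean(inside[idx]))
  }))
  per_rec <- per_rec[order(per_rec$recording_id), , drop = FALSE]
  rownames(per_rec) <- NULL
  by_day <- do.call(rbind, lapply(split(per_rec, per_rec$day), function(g) {
    data.frame(day = g$day[1], mean = mean(g$rate), sd = stats::sd(g$rate),
               n_recordings = nrow(g))
  }))
  rownames(by_day) <- NULL
  attr(per_rec, "by_day") <- by_day
  per_rec
}
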