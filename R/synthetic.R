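#' Specify one simulated rhythm band
#'
#' A band is a Gaussian component of the day-varying IOI mixture. Its mean
#' position can drift linearly from a birth position to a terminal position
#' (branching bands drift away from their parent); its jitter anneals
#' exponentially from `sd_start` toward `sd_end` at `anneal_rate` per day,
#' and is frozen from `freeze_day` on (planting a crystallized stage).
#'
#' @param track_id integer id.
#' @param birth_day first day the band is active.
#' @param mode `"founder"`, `"branching"` or `"denovo"`.
#' @param parent parent `track_id` for branching bands, else `NA`.
#' @param birth_position mean IOI (ms) at `birth_day`.
#' @param terminal_position mean IOI (ms) reached at `drift_end_day`
#'   (default: no drift).
#' @param drift_end_day day the linear drift ends (default `birth_day`).
#' @param settle_position,settle_end_day optional second drift segment:
#'   after reaching `terminal_position`, the band settles linearly to
#'   `settle_position` by `settle_end_day` (defaults: no settling). Lets a
#'   band overshoot and refine late in development.
#' @param sd_start,sd_end jitter sd (ms) at birth and asymptotically.
#' @param anneal_rate exponential annealing rate of the jitter (per day).
#' @param freeze_day day from which the band's jitter and raw weight stay
#'   at their current values (plants a crystallized stage).
#' @param weight relative weight scale (raw weights are normalized across
#'   the day's active bands; non-founder bands ramp in over ~16 days).
#' @param weight_decay exponential decay rate of the raw weight (per day,
#'   default 0); lets a broadband juvenile component fade out.
#' @return object of class `band_spec` (a list of the above).
#' @export
band_spec <- function(track_id, birth_day, mode = c("founder", "branching",
                                                    "denovo"),
                      parent = NA_integer_, birth_position,
                      terminal_position = birth_position,
                      drift_end_day = birth_day,
                      settle_position = terminal_position,
                      settle_end_day = drift_end_day, sd_start = 10,
                      sd_end = sd_start, anneal_rate = 0.05,
                      freeze_day = Inf, weight = 1, weight_decay = 0) {
  mode <- match.arg(mode)
  stopifnot(birth_position > 0, sd_start > 0, sd_end > 0, weight > 0,
            weight_decay >= 0, drift_end_day >= birth_day,
            settle_end_day >= drift_end_day)
  structure(list(track_id = as.integer(track_id), birth_day = birth_day,
                 mode = mode, parent = parent,
                 birth_position = birth_position,
                 terminal_position = terminal_position,
                 drift_end_day = drift_end_day,
                 settle_position = settle_position,
                 settle_end_day = settle_end_day, sd_start = sd_start,
                 sd_end = sd_end, anneal_rate = anneal_rate,
                 freeze_day = freeze_day, weight = weight,
                 weight_decay = weight_decay),
            class = "band_spec")
}

# evaluate one band's (position, sd, raw weight) on one day; NA if inactive
.band_state <- function(spec, day) {
  if (day < spec$birth_day) {
    return(c(position = NA_real_, sd = NA_real_, weight = NA_real_))
  }
  pos <- if (day <= spec$drift_end_day) {
    frac <- if (spec$drift_end_day > spec$birth_day) {
      (day - spec$birth_day) / (spec$drift_end_day - spec$birth_day)
    } else 1
    spec$birth_position + frac * (spec$terminal_position - spec$birth_position)
  } else if (day >= spec$settle_end_day) {
    spec$settle_position
  } else {
    frac <- (day - spec$drift_end_day) /
      (spec$settle_end_day - spec$drift_end_day)
    spec$terminal_position +
      frac * (spec$settle_position - spec$terminal_position)
  }
  sd_at <- function(d) {
    spec$sd_end + (spec$sd_start - spec$sd_end) *
      exp(-spec$anneal_rate * (d - spec$birth_day))
  }
  d_eff <- min(day, spec$freeze_day)
  s <- sd_at(d_eff)
  ramp <- if (spec$mode == "founder") 1 else
    min(1, 0.3 + 0.7 * (day - spec$birth_day) / 16)
  w <- spec$weight * ramp * exp(-spec$weight_decay * (d_eff - spec$birth_day))
  c(position = pos, sd = s, weight = w)
}

#' Evaluate band schedules on a set of days
#'
#' @param bands list of [band_spec()].
#' @param days numeric vector of days.
#' @return data.frame with columns `day`, `track_id`, `position`, `sd`,
#'   `weight` (normalized within day), active bands only.
#' @export
band_schedule <- function(bands, days) {
  rows <- lapply(days, function(d) {
    st <- t(vapply(bands, .band_state, numeric(3), day = d))
    active <- !is.na(st[, "position"])
    if (!any(active)) stop("no active band on day ", d)
    w <- st[active, "weight"]
    if (sum(w) <= 0) stop("weights not normalizable on day ", d)
    data.frame(day = d,
               track_id = vapply(bands[active], `[[`, 1L, "track_id"),
               position = st[active, "position"], sd = st[active, "sd"],
               weight = w / sum(w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' @param bands list of [band_spec()].
#' @param bird_id bird identifier.
#' @param recording_days days post-hatch with a recording; the default,
#'   every 4 days from day 40 to day 152, emulates intermittent 24 h
#'   recording snapshots of song development.
#' @param notes_per_day notes recorded per day (default 2000; real corpora
#'   carry thousands of notes per recording day).
#' @param notes_per_recording notes per wav-file recording (default 250).
#' @param duration_mean,duration_sd note-duration model (ms); durations are
#'   clipped below the following interval so silent gaps stay non-negative.
#' @param hours clock hours a recording may start at (default 6-19).
#' @param hourly_step optional rapid within-day change: list with `day`,
#'   `hour`, and `weight_mult` (named numeric, track_id -> multiplier)
#'   applied to raw band weights from that clock hour on.
#' @param seed RNG seed; a fixed seed makes the emitted note table
#'   byte-identical across runs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(bands, bird_id = "simbird",
                       recording_days = seq(40, 152, by = 4),
                       notes_per_day = 2000, notes_per_recording = 250,
                       duration_mean = 40, duration_sd = 8,
                       hours = 6:19, hourly_step = NULL, seed = 1) {
  stopifnot(length(bands) >= 1, notes_per_day >= 2,
            notes_per_recording >= 2)
  structure(list(bands = bands, bird_id = bird_id,
                 recording_days = recording_days,
                 notes_per_day = notes_per_day,
                 notes_per_recording = notes_per_recording,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 hours = hours, hourly_step = hourly_step,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a developmental note-event dataset
#'
#' For each recording day, inter-onset intervals are drawn i.i.d. from the
#' day's band mixture (clipped to [25, 350] ms), accumulated into onsets
#' and partitioned into serial recordings; note durations are drawn from
#' the duration model and clipped into [15, following-interval minus 1] ms
#' so the notes survive the standard 15-350 ms noise filter and gaps are
#' non-negative. The planted band schedule and emergence events are
#' returned alongside as ground truth for parameter-recovery tests.
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a [song_dev()]) and `truth` (list with
#'   `bands` = [band_schedule()] table, `events` = data.frame of planted
#'   emergence events with `track_id`, `mode`, `parent`, `birth_day`,
#'   `birth_position`, `stem_position` (parent/nearest band position at the
#'   previous recording day), `planted_distance`).
#' @export
simulate_development <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sched <- band_schedule(cfg$bands, cfg$recording_days)
  rec_id <- 0L
  pieces <- vector("list", length(cfg$recording_days))
  for (di in seq_along(cfg$recording_days)) {
    d <- cfg$recording_days[di]
    day_sched <- sched[sched$day == d, , drop = FALSE]
    n_rec <- max(1L, round(cfg$notes_per_day / cfg$notes_per_recording))
    rec_hours <- sort(sample(cfg$hours, n_rec, replace = TRUE))
    rec_rows <- vector("list", n_rec)
    for (r in seq_len(n_rec)) {
      rec_id <- rec_id + 1L
      m <- cfg$notes_per_recording
      w <- day_sched$weight
      hs <- cfg$hourly_step
      if (!is.null(hs) && d == hs$day && rec_hours[r] >= hs$hour) {
        mult <- hs$weight_mult[as.character(day_sched$track_id)]
        mult[is.na(mult)] <- 1
        w <- w * mult
      }
      w <- w / sum(w)
      comp <- sample.int(nrow(day_sched), m - 1L, replace = TRUE, prob = w)
      iois <- stats::rnorm(m - 1L, day_sched$position[comp],
                           day_sched$sd[comp])
      iois <- pmin(pmax(iois, 25), 350)
      onsets <- cumsum(c(0, iois))
      durs <- stats::rnorm(m, cfg$duration_mean, cfg$duration_sd)
      durs <- pmax(durs, 15)
      durs <- pmin(durs, c(iois - 1, 349), 349)
      rec_rows[[r]] <- data.frame(
        recording_id = rec_id, day = d,
        onset = round(onsets, 3), duration = round(durs, 3),
        hour = rec_hours[r], label = NA_character_)
    }
    pieces[[di]] <- do.call(rbind, rec_rows)
  }
  notes <- do.call(rbind, pieces)
  ds <- song_dev(notes, bird_id = cfg$bird_id,
                 final_day = max(cfg$recording_days))
  truth_events <- .planted_events(cfg$bands, cfg$recording_days)
  list(dataset = ds,
       truth = list(bands = sched, events = truth_events, config = cfg))
}

# planted emergence events: every non-founder band, with the stem evaluated
# at the recording day just before birth
.planted_events <- function(bands, recording_days) {
  non_founder <- Filter(function(b) b$mode != "founder", bands)
  if (!length(non_founder)) {
    return(data.frame(track_id = integer(), mode = character(),
                      parent = integer(), birth_day = numeric(),
                      birth_position = numeric(), stem_position = numeric(),
                      planted_distance = numeric()))
  }
  rows <- lapply(non_founder, function(b) {
    prior_days <- recording_days[recording_days < b$birth_day]
    stem <- NA_real_
    if (length(prior_days)) {
      pd <- max(prior_days)
      st <- band_schedule(bands, pd)
      stem <- .nearest_position(st$position, b$birth_position)
    }
    data.frame(track_id = b$track_id, mode = b$mode, parent = b$parent,
               birth_day = b$birth_day, birth_position = b$birth_position,
               stem_position = stem,
               planted_distance = abs(b$birth_position - stem))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# truncated-normal draw by rejection (narrow use; bounds well inside 3 sd)
.rtnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Bengalese-finch-like developmental simulation preset
#'
#' A single-bird configuration emulating the observed Bengalese-finch
#' development: a broadband juvenile component (180 ms, sd 55 ms) that
#' fades out over development while a founder core band anneals, three
#' branching events (planted stem distances drawn near 25 ms) and one
#' de-novo band (planted stem distance near 80 ms), reaching five terminal
#' bands by day 70; band positions stop drifting by day 84 and all jitter
#' and weights are frozen from day 90, planting a crystallized stage. The
#' resulting JS-vs-final-day trajectory decays approximately exponentially.
#'
#' @param seed RNG seed (also used for the planted event distances).
#' @param bird_id bird identifier.
#' @param notes_per_day notes per recording day (default 2000).
#' @param annealing_rate jitter annealing rate per day (default 0.05).
#' @return a [sim_config()].
#' @export
preset_bengalese <- function(seed = 1, bird_id = "simbird",
                             notes_per_day = 2000, annealing_rate = 0.05) {
  set.seed(seed)
  d_branch <- .rtnorm(3, 25, 15, 5, 55)    # branching stem distances
  d_denovo <- .rtnorm(1, 78, 12, 68, 100)  # de-novo stem distance
  pos_t2 <- 180 + d_branch[1]              # upper branch, done by day 64
  pos_t3 <- 180 - d_branch[2]              # lower branch, done by day 72
  # de-novo band appears at day 64 above the (by then established) upper
  # branch; its stem is that branch's position at the prior recording day
  pos_t2_60 <- pos_t2 + (225 - pos_t2) * (60 - 48) / (64 - 48)
  # t5 branches off the lower branch at day 68 (lower branch at 56 -> 72)
  pos_t3_68 <- 128 + (pos_t3 - 128) * (1 - (68 - 56) / (72 - 56))
  bands <- list(
    # broadband juvenile component, fading out as real bands take over
    band_spec(0L, 40, "founder", birth_position = 180,
              sd_start = 55, freeze_day = 90, weight = 4,
              weight_decay = 0.035),
    band_spec(1L, 40, "founder", birth_position = 180,
              sd_start = 18, sd_end = 9, anneal_rate = annealing_rate,
              freeze_day = 90),
    band_spec(2L, 48, "branching", parent = 1L, birth_position = pos_t2,
              terminal_position = 225, drift_end_day = 64,
              sd_start = 14, sd_end = 9, anneal_rate = annealing_rate,
              freeze_day = 90),
    band_spec(3L, 56, "branching", parent = 1L, birth_position = pos_t3,
              terminal_position = 128, drift_end_day = 72,
              sd_start = 14, sd_end = 9, anneal_rate = annealing_rate,
              freeze_day = 90),
    band_spec(4L, 64, "denovo", birth_position = pos_t2_60 + d_denovo,
              sd_start = 9, anneal_rate = annealing_rate,
              freeze_day = 90),
    band_spec(5L, 68, "branching", parent = 3L,
              birth_position = pos_t3_68 - d_branch[3],
              terminal_position = 80, drift_end_day = 78,
              settle_position = 68, settle_end_day = 86,
              sd_start = 14, sd_end = 9, anneal_rate = annealing_rate,
              freeze_day = 90))
  sim_config(bands, bird_id = bird_id, notes_per_day = notes_per_day,
             seed = seed)
}

#' Match detected emergence events to planted ground truth
#'
#' Each planted event is matched to the detected emergence event whose new
#' band lies within `tol_ms` of the planted track's true position on the
#' detection day; the earliest such detection wins. For branching events
#' the parent's true position is also accepted: when a merged peak splits,
#' which of the two resulting bands keeps the old track identity is
#' arbitrary, so the "new" detected band may be on the parent's side.
#' Unmatched planted events count as misses.
#'
#' @param events classified detected events (from [band_emergence()]).
#' @param truth the `truth` element of [simulate_development()].
#' @param tol_ms matching tolerance (ms), default 25.
#' @return the truth events data.frame with columns `detected_day`,
#'   `detected_position`, `detected_distance`, `detected_class` (NA for
#'   misses) and `agree` (planted mode "branching" vs detected class;
#'   de-novo counts as "other").
#' @export
match_emergence_events <- function(events, truth, tol_ms = 25) {
  te <- truth$events
  te$detected_day <- NA_real_
  te$detected_position <- NA_real_
  te$detected_distance <- NA_real_
  te$detected_class <- NA_character_
  used <- rep(FALSE, nrow(events))
  if (nrow(events)) {
    for (r in seq_len(nrow(te))) {
      tb <- truth$bands[truth$bands$track_id == te$track_id[r], ]
      cand <- which(!used & !is.na(events$class))
      if (!length(cand)) next
      true_pos <- tb$position[match(events$day[cand], tb$day)]
      dist <- abs(events$new_position[cand] - true_pos)
      if (!is.na(te$parent[r])) {
        pb <- truth$bands[truth$bands$track_id == te$parent[r], ]
        par_pos <- pb$position[match(events$day[cand], pb$day)]
        # only accept the parent side once the child is actually active
        par_pos[events$day[cand] < te$birth_day[r]] <- NA_real_
        dist <- pmin(dist, abs(events$new_position[cand] - par_pos),
                     na.rm = TRUE)
      }
      ok <- which(!is.na(dist) & dist <= tol_ms)
      if (!length(ok)) next
      pick <- cand[ok][order(events$day[cand][ok])][1]
      used[pick] <- TRUE
      te$detected_day[r] <- events$day[pick]
      te$detected_position[r] <- events$new_position[pick]
      te$detected_distance[r] <- events$distance[pick]
      te$detected_class[r] <- events$class[pick]
    }
  }
  expected <- ifelse(te$mode == "branching", "branching", "other")
  te$agree <- !is.na(te$detected_class) & te$detected_class == expected
  te
}
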