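# fixture builders shared across test files; everything is generated in code

# one-recording note frame from onsets (and optional durations)
make_notes <- function(onsets, durations = rep(10, length(onsets)),
                       recording_id = 1L, day = 50L, hour = NA_real_) {
  data.frame(recording_id = recording_id, day = day, onset = onsets,
             duration = durations, hour = hour)
}

# dataset whose every recording day carries the same interval values:
# onsets are the cumulative sums of `values` within one recording per day
flat_dataset <- function(values, days, bird_id = "flat") {
  notes <- do.call(rbind, lapply(seq_along(days), function(i) {
    make_notes(cumsum(c(0, values)), recording_id = i, day = days[i])
  }))
  song_dev(notes, bird_id = bird_id)
}

# random valid dataset for round-trip property tests (values rounded so the
# text representation is exact)
random_dataset <- function(seed, with_label = FALSE) {
  set.seed(seed)
  n_days <- sample(2:4, 1)
  days <- sort(sample(40:120, n_days))
  rec <- 0L
  notes <- do.call(rbind, lapply(days, function(d) {
    do.call(rbind, lapply(seq_len(sample(1:3, 1)), function(r) {
      rec <<- rec + 1L
      n <- sample(2:30, 1)
      iois <- round(runif(n - 1, 30, 300), 1)
      onsets <- cumsum(c(0, iois))
      durs <- round(pmin(runif(n, 16, 80), c(iois - 1, 80)), 1)
      df <- make_notes(onsets, durs, recording_id = rec, day = d,
                       hour = sample(6:19, 1))
      if (with_label) df$label <- sample(letters[1:5], n, replace = TRUE)
      df
    }))
  }))
  song_dev(notes, bird_id = paste0("rand", seed))
}

# brute-force histogram oracle: per-value loop over bins
brute_force_bins <- function(values, range = c(0, 350), width = 10) {
  nbins <- as.integer((range[2] - range[1]) / width)
  counts <- integer(nbins)
  for (v in values) {
    if (!is.finite(v) || v < range[1] || v > range[2]) next
    placed <- FALSE
    for (b in seq_len(nbins)) {
      lo <- range[1] + (b - 1) * width
      hi <- lo + width
      if ((v >= lo && v < hi) || (b == nbins && v == range[2])) {
        counts[b] <- counts[b] + 1L
        placed <- TRUE
        break
      }
    }
  }
  counts
}

# brute-force JS oracle: term-by-term sums, no shared code with the package
brute_force_js <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a, b) if (a == 0) 0 else a * log2(a / b)
  kl_pm <- sum(mapply(term, p, m))
  kl_qm <- sum(mapply(term, q, m))
  (kl_pm + kl_qm) / 2
}

# a band_density object built directly from a curve, for detector tests
curve_density <- function(y, grid = seq(0, 350, length.out = length(y)),
                          day = 50L) {
  structure(list(grid = grid, density = y, bw = 1, n = 1000L, day = day),
            class = "band_density")
}

# density curve with Gaussian bumps at given positions (equal weights)
bump_density <- function(positions, sd = 8, grid = 0:350) {
  y <- rowSums(vapply(positions, function(p) stats::dnorm(grid, p, sd),
                      numeric(length(grid)))) / length(positions)
  curve_density(y, grid = grid)
}

# random probability vector over k bins
random_probs <- function(k = 35) {
  x <- stats::rexp(k)
  x / sum(x)
}
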