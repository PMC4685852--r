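#' Inter-onset intervals of a dataset
#'
#' The order-1 inter-onset interval (IOI) is the time between the onsets of
#' consecutive notes, `IOI(i) = t(s[i+1]) - t(s[i])`; it is the proxy for
#' first-order rhythm (note-to-note transitions). Order-`k` intervals span
#' `k` transitions, `onset[i+k] - onset[i]`, and characterise higher-order
#' rhythm (two or more consecutive transitions, e.g. the interval from the
#' first to the last note of a chunk). Intervals never cross recording
#' (file) boundaries.
#'
#' @param ds a [song_dev()] dataset.
#' @param order integer k >= 1.
#' @return data.frame with columns `recording_id`, `day`, `hour`, `value`
#'   (ms), one row per interval, in onset order within each recording. A
#'   recording with fewer than `order + 1` notes contributes no rows.
#' @export
compute_iois <- function(ds, order = 1) {
  stopifnot(inherits(ds, "song_dev"), order >= 1)
  .lagged_series(ds$notes, order, function(n, k, idx) {
    n$onset[idx + k] - n$onset[idx]
  })
}

#' Silent gaps of a dataset
#'
#' The silent gap after note j is `onset[j+1] - (onset[j] + duration[j])`,
#' i.e. the order-1 IOI minus the first note's duration. Negative gaps
#' (overlapping detections) are dropped; their count is kept in attribute
#' `n_overlap`.
#'
#' @param ds a [song_dev()] dataset.
#' @return data.frame as in [compute_iois()], with attribute `n_overlap`.
#' @export
compute_gaps <- function(ds) {
  stopifnot(inherits(ds, "song_dev"))
  out <- .lagged_series(ds$notes, 1L, function(n, k, idx) {
    n$onset[idx + 1] - (n$onset[idx] + n$duration[idx])
  })
  neg <- out$value < 0
  res <- out[!neg, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_overlap") <- sum(neg)
  res
}

# shared walker: applies f to within-recording index pairs (idx, idx + k)
.lagged_series <- function(notes, k, f) {
  empty <- data.frame(recording_id = integer(), day = integer(),
                      hour = numeric(), value = numeric())
  if (nrow(notes) <= k) return(empty)
  # notes are sorted by (day, recording_id, onset); groups are contiguous
  rle_rec <- rle(notes$recording_id)
  ends <- cumsum(rle_rec$lengths)
  starts <- ends - rle_rec$lengths + 1
  pieces <- lapply(seq_along(starts), function(g) {
    n_g <- ends[g] - starts[g] + 1
    if (n_g <= k) return(NULL)
    idx <- starts[g]:(ends[g] - k)
    data.frame(recording_id = notes$recording_id[idx],
               day = notes$day[idx], hour = notes$hour[idx],
               value = f(notes, k, idx))
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# feature value table for a dataset: ioi (order-k), duration, or gap
.feature_values <- function(ds, feature = c("ioi", "duration", "gap"),
                            order = 1) {
  feature <- match.arg(feature)
  switch(feature,
    ioi = compute_iois(ds, order = order),
    gap = compute_gaps(ds),
    duration = {
      n <- ds$notes
      data.frame(recording_id = n$recording_id, day = n$day, hour = n$hour,
                 value = n$duration)
    })
}

#' Binned daily interval distribution
#'
#' Histogram of interval values over `[0, 350]` ms with 10 ms bins (35 bins),
#' normalized by the retained sample size: the per-day "IOI distribution"
#' that the band and divergence analyses operate on. Bins are half-open
#' `[lo, hi)`, except the final bin which also includes the upper range
#' limit. Values outside the range are excluded before binning.
#'
#' @param values numeric vector of interval values (ms).
#' @param day day post-hatch label.
#' @param range numeric length-2, default `c(0, 350)` ms.
#' @param width bin width (ms), default 10; must divide the range length.
#' @return an object of class `ioi_distribution`: list with `day`, `breaks`
#'   (length nbins + 1), `counts`, `probs` (NULL when empty), `n` (retained
#'   sample size) and `values` (the retained raw values, kept for kernel
#'   smoothing).
#' @export
daily_distribution <- function(values, day = NA_integer_,
                               range = c(0, 350), width = 10) {
  stopifnot(length(range) == 2, range[2] > range[1], width > 0)
  nbins <- (range[2] - range[1]) / width
  if (abs(nbins - round(nbins)) > 1e-9) {
    stop("bin width must divide the range length")
  }
  nbins <- as.integer(round(nbins))
  values <- values[is.finite(values)]
  keep <- values >= range[1] & values <= range[2]
  v <- values[keep]
  idx <- pmin(floor((v - range[1]) / width), nbins - 1) + 1L
  counts <- tabulate(idx, nbins)
  n <- length(v)
  structure(list(day = day,
                 breaks = seq(range[1], range[2], by = width),
                 counts = counts,
                 probs = if (n > 0) counts / n else NULL,
                 n = n, values = v),
            class = "ioi_distribution")
}

#' @export
print.ioi_distribution <- function(x, ...) {
  cat(sprintf("<ioi_distribution> day %s: n = %d over [%g, %g] ms, %d bins\n",
              x$day, x$n, min(x$breaks), max(x$breaks),
              length(x$counts)))
  invisible(x)
}

#' Per-day interval distributions of a dataset
#'
#' Pools all recordings of each calendar recording day and bins the pooled
#' values with [daily_distribution()].
#'
#' @param ds a [song_dev()] dataset.
#' @param feature `"ioi"` (default), `"duration"` or `"gap"`.
#' @param order IOI order (ignored for other features).
#' @inheritParams daily_distribution
#' @return named list of `ioi_distribution` objects, one per recording day,
#'   names = day.
#' @export
daily_distributions <- function(ds, feature = "ioi", order = 1,
                                range = c(0, 350), width = 10) {
  vals <- .feature_values(ds, feature, order)
  days <- sort(unique(ds$notes$day))
  out <- lapply(days, function(d) {
    daily_distribution(vals$value[vals$day == d], day = d,
                       range = range, width = width)
  })
  names(out) <- days
  out
}

#' Build a developmental landscape
#'
#' Joint probability histogram of (development, interval value): each
#' retained feature value contributes one count at (its recording's position
#' on the development axis, its value in ms); the matrix is normalized by
#' the total count so it sums to one. With the default 300 x 300 binning
#' and the IOI feature this is the "rhythm landscape" visualization;
#' `feature = "duration"` and `"gap"` give the note-duration and silent-gap
#' landscapes built in the same manner.
#'
#' @param ds a [song_dev()] dataset.
#' @param feature `"ioi"`, `"duration"` or `"gap"`.
#' @param bins length-2 integer (development bins, value bins), default
#'   `c(300, 300)`. This binning is for visualization; quantitative analyses
#'   use [daily_distributions()].
#' @param axis `"recording"` (serial recording IDs, default) or `"day"`.
#' @param value_range ms range of the value axis, default `c(0, 350)`.
#' @param order IOI order.
#' @return object of class `rhythm_landscape`: list with `x_edges`,
#'   `y_edges`, `matrix` (x bins in rows), `n`, `feature`, `axis`.
#' @export
build_landscape <- function(ds, feature = c("ioi", "duration", "gap"),
                            bins = c(300, 300), axis = c("recording", "day"),
                            value_range = c(0, 350), order = 1) {
  feature <- match.arg(feature)
  axis <- match.arg(axis)
  stopifnot(length(bins) == 2, all(bins >= 1))
  vals <- .feature_values(ds, feature, order)
  x <- if (axis == "recording") as.numeric(vals$recording_id) else
    as.numeric(vals$day)
  y <- vals$value
  keep <- y >= value_range[1] & y <= value_range[2]
  x <- x[keep]; y <- y[keep]
  if (!length(y)) stop("no ", feature, " values available for the landscape")
  xr <- range(x)
  if (xr[1] == xr[2]) xr <- xr + c(-0.5, 0.5)
  x_edges <- seq(xr[1], xr[2], length.out = bins[1] + 1)
  y_edges <- seq(value_range[1], value_range[2], length.out = bins[2] + 1)
  ix <- .bin_index(x, x_edges)
  iy <- .bin_index(y, y_edges)
  m <- matrix(0, nrow = bins[1], ncol = bins[2])
  tab <- table(factor(ix, levels = seq_len(bins[1])),
               factor(iy, levels = seq_len(bins[2])))
  m[] <- as.numeric(tab)
  m <- m / length(y)
  structure(list(x_edges = x_edges, y_edges = y_edges, matrix = m,
                 n = length(y), feature = feature, axis = axis),
            class = "rhythm_landscape")
}

# half-open bins [lo, hi), last bin closed; values assumed inside range
.bin_index <- function(v, edges) {
  pmin(findInterval(v, edges, rightmost.closed = TRUE), length(edges) - 1)
}

#' @export
print.rhythm_landscape <- function(x, ...) {
  cat(sprintf("<rhythm_landscape> %s by %s: %d x %d bins, n = %d\n",
              x$feature, x$axis, nrow(x$matrix), ncol(x$matrix), x$n))
  invisible(x)
}

#' Pseudo-color plot of a landscape
#'
#' Brighter points denote higher density; the development axis is
#' horizontal, the millisecond axis vertical.
#'
#' @param x a `rhythm_landscape`.
#' @param log use log(1 + density) shading to reveal faint bands (default
#'   TRUE).
#' @param ... passed to [graphics::image()].
#' @export
plot.rhythm_landscape <- function(x, log = TRUE, ...) {
  z <- x$matrix
  if (log) z <- log1p(z / max(z) * 1e3)
  graphics::image(x = x$x_edges, y = x$y_edges, z = z,
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = if (x$axis == "recording") "recording ID" else
                    "day post-hatch",
                  ylab = sprintf("%s (ms)", x$feature),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Export a landscape as text
#'
#' Writes the probability matrix as a delimited text file plus a JSON
#' sidecar holding the axes, bin edges and sample size.
#'
#' @param ls a `rhythm_landscape`.
#' @param path matrix file path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(ls, path) {
  stopifnot(inherits(ls, "rhythm_landscape"))
  utils::write.table(ls$matrix, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(feature = ls$feature, axis = ls$axis, n = ls$n,
                            x_edges = ls$x_edges, y_edges = ls$y_edges),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export per-day distributions as TSV
#'
#' @param dists list of `ioi_distribution` (from [daily_distributions()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_distributions <- function(dists, path) {
  rows <- lapply(dists, function(d) {
    k <- length(d$counts)
    data.frame(day = d$day, bin_lo = d$breaks[-(k + 1)],
               bin_hi = d$breaks[-1], count = d$counts,
               prob = if (is.null(d$probs)) rep(NA_real_, k) else d$probs)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
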