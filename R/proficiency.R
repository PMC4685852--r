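#' Kullback-Leibler divergence (base 2)
#'
#' `KL(P || Q) = sum_i p_i log2(p_i / q_i)`, with the usual conventions:
#' terms with `p_i = 0` contribute 0, and any `p_i > 0` where `q_i = 0`
#' makes the divergence `+Inf`.
#'
#' @param p,q probability vectors of equal length, each summing to 1
#'   (within 1e-9).
#' @return non-negative scalar in bits (possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  .check_probs(p, q)
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Jensen-Shannon divergence (base 2)
#'
#' Symmetric, bounded dissimilarity between two probability distributions:
#' `JS(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with the midpoint
#' `M = (P + Q)/2`. With base-2 logarithms `JS` lies in `[0, 1]`, is 0 iff
#' `P = Q`, and is always finite, which makes it suitable as a rhythm
#' proficiency measure: taking `P` as the final-day (crystallized) interval
#' distribution, `JS` shrinks to zero as the developing rhythm `Q`
#' approaches the adult rhythm.
#'
#' @inheritParams kl_divergence
#' @return scalar in `[0, 1]` (bits).
#' @export
js_divergence <- function(p, q) {
  .check_probs(p, q)
  m <- (p + q) / 2
  0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m)
}

.check_probs <- function(p, q) {
  if (length(p) != length(q)) stop("P and Q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("P and Q must each sum to 1")
  }
  invisible(TRUE)
}

#' Rhythm-proficiency trajectory of one bird
#'
#' Jensen-Shannon divergence between each recording day's interval
#' distribution `Q` and the final-day reference distribution `P`, one point
#' per recording day. The reference day itself scores exactly 0. Days with
#' an empty distribution are skipped with a warning.
#'
#' @param ds a [song_dev()] dataset with at least 2 recording days.
#' @param reference_day day whose distribution is the reference `P`;
#'   default `ds$final_day`.
#' @param feature,order,range,width passed to [daily_distributions()].
#' @return object of class `js_trajectory`: data.frame with columns `day`,
#'   `js`, `n` (day sample size), attributes `bird_id` and `reference_day`.
#' @export
js_trajectory <- function(ds, reference_day = NULL, feature = "ioi",
                          order = 1, range = c(0, 350), width = 10) {
  stopifnot(inherits(ds, "song_dev"))
  dists <- daily_distributions(ds, feature = feature, order = order,
                               range = range, width = width)
  if (length(dists) < 2) stop("need at least 2 recording days")
  if (is.null(reference_day)) reference_day <- ds$final_day
  ref <- dists[[as.character(reference_day)]]
  if (is.null(ref) || ref$n == 0) {
    stop("reference day ", reference_day, " has no interval distribution")
  }
  rows <- lapply(dists, function(d) {
    if (d$n == 0) {
      warning("day ", d$day, " has an empty distribution; skipped")
      return(NULL)
    }
    data.frame(day = d$day,
               js = if (d$day == reference_day) 0 else
                 js_divergence(ref$probs, d$probs),
               n = d$n)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  structure(out, class = c("js_trajectory", "data.frame"),
            bird_id = ds$bird_id, reference_day = reference_day)
}

#' Per-decade means of a trajectory
#'
#' Bins trajectory points into `window`-day windows from `start` days
#' post-hatch and averages within each. The reference-day point (exactly 0
#' by construction) is excluded by default so late decades reflect the
#' sampling floor rather than the self-comparison.
#'
#' @param traj a `js_trajectory`.
#' @param window window length in days (default 10).
#' @param start first window start (default 40).
#' @param include_reference keep the reference-day point (default FALSE).
#' @return data.frame with columns `decade` (window start), `mid` (window
#'   midpoint), `mean_js`, `n_days`.
#' @export
decade_means <- function(traj, window = 10, start = 40,
                         include_reference = FALSE) {
  stopifnot(inherits(traj, "js_trajectory"))
  pts <- as.data.frame(traj)
  if (!include_reference) {
    pts <- pts[pts$day != attr(traj, "reference_day"), , drop = FALSE]
  }
  pts <- pts[pts$day >= start, , drop = FALSE]
  if (!nrow(pts)) {
    return(data.frame(decade = numeric(), mid = numeric(),
                      mean_js = numeric(), n_days = integer()))
  }
  pts$decade <- start + floor((pts$day - start) / window) * window
  agg <- stats::aggregate(js ~ decade, data = pts, FUN = mean)
  cnt <- stats::aggregate(js ~ decade, data = pts, FUN = length)
  data.frame(decade = agg$decade, mid = agg$decade + window / 2,
             mean_js = agg$js, n_days = cnt$js)
}

#' Within-day divergence between two clock windows
#'
#' Jensen-Shannon divergence between the interval distributions of two
#' wall-clock windows of the same recording day, for quantifying rapid
#' (hour-scale) song changes.
#'
#' @param ds a [song_dev()] dataset whose notes carry clock hours.
#' @param day recording day to analyse.
#' @param window_a,window_b numeric length-2 clock intervals in hours,
#'   half-open `[from, to)`.
#' @param order,range,width passed to the interval distributions.
#' @return scalar JS divergence (bits).
#' @export
js_window <- function(ds, day, window_a, window_b, order = 1,
                      range = c(0, 350), width = 10) {
  stopifnot(inherits(ds, "song_dev"),
            length(window_a) == 2, length(window_b) == 2)
  iois <- compute_iois(ds, order = order)
  iois <- iois[iois$day == day, , drop = FALSE]
  pick <- function(w, label) {
    v <- iois$value[!is.na(iois$hour) & iois$hour >= w[1] & iois$hour < w[2]]
    d <- daily_distribution(v, day = day, range = range, width = width)
    if (d$n == 0) {
      stop(sprintf("clock window [%g, %g) on day %s contains no intervals",
                   w[1], w[2], day))
    }
    d
  }
  a <- pick(window_a, "a")
  b <- pick(window_b, "b")
  js_divergence(a$probs, b$probs)
}

#' Fit an exponential decay to decade means
#'
#' Least-squares fit of `y = a * exp(-b * x)` with `b >= 0`, `x` in days
#' post-hatch. The decay rate is found deterministically: a coarse grid on
#' `b` (with the amplitude profiled out in closed form) picks the basin,
#' then a golden-section refinement polishes it; the result is invariant to
#' the ordering of the input points.
#'
#' @param x numeric days (e.g. decade midpoints).
#' @param y positive mean JS values.
#' @param b_grid candidate decay rates for the coarse scan (default
#'   `seq(0, 0.3, 5e-4)` per day).
#' @return object of class `exp_fit`: list with `a`, `b`, `chi2` (sum of
#'   squared residuals), `n`, `fitted` (in the sorted-x order), `x`, `y`.
#' @export
fit_exponential <- function(x, y, b_grid = seq(0, 0.3, by = 5e-4)) {
  stopifnot(length(x) == length(y))
  ord <- order(x)
  x <- as.numeric(x)[ord]; y <- as.numeric(y)[ord]
  if (length(x) < 3) stop("need at least 3 points")
  if (all(y == 0)) stop("degenerate input: all y are zero")
  if (any(y < 0)) stop("y must be non-negative")
  amp <- function(b) {
    e <- exp(-b * x)
    sum(y * e) / sum(e * e)
  }
  rss <- function(b) {
    a <- amp(b)
    sum((y - a * exp(-b * x))^2)
  }
  r <- vapply(b_grid, rss, numeric(1))
  i <- which.min(r)
  lo <- b_grid[max(1, i - 1)]; hi <- b_grid[min(length(b_grid), i + 1)]
  opt <- stats::optimize(rss, lower = lo, upper = hi, tol = 1e-12)
  b <- max(0, opt$minimum)
  if (rss(b_grid[i]) < rss(b)) b <- b_grid[i]  # guard against edge basins
  a <- amp(b)
  structure(list(a = a, b = b, chi2 = rss(b), n = length(x),
                 fitted = a * exp(-b * x), x = x, y = y),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> y = %.4g * exp(-%.4g x), chi2 = %.3g (n = %d)\n",
              x$a, x$b, x$chi2, x$n))
  invisible(x)
}

#' Locate the crystallization decade of a cohort
#'
#' Paired two-sided t-test of each decade's per-bird mean JS values against
#' the reference decade (by default the last decade with data), at
#' `alpha = 0.01`. The crystallization decade is the earliest decade from
#' which every comparison up to the reference is non-significant: from that
#' point on the interval distributions no longer move measurably toward the
#' adult rhythm.
#'
#' @param decade_values data.frame with columns `bird`, `decade`, `value`
#'   (per-bird per-decade mean JS, e.g. stacked [decade_means()] outputs).
#' @param reference_decade reference decade start day; default the maximum
#'   decade present.
#' @param alpha significance level (default 0.01).
#' @return list with `table` (data.frame decade, n_pairs, mean_value,
#'   mean_reference, t, p, significant) and `crystallization_decade`
#'   (NA when no decade qualifies or comparisons are undefined).
#' @export
crystallization_test <- function(decade_values, reference_decade = NULL,
                                 alpha = 0.01) {
  stopifnot(all(c("bird", "decade", "value") %in% names(decade_values)))
  if (is.null(reference_decade)) {
    reference_decade <- max(decade_values$decade)
  }
  ref <- decade_values[decade_values$decade == reference_decade, ]
  decades <- sort(unique(decade_values$decade))
  decades <- decades[decades != reference_decade]
  rows <- lapply(decades, function(d) {
    cur <- decade_values[decade_values$decade == d, ]
    both <- intersect(cur$bird, ref$bird)
    if (length(both) < 2) {
      return(data.frame(decade = d, n_pairs = length(both),
                        mean_value = if (nrow(cur)) mean(cur$value) else NA,
                        mean_reference = if (nrow(ref)) mean(ref$value) else NA,
                        t = NA_real_, p = NA_real_, significant = NA))
    }
    a <- cur$value[match(both, cur$bird)]
    b <- ref$value[match(both, ref$bird)]
    if (isTRUE(all.equal(a, b))) {  # identical values: trivially n.s.
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    data.frame(decade = d, n_pairs = length(both), mean_value = mean(a),
               mean_reference = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value <= alpha)
  })
  tab <- do.call(rbind, rows)
  crys <- NA_real_
  if (nrow(tab) && !any(is.na(tab$significant))) {
    ok <- rev(cumprod(rev(!tab$significant))) == 1  # all later n.s. too
    if (any(ok)) crys <- tab$decade[which(ok)[1]]
  }
  list(table = tab, crystallization_decade = crys,
       reference_decade = reference_decade, alpha = alpha)
}
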