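test_that("KL divergence follows the standard conventions", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.3, 0.2)), "equal length")
  expect_error(kl_divergence(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
})

test_that("JS divergence is symmetric, bounded and matches hand values", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  # hand evaluation of JS([1,0],[.5,.5]) in bits
  hand <- 0.5 * log2(4 / 3) + 0.5 * (0.5 * log2(2 / 3) + 0.5 * log2(2))
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), hand)
  expect_lt(abs(hand - 0.3113), 1e-4)

  set.seed(13)
  for (i in 1:200) {
    p <- random_probs(); q <- random_probs()
    expect_identical(js_divergence(p, q), js_divergence(q, p))
    v <- js_divergence(p, q)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_lt(abs(v - brute_force_js(p, q)), 1e-12)
  }
})

test_that("the square root of JS behaves like a metric on random triples", {
  set.seed(17)
  for (i in 1:100) {
    p <- random_probs(); q <- random_probs(); r <- random_probs()
    d <- function(a, b) sqrt(js_divergence(a, b))
    expect_lte(d(p, r), d(p, q) + d(q, r) + 1e-12)
  }
})

test_that("JS trajectories measure dissimilarity to the final day", {
  # identical interval samples on every day: flat zero trajectory
  ds <- flat_dataset(rep(c(100, 150), 30), days = c(50, 60, 70, 80))
  traj <- js_trajectory(ds)
  expect_equal(traj$js, rep(0, 4))
  expect_equal(attr(traj, "reference_day"), 80)

  # two-day dataset: the single point equals a direct JS computation
  set.seed(3)
  v1 <- runif(300, 40, 340); v2 <- runif(300, 40, 340)
  notes <- rbind(make_notes(cumsum(c(0, v1)), recording_id = 1, day = 50),
                 make_notes(cumsum(c(0, v2)), recording_id = 2, day = 90))
  ds2 <- song_dev(notes)
  traj2 <- js_trajectory(ds2)
  direct <- js_divergence(daily_distribution(v2)$probs,
                          daily_distribution(v1)$probs)
  expect_equal(traj2$js[traj2$day == 50], direct)
  expect_equal(traj2$js[traj2$day == 90], 0)

  expect_error(js_trajectory(flat_dataset(c(100, 100), days = 50)),
               "at least 2")
})

test_that("decade means bin points from day 40 and drop the reference", {
  ds <- flat_dataset(rep(c(100, 150), 30), days = c(44, 48, 52, 90))
  dm <- decade_means(js_trajectory(ds))
  expect_equal(dm$decade, c(40, 50))  # reference day 90 excluded
  expect_equal(dm$n_days, c(2L, 1L))
  dm2 <- decade_means(js_trajectory(ds), include_reference = TRUE)
  expect_equal(dm2$decade, c(40, 50, 90))
})

test_that("annealing toward a fixed mixture gives non-increasing decades", {
  bands <- list(
    band_spec(1L, 40, "founder", birth_position = 120, sd_start = 45,
              sd_end = 8, anneal_rate = 0.05),
    band_spec(2L, 40, "founder", birth_position = 240, sd_start = 45,
              sd_end = 8, anneal_rate = 0.05))
  sim <- simulate_development(sim_config(bands, seed = 99))
  dm <- decade_means(js_trajectory(filter_notes(sim$dataset)))
  expect_true(all(diff(dm$mean_js) <= 0.01))
})

test_that("clock-window divergences compare within-day distributions", {
  n <- make_notes(cumsum(c(0, rep(100, 200))), recording_id = 1, day = 60,
                  hour = 9)
  n2 <- make_notes(cumsum(c(0, rep(250, 200))), recording_id = 2, day = 60,
                   hour = 15)
  ds <- song_dev(rbind(n, n2))
  expect_equal(js_window(ds, 60, c(9, 10), c(9, 10)), 0)
  expect_equal(js_window(ds, 60, c(9, 10), c(15, 16)), 1)
  expect_error(js_window(ds, 60, c(9, 10), c(11, 12)), "no intervals")
})

test_that("a planted within-day weight step raises the window divergence", {
  bands <- list(
    band_spec(1L, 40, "founder", birth_position = 120, sd_start = 10),
    band_spec(2L, 40, "founder", birth_position = 240, sd_start = 10))
  cfg <- sim_config(bands, recording_days = seq(40, 60, 4),
                    notes_per_day = 4000, seed = 7,
                    hourly_step = list(day = 52, hour = 13,
                                       weight_mult = c(`1` = 0.2, `2` = 5)))
  sim <- simulate_development(cfg)
  ds <- filter_notes(sim$dataset)
  js_step <- js_window(ds, 52, c(6, 13), c(13, 20))
  js_null <- js_window(ds, 48, c(6, 13), c(13, 20))
  expect_gt(js_step, js_null)
})

test_that("exponential fits recover planted decay parameters", {
  x <- seq(40, 130, 10)
  fit <- fit_exponential(x, 0.97 * exp(-0.03 * x))
  expect_lt(abs(fit$a - 0.97), 1e-6)
  expect_lt(abs(fit$b - 0.03), 1e-6)
  expect_lt(fit$chi2, 1e-12)

  # constant series: zero decay at the constant amplitude
  flat <- fit_exponential(x, rep(0.4, length(x)))
  expect_equal(flat$b, 0)
  expect_equal(flat$a, 0.4)

  # residual is invariant to point order
  set.seed(2)
  y <- 0.8 * exp(-0.05 * x) + rnorm(length(x), 0, 0.02)
  y <- pmax(y, 1e-4)
  f1 <- fit_exponential(x, y)
  idx <- sample(length(x))
  f2 <- fit_exponential(x[idx], y[idx])
  expect_equal(f1$chi2, f2$chi2)
  expect_equal(f1$b, f2$b)

  expect_error(fit_exponential(x[1:2], c(1, 2)), "at least 3")
  expect_error(fit_exponential(x, rep(0, length(x))), "degenerate")
})

test_that("crystallization is the earliest stably non-significant decade", {
  # identical values everywhere: nothing ever differs
  dv <- expand.grid(bird = paste0("b", 1:5), decade = seq(40, 130, 10))
  dv$value <- 0.02
  ct <- crystallization_test(dv)
  expect_true(all(!ct$table$significant))
  expect_equal(ct$crystallization_decade, 40)

  # planted flattening: early decades high, late at a common floor
  set.seed(23)
  dv2 <- expand.grid(bird = paste0("b", 1:12), decade = seq(40, 130, 10))
  dv2$value <- ifelse(dv2$decade < 90, 0.4 - 0.003 * dv2$decade, 0.02) +
    rnorm(nrow(dv2), 0, 0.002)
  ct2 <- crystallization_test(dv2)
  expect_equal(ct2$crystallization_decade, 90)
  expect_true(all(ct2$table$significant[ct2$table$decade < 90]))

  # a single bird leaves every comparison undefined
  one <- dv[dv$bird == "b1", ]
  ct3 <- crystallization_test(one)
  expect_true(all(is.na(ct3$table$p)))
  expect_true(is.na(ct3$crystallization_decade))
})
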