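test_that("kernel smoothing recovers planted modes", {
  # point mass: maximum at the common value, within grid resolution
  d <- smooth_distribution(daily_distribution(rep(100, 50), day = 50))
  expect_lte(abs(d$grid[which.max(d$density)] - 100), 1)

  set.seed(21)
  d1 <- smooth_distribution(rnorm(5000, 100, 10))
  expect_lte(abs(d1$grid[which.max(d1$density)] - 100), 3)

  d2 <- smooth_distribution(c(rnorm(2500, 100, 10), rnorm(2500, 250, 10)))
  b <- detect_bands(d2)
  expect_equal(nrow(b), 2)
  expect_lte(abs(b$position[1] - 100), 5)
  expect_lte(abs(b$position[2] - 250), 5)

  expect_error(smooth_distribution(daily_distribution(100)), "at least 2")
  # density integrates to ~1 over the range
  expect_lt(abs(sum(d1$density) * 1 - 1), 0.02)
})

test_that("band detection uses strict interior maxima with prominence", {
  # monotone decreasing curve: no interior band by default
  mono <- curve_density(rev(seq_len(351)) / sum(seq_len(351)))
  expect_equal(nrow(detect_bands(mono)), 0)
  expect_equal(detect_bands(mono, include_endpoints = TRUE)$position, 0)

  # plateau maxima are reported at the plateau midpoint
  y <- stats::dnorm(0:350, 120, 20)
  y[119:123] <- max(y)   # flat top covering 118-122 ms
  plat <- curve_density(y)
  expect_equal(detect_bands(plat)$position, 120)

  # raising the prominence threshold never increases the band count
  set.seed(5)
  noisy <- smooth_distribution(runif(400, 0, 350), bandwidth = 4)
  n0 <- nrow(detect_bands(noisy, min_prominence = 0))
  n05 <- nrow(detect_bands(noisy, min_prominence = 0.05))
  n2 <- nrow(detect_bands(noisy, min_prominence = 0.2))
  expect_gte(n0, n05)
  expect_gte(n05, n2)

  expect_error(detect_bands(curve_density(c(0, 0, 0))), "degenerate")
})

test_that("small shoulder peaks are pruned by prominence, not height", {
  # a high shoulder wiggle: tall in absolute height, tiny in prominence
  y <- stats::dnorm(0:350, 150, 25)
  y[160] <- y[160] * 1.01
  b <- detect_bands(curve_density(y), min_prominence = 0.05)
  expect_equal(nrow(b), 1)
  expect_lte(abs(b$position - 150), 2)
})

test_that("band counts average per bird within 10-day windows", {
  b1 <- data.frame(bird = "b1", day = 45, position = c(100, 150, 200))
  expect_equal(count_bands_by_decade(b1)$mean_bands, 3)
  expect_equal(count_bands_by_decade(b1)$decade, 40)

  b2 <- rbind(data.frame(bird = "b", day = 41, position = c(1, 2)),
              data.frame(bird = "b", day = 48, position = c(1, 2, 3, 4)))
  expect_equal(count_bands_by_decade(b2)$mean_bands, 3)

  # missing windows are absent, not zero
  b3 <- data.frame(bird = "b", day = c(45, 95), position = 100)
  out <- count_bands_by_decade(b3)
  expect_equal(out$decade, c(40, 90))
})

test_that("band tracking links nearest neighbours and flags new bands", {
  b <- data.frame(day = c(50, 54), position = c(100, 100))
  tr <- track_bands(b)
  expect_equal(length(unique(tr$tracks$track_id)), 1)
  expect_equal(nrow(tr$events), 0)

  b2 <- data.frame(day = c(50, 54, 54), position = c(100, 98, 130))
  tr2 <- track_bands(b2)
  expect_equal(nrow(tr2$events), 1)
  expect_equal(tr2$events$new_position, 130)
  # the stem is read off the PRIOR recording day, where the only band is 100
  expect_equal(tr2$events$stem_position, 100)
  expect_equal(tr2$events$distance, 30)
  cont <- tr2$tracks[tr2$tracks$track_id == 1, ]
  expect_equal(cont$position, c(100, 98))
})

test_that("band tracking is invariant to within-day band order", {
  set.seed(31)
  days <- seq(40, 80, 4)
  bands <- do.call(rbind, lapply(days, function(d) {
    data.frame(day = d, position = sort(runif(3, 50, 300)))
  }))
  ref <- track_bands(bands)
  shuf <- bands[sample(nrow(bands)), ]
  expect_equal(track_bands(shuf), ref)
})

test_that("two converging bands merge deterministically", {
  b <- data.frame(day = c(50, 50, 54), position = c(100, 120, 108))
  tr <- track_bands(b)
  # 108 links to 100? no: nearest is 108-100=8 vs 120-108=12 -> track 1
  linked <- tr$tracks$track_id[tr$tracks$day == 54]
  expect_equal(linked, 1L)
  expect_equal(nrow(tr$events), 0)
})

test_that("stems are the nearest prior-day maxima, ties to the left", {
  ev <- data.frame(day = 54, track_id = 9L, new_position = 130,
                   stem_position = NA_real_, distance = NA_real_,
                   unassignable = FALSE)
  dens <- list(`50` = bump_density(c(110, 200)),
               `54` = bump_density(c(110, 130, 200)))
  out <- assign_stem(ev, dens)
  expect_equal(out$stem_position, 110)
  expect_equal(out$distance, 20)

  dens1 <- list(`50` = bump_density(120), `54` = bump_density(c(120, 260)))
  ev$new_position <- 260
  out1 <- assign_stem(ev, dens1)
  expect_equal(out1$stem_position, 120)
  expect_equal(out1$distance, 140)

  # equidistant maxima: smaller position wins
  dens2 <- list(`50` = bump_density(c(100, 160), sd = 6))
  ev$new_position <- 130
  out2 <- assign_stem(ev, dens2)
  expect_equal(out2$stem_position, 100)
  expect_equal(out2$distance, 30)

  # no prior day: unassignable
  ev2 <- ev
  ev2$day <- 50
  expect_true(assign_stem(ev2, dens2)$unassignable)
})

test_that("branching needs a filled valley and a nearby stem", {
  ev <- data.frame(day = 54, track_id = 2L, new_position = 130,
                   stem_position = 110, distance = 20,
                   unassignable = FALSE)
  # overlapping bumps: valley stays high -> branching
  dens <- list(`54` = bump_density(c(110, 130), sd = 12))
  expect_equal(classify_emergence(ev, dens)$class, "branching")

  # deep valley between distant narrow bumps -> other
  ev$new_position <- 250; ev$stem_position <- 110; ev$distance <- 140
  dens2 <- list(`54` = bump_density(c(110, 250), sd = 8))
  expect_equal(classify_emergence(ev, dens2)$class, "other")

  # zero distance is trivially branching
  ev$new_position <- 110; ev$distance <- 0
  expect_equal(classify_emergence(ev, dens2)$class, "branching")

  # events at or beyond the day limit are excluded
  ev$day <- 85
  expect_equal(nrow(classify_emergence(ev, dens2)), 0)
})

test_that("raising the valley ratio never adds branching labels", {
  set.seed(8)
  sim <- simulate_development(preset_bengalese(seed = 8))
  ds <- filter_notes(sim$dataset)
  db <- daily_bands(ds)
  tr <- track_bands(db$bands)
  ev <- assign_stem(tr$events, db$densities)
  n_br <- vapply(c(0.2, 0.5, 0.9), function(vr) {
    cl <- classify_emergence(ev, db$densities, valley_ratio = vr)
    sum(cl$class == "branching", na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(n_br) <= 0))
})

test_that("emergence statistics summarise both classes and compare them", {
  ev <- data.frame(day = c(60, 64, 62, 70),
                   distance = c(20, 30, 70, 90),
                   class = c("branching", "branching", "other", "other"))
  st <- emergence_statistics(ev)
  expect_equal(st$by_class$distance_mean[st$by_class$class == "branching"],
               25)
  expect_equal(st$by_class$distance_mean[st$by_class$class == "other"], 80)
  expect_s3_class(st$tests$distance, "htest")

  single <- ev[1, ]
  st1 <- emergence_statistics(single)
  expect_equal(nrow(st1$by_class), 1)
  expect_null(st1$tests)

  expect_error(emergence_statistics(data.frame(day = 1, distance = 1,
                                               class = NA_character_)),
               "no classified")
})

test_that("interval-window use rates count order-k IOIs per recording", {
  ds <- flat_dataset(c(130, 133, 150, 131), days = 50)
  ur <- band_usage_rate(ds, 132, 4)
  expect_equal(ur$rate, 0.75)

  # a window covering the whole range scores 1 everywhere
  ds2 <- random_dataset(4)
  ur2 <- band_usage_rate(ds2, 175, 175)
  expect_true(all(ur2$rate == 1))

  # order-2 window: chunk-level interval between first and last onsets
  ds3 <- song_dev(make_notes(c(0, 80, 160, 400)))
  ur3 <- band_usage_rate(ds3, 160, 4, order = 2)
  expect_equal(ur3$rate, 0.5)
  expect_equal(ur3$n, 2)

  by_day <- attr(band_usage_rate(ds2, 100, 20), "by_day")
  expect_true(all(c("day", "mean", "sd", "n_recordings") %in%
                    names(by_day)))
  expect_error(band_usage_rate(ds2, 340, 20))
})
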