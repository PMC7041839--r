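test_that("triangulation recovers exact line intersections", {
  b <- tibble::tibble(station_id = c("A", "B"), x = c(0, 10), y = c(0, 10),
                      azimuth = c(90, 180))
  p <- triangulate(b)
  expect_equal(p$x, 10, tolerance = 1e-9)
  expect_equal(p$y, 0, tolerance = 1e-9)
  expect_equal(p$source, "triangulated")

  # three consistent bearings through (5, 5)
  st <- tibble::tibble(
    station_id = c("A", "B", "C"),
    x = c(5, 0, 0), y = c(0, 5, 0),
    azimuth = c(0, 90, 45)
  )
  p3 <- triangulate(st)
  expect_equal(c(p3$x, p3$y), c(5, 5), tolerance = 1e-9)
})

test_that("triangulation rejects degenerate input", {
  expect_error(
    triangulate(tibble::tibble(station_id = "A", x = 0, y = 0, azimuth = 10)),
    "insufficient bearings")
  expect_error(
    triangulate(tibble::tibble(station_id = c("A", "B"), x = c(0, 10),
                               y = c(0, 0), azimuth = c(0, 0))),
    "degenerate geometry")
  # opposite azimuths are the same line: still degenerate
  expect_error(
    triangulate(tibble::tibble(station_id = c("A", "B"), x = c(0, 10),
                               y = c(0, 0), azimuth = c(0, 180))),
    "degenerate geometry")
  expect_error(
    triangulate(tibble::tibble(station_id = c("A", "B"), x = c(0, 10),
                               y = c(0, 0), azimuth = c(45, 90),
                               timestamp = as.POSIXct(c("2010-11-01 20:00:00",
                                                        "2010-11-01 20:05:00"),
                                                      tz = "UTC"))),
    "window")
})

test_that("triangulation is invariant to bearing order and translation", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(2:5, 1)
      b <- tibble::tibble(
        station_id = as.character(seq_len(n)),
        x = runif(n, 0, 1000), y = runif(n, 0, 1000),
        azimuth = runif(n, 0, 360)
      )
      p <- tryCatch(triangulate(b), error = function(e) NULL)
      if (is.null(p)) next
      shuf <- b[sample(n), ]
      p2 <- triangulate(shuf)
      expect_equal(c(p$x, p$y), c(p2$x, p2$y), tolerance = 1e-8)
      dx <- 1234.5; dy <- -987.6
      b3 <- dplyr::mutate(b, x = x + dx, y = y + dy)
      p3 <- triangulate(b3)
      expect_equal(c(p3$x, p3$y), c(p$x + dx, p$y + dy), tolerance = 1e-6)
    }
  })
})

test_that("night assignment uses the noon-to-noon convention", {
  expect_equal(assign_night("2010-11-03 22:10:00"), as.Date("2010-11-03"))
  expect_equal(assign_night("2010-11-04 03:00:00"), as.Date("2010-11-03"))
  expect_equal(assign_night("2010-11-04 13:00:00"), as.Date("2010-11-04"))
  expect_equal(assign_night("2010-11-03T22:10"), as.Date("2010-11-03"))
  expect_error(assign_night("not a time"), "unparseable")
  # monotone in time
  ts <- as.POSIXct("2010-11-01 13:00:00", tz = "UTC") + (0:100) * 3600
  expect_true(all(diff(as.numeric(assign_night(ts))) >= 0))
})

test_that("visit assignment applies the minimum-fix threshold", {
  ls <- structure(list(
    sites = tibble::tibble(site_id = c("A", "B"), x = c(0, 1000),
                           y = c(0, 0), radius = 70.7),
    trees = tibble::tibble(site_id = "A", season = "w", species = "d",
                           n_trees = 1L),
    roosts = tibble::tibble(roost_id = "R", x = 500, y = 500),
    extent = c(-100, 1100, -100, 100)
  ), class = "landscape")
  fx <- tibble::tibble(
    bat_id = "b1", night = 1L,
    x = c(0, 5, -5, 1000), y = c(0, 5, 5, 0)
  )
  v <- assign_visits(fx, ls, min_fixes_per_visit = 2)
  expect_equal(nrow(v), 1L)          # three fixes in A, one in B
  expect_equal(v$site_id, "A")
  v1 <- assign_visits(fx, ls, min_fixes_per_visit = 1)
  expect_setequal(v1$site_id, c("A", "B"))
  expect_error(assign_visits(fx, structure(list(sites = tibble::tibble()),
                                           class = "landscape")),
               "empty landscape")
})

test_that("adding fixes never removes a visit (monotonicity at threshold 1)", {
  withr::with_seed(22, s <- sim_season(n_bats = 6, n_nights = 3))
  v_all <- assign_visits(s$fixes, s$landscape, min_fixes_per_visit = 1)
  sub <- s$fixes[seq_len(floor(nrow(s$fixes) / 2)), ]
  v_sub <- assign_visits(sub, s$landscape, min_fixes_per_visit = 1)
  key <- function(v) paste(v$bat_id, v$night, v$site_id)
  expect_true(all(key(v_sub) %in% key(v_all)))
})

test_that("noiseless simulated fixes reproduce the ground-truth visit table", {
  for (seed in 23:25) {
    withr::with_seed(seed, {
      ped <- sim_pedigree(16, 2)
      K <- kinship_matrix(ped)
      bats <- rev(ped$id)[1:8]
      ls <- sim_landscape(default_regimes()$winter, "winter")
      cfg <- sim_config(n_bats = 8, n_nights = 5, fix_noise_sd = 0,
                        n_commute_fixes = 1)
      mv <- sim_movement(ls, K, cfg, "winter", bats = bats)
    })
    v <- assign_visits(mv$fixes, ls, min_fixes_per_visit = 2)
    truth <- dplyr::arrange(mv$visits, bat_id, night, site_id)
    expect_equal(v[, c("bat_id", "night", "site_id")], truth)
  }
})

test_that("tracking effort follows the stated per-night formula", {
  # every bat visits exactly one brand-new site each night
  v <- tidyr::expand_grid(bat_id = c("a", "b"), night = 1:5) |>
    dplyr::mutate(site_id = paste0(bat_id, night))
  eff <- tracking_effort(v)
  expect_equal(eff$mean_new_sites, rep(1, 5))
  expect_equal(eff$p_new_site[5], 0.2)

  # a bat revisiting only night-1 sites contributes 0 new sites later
  v2 <- tibble::tibble(bat_id = "a", night = c(1, 1, 2, 3),
                       site_id = c("s1", "s2", "s1", "s2"))
  eff2 <- tracking_effort(v2)
  expect_equal(eff2$mean_new_sites, c(2, 0, 0))

  # cumulative variant divides mean distinct sites seen so far by t
  effc <- tracking_effort(v, method = "cumulative")
  expect_equal(effc$p_new_site, rep(1, 5))
  expect_error(tracking_effort(v[0, ]), "empty")
})
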