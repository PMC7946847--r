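# Scoring: accuracy cells, the ascending criterion rule, window geometry.

test_that("accuracy cells pool the diagonals and use exact fractions", {
  trials <- generate_session(awt_config(), seed = 6)
  rec <- trials
  rec$correct <- rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                     length.out = nrow(rec))
  cells <- score_records(rec)
  expect_setequal(unique(cells$meridian_class),
                  c("horizontal", "vertical", "diagonal"))
  expect_true(all(cells$n_trials[cells$meridian_class == "diagonal"] == 18))
  expect_true(all(cells$n_trials[cells$meridian_class != "diagonal"] == 9))
  expect_equal(cells$accuracy, cells$n_correct / cells$n_trials)
  # 7 of 9 correct is 0.7778, above the inclusive criterion
  expect_equal(round(7 / 9, 4), 0.7778)
  all_correct <- score_records(dplyr::mutate(rec, correct = TRUE))
  expect_true(all(all_correct$accuracy == 1))
})

test_that("the ascending rule reproduces the worked example and censoring", {
  grid <- seq(10, 45, by = 5)
  # above criterion through 25, first failure at 30 -> threshold 25
  acc <- c(0.95, 0.9, 0.85, 0.78, 0.60, 0.9, 0.5, 0.4)
  expect_equal(estimate_threshold(acc, grid)$threshold_deg, 25)
  expect_equal(estimate_threshold(acc, grid)$censoring, "none")
  # no failure anywhere: ceiling at the largest tested separation
  ceiling_case <- estimate_threshold(rep(0.8, 8), grid)
  expect_equal(ceiling_case$threshold_deg, 45)
  expect_equal(ceiling_case$censoring, "ceiling")
  # failure already at 10: floor, kept numeric at 0
  floor_case <- estimate_threshold(c(0.5, rep(0.9, 7)), grid)
  expect_equal(floor_case$threshold_deg, 0)
  expect_equal(floor_case$censoring, "floor")
  # first-failure rule ignores later recoveries
  recov <- c(0.9, 0.85, 0.6, 0.9, 0.9, 0.9, 0.9, 0.9)
  expect_equal(estimate_threshold(recov, grid)$threshold_deg, 15)
  # the criterion is inclusive: exactly 0.75 passes
  exact <- estimate_threshold(c(0.75, 0.75, 0.5, rep(0.9, 5)), grid)
  expect_equal(exact$threshold_deg, 15)
})

test_that("threshold estimation is gap-intolerant unless told otherwise", {
  grid <- seq(10, 45, by = 5)
  cells <- tibble::tibble(
    subject = "s01", meridian_class = "horizontal",
    separation_deg = grid[-3], n_trials = 9, n_correct = 9,
    accuracy = 1
  )
  expect_error(estimate_thresholds(cells, separations = grid), "full separation grid")
  dropped <- estimate_thresholds(cells, separations = grid, on_missing = "drop")
  expect_equal(dropped$threshold_deg, 45)
})

test_that("raising accuracy never lowers the threshold", {
  grid <- seq(10, 45, by = 5)
  set.seed(12)
  for (i in 1:50) {
    acc <- runif(8, 0.4, 1)
    base <- estimate_threshold(acc, grid)$threshold_deg
    j <- sample(8, 1)
    up <- acc
    up[j] <- min(1, up[j] + runif(1, 0, 0.5))
    expect_gte(estimate_threshold(up, grid)$threshold_deg, base)
  }
})

test_that("pooled and unpooled thresholds agree when diagonals are identical", {
  trials <- generate_session(awt_config(), seed = 14)
  # correctness depends only on separation -> both diagonals identical
  rec <- dplyr::mutate(trials, correct = separation_deg <= 30)
  pooled <- estimate_thresholds(score_records(rec))
  raw <- estimate_thresholds(score_records(rec, pool_diagonals = FALSE))
  expect_equal(pooled$threshold_deg[pooled$meridian_class == "diagonal"],
               unique(raw$threshold_deg[grepl("diagonal", raw$meridian_class)]))
  expect_equal(nrow(raw), 4)
})

test_that("window geometry matches the closed-form octagon oracle", {
  # equal thresholds: regular octagon with circumradius R = 40/2
  aw <- build_attention_window(
    c(horizontal = 40, vertical = 40, diagonal = 40))
  expect_equal(aw$polygon_area_deg2, 2 * sqrt(2) * 20^2, tolerance = 1e-12)
  # mixed thresholds: shoelace equals (sin 45 / 2) * sum(r_i r_{i+1})
  aw2 <- build_attention_window(
    c(horizontal = 40, vertical = 20, diagonal = 30))
  r <- aw2$vertices$radius_deg
  expect_equal(r, c(20, 15, 10, 15, 20, 15, 10, 15))
  oracle <- sin(pi / 4) / 2 * sum(r * r[c(2:8, 1)])
  expect_equal(aw2$polygon_area_deg2, oracle, tolerance = 1e-12)
  expect_equal(aw2$polygon_area_deg2, 636.3961, tolerance = 1e-4)
  expect_equal(aw2$ellipse_area_deg2, pi * 10 * 5)
  expect_equal(aw2$aspect_ratio, 2)
  # random thresholds obey the same identity
  set.seed(3)
  for (i in 1:20) {
    thr <- stats::runif(4, 0, 45)
    names(thr) <- c("horizontal", "vertical", "diagonal1", "diagonal2")
    w <- build_attention_window(thr)
    rr <- w$vertices$radius_deg
    expect_equal(w$polygon_area_deg2,
                 sin(pi / 4) / 2 * sum(rr * rr[c(2:8, 1)]),
                 tolerance = 1e-9)
  }
})

test_that("degenerate and invalid windows are handled", {
  zero <- build_attention_window(c(horizontal = 0, vertical = 0, diagonal = 0))
  expect_equal(zero$polygon_area_deg2, 0)
  expect_true(is.na(zero$aspect_ratio))
  expect_error(build_attention_window(c(horizontal = -1, vertical = 10,
                                        diagonal = 10)), "non-negative")
  expect_error(build_attention_window(c(horizontal = 10)), "must name")
})

test_that("window tidiers and plot return the expected shapes", {
  aw <- build_attention_window(c(horizontal = 40, vertical = 20, diagonal = 30))
  td <- generics::tidy(aw)
  expect_equal(nrow(td), 8)
  expect_true(all(c("angle_deg", "radius_deg", "x", "y") %in% names(td)))
  gl <- generics::glance(aw)
  expect_equal(nrow(gl), 1)
  p <- ggplot2::autoplot(aw)
  expect_s3_class(p, "ggplot")
})
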