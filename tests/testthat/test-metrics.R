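test_that("Feret diameter follows the pixel-center convention", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(feret_diameter(m1), 0)

  m2 <- matrix(FALSE, 3, 13); m2[2, 2:12] <- TRUE
  expect_equal(feret_diameter(m2, pixel_size = 1), 10)
  expect_equal(feret_diameter(m2, pixel_size = 0.5), 5)

  expect_error(feret_diameter(matrix(FALSE, 3, 3)), "nonempty")
})

test_that("caliper Feret equals the brute-force pairwise maximum", {
  withr::with_seed(101, {
    for (i in 1:100) {
      m <- random_connected_mask(n_steps = sample(5:80, 1))
      expect_identical(feret_diameter(m, 1), feret_brute_force(m, 1))
    }
  })
})

test_that("ring width is half the Feret difference", {
  expect_equal(ring_width(list(outer_feret = 40, inner_feret = 30)), 5)
  expect_equal(ring_width(list(outer_feret = 30, inner_feret = 30)), 0)
  expect_error(ring_width(list(outer_feret = 20, inner_feret = 30)), "invariant")
})

test_that("ring mean intensity is the annulus mean", {
  d <- 41; cen <- 21
  r <- sqrt(outer((1:d - cen)^2, (1:d - cen)^2, "+"))
  inner <- r <= 8; outer <- r <= 14

  geom <- list(inner_mask = inner, outer_mask = outer)
  fr7 <- matrix(7, d, d)
  expect_equal(ring_mean_intensity(fr7, geom), 7)

  fr10 <- matrix(0, d, d); fr10[outer & !inner] <- 10
  expect_equal(ring_mean_intensity(fr10, geom), 10)

  frr <- withr::with_seed(5, matrix(runif(d * d), d, d))
  expect_equal(ring_mean_intensity(frr, geom), mean(frr[outer & !inner]))

  expect_error(ring_mean_intensity(fr7, list(inner_mask = inner, outer_mask = inner)),
               "exceed")
})

test_that("unwounded baseline is the centered 50x50 window mean", {
  expect_equal(uw_baseline(matrix(12, 60, 60)), 12)

  fr <- matrix(0, 100, 100)
  fr[26:75, 26:75] <- 100
  expect_equal(uw_baseline(fr), 100)

  frr <- withr::with_seed(9, matrix(runif(120 * 80), 120, 80))
  expect_equal(uw_baseline(frr), mean(frr[36:85, 16:65]))

  expect_error(uw_baseline(matrix(1, 40, 60)), "smaller")
})

test_that("relative ring intensity divides by the baseline", {
  expect_equal(relative_ring_intensity(rep(10, 4), 10), rep(1, 4))
  expect_equal(relative_ring_intensity(c(10, 20), 10), c(1, 2))
  expect_error(relative_ring_intensity(c(1, 2), 0), "positive")
  expect_error(relative_ring_intensity(c(1, 2), -3), "positive")
})

test_that("expansion fold is max area over first post-wound area", {
  tr <- data.frame(frame_time = c(-30, 0, 60, 120, 180),
                   area_um2 = c(0, 100, 140, 120, 60))
  expect_equal(expansion_fold(tr), 1.4)

  closing <- data.frame(frame_time = c(0, 30, 60), area_um2 = c(90, 80, 60))
  expect_equal(expansion_fold(closing), 1)

  expect_error(expansion_fold(data.frame(frame_time = 0, area_um2 = 0)), "area")
})

test_that("t_max and t_half follow the earliest-crossing definitions", {
  tr <- data.frame(frame_time = seq(0, 360, by = 60),
                   area_um2 = c(100, 140, 120, 100, 80, 70, 60))
  tt <- find_tmax_thalf(tr, fraction = 0.5)
  expect_equal(tt$t_max, 60)
  expect_equal(tt$t_half, 300)

  # tie at the maximum: earlier time wins
  tie <- data.frame(frame_time = seq(0, 300, by = 60),
                    area_um2 = c(100, 140, 140, 90, 70, 50))
  expect_equal(find_tmax_thalf(tie)$t_max, 60)

  expect_error(find_tmax_thalf(tr, fraction = 0.2), "fraction")
  flat <- data.frame(frame_time = c(0, 60), area_um2 = c(100, 95))
  expect_error(find_tmax_thalf(flat), "did not contract")
})

test_that("contraction rate is the positive secant slope", {
  tr <- data.frame(frame_time = seq(0, 360, by = 60),
                   area_um2 = c(100, 140, 120, 100, 80, 70, 60))
  expect_equal(contraction_rate(tr, 0.5), (140 - 70) / (300 - 60))

  # instant drop skips the exact half level: first area at or below it counts
  drop <- data.frame(frame_time = c(0, 30, 60), area_um2 = c(100, 140, 60))
  expect_equal(contraction_rate(drop, 0.5), (140 - 60) / 30)
})

test_that("metrics transform correctly under pixel-size and gain changes", {
  p1 <- tiny_wound_params()
  p2 <- tiny_wound_params(pixel_size = 0.44, image_shape = c(64L, 64L))
  s1 <- simulate_wound_stack(p1); s2 <- simulate_wound_stack(p2)
  i <- which(s1$stack$frame_times == 120)

  m1 <- segment_wound(s1$stack$frames[[i]], p1$pixel_size)
  m2 <- segment_wound(s2$stack$frames[[i]], p2$pixel_size)
  # same physical wound measured at two magnifications
  expect_equal(m2$area_um2, m1$area_um2, tolerance = 0.05)

  g1 <- detect_ring_edges(s1$stack$frames[[i]], m1, p1$pixel_size)
  expect_equal(feret_diameter(g1$outer_mask, 2 * p1$pixel_size),
               2 * feret_diameter(g1$outer_mask, p1$pixel_size))

  # intensity gain: ring mean scales, relative intensity does not
  fr <- s1$stack$frames[[i]]
  rmi <- ring_mean_intensity(fr, g1)
  expect_equal(ring_mean_intensity(fr * 3, g1) /
                 uw_baseline(s1$stack$frames[[1]] * 3),
               rmi / uw_baseline(s1$stack$frames[[1]]))
  expect_equal(ring_mean_intensity(fr * 3, g1), 3 * rmi)
})

test_that("summarize_repair recovers all ground-truth metrics when noiseless", {
  p <- tiny_wound_params(expansion_fold_true = 1.5, closure_rate_true = 0.3)
  sim <- simulate_wound_stack(p)
  m <- summarize_repair(sim$stack, ring_series = TRUE)

  expect_equal(m$expansion_fold, 1.5, tolerance = 0.05)
  expect_lt(abs(m$t_max_s - p$t_max_true), 30 + 1e-9) # within one frame
  expect_equal(m$contraction_rate_um2_s, 0.3, tolerance = 0.05)
  expect_lt(abs(m$ring_width_um - p$ring_width_true), p$pixel_size)
  expect_equal(m$relative_ring_intensity,
               sim$truth$implied_relative_ring_intensity, tolerance = 0.05)
  expect_equal(m$uw_baseline, p$cortex_baseline, tolerance = 1e-6)
  # the relative-intensity series exists and is near-constant while open
  rs <- m$relative_ring_intensity_series
  expect_gt(nrow(rs), 3)

  # no-expansion limit
  m1 <- summarize_repair(simulate_wound_stack(tiny_wound_params(
    expansion_fold_true = 1, closure_rate_true = 0.3))$stack,
    ring_series = FALSE)
  expect_equal(m1$expansion_fold, 1, tolerance = 0.05)
})

test_that("summarize_repair requires the pre-wound baseline frame", {
  p <- tiny_wound_params()
  sim <- simulate_wound_stack(p)
  post <- sim$stack$frame_times >= 0
  st <- new_wound_stack(sim$stack$frames[post], sim$stack$frame_times[post],
                        sim$stack$pixel_size)
  expect_error(summarize_repair(st), "uw_baseline")
})

test_that("cohort summary reports mean, SEM and t-test per group", {
  withr::with_seed(3, {
    rows <- do.call(rbind, lapply(1:12, function(i) {
      r <- repair_metrics_row(list(expansion_fold = rnorm(1, 1.4, 0.05),
                                   t_max_s = 60, t_half_s = 300,
                                   contraction_rate_um2_s = rnorm(1, 0.2, 0.02),
                                   ring_width_um = rnorm(1, 2, 0.1),
                                   relative_ring_intensity = rnorm(1, 3, 0.2)),
                              stack_id = paste0("s", i))
      r$group <- if (i <= 6) "control" else "knockdown"
      r
    }))
    out <- cohort_summary(rows, control = "control")
    expect_equal(nrow(out), 8)
    expect_true(all(out$n == 6))
    ctrl_fold <- out$mean[out$group == "control" & out$metric == "expansion_fold"]
    expect_equal(ctrl_fold, mean(rows$expansion_fold[rows$group == "control"]))
    expect_true(all(is.na(out$p_vs_control[out$group == "control"])))
    expect_true(all(!is.na(out$p_vs_control[out$group == "knockdown"])))
  })
})
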