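test_that("thresholding is strict and per channel", {
  st <- toy_stack(nz = 1, ny = 1, nx = 3)
  st$channels$live_green[1, 1, ] <- c(0, 10, 50)
  cfg <- threshold_config(c(live_green = 20, til_red = 20, dead_apc = 20))
  m <- threshold_channel(st, "live_green", cfg)
  expect_equal(as.vector(m), c(FALSE, FALSE, TRUE))
  # threshold 0: mask equals intensity > 0 (strict inequality at the bound)
  cfg0 <- threshold_config(c(live_green = 0, til_red = 0, dead_apc = 0))
  expect_equal(as.vector(threshold_channel(st, "live_green", cfg0)),
               c(FALSE, TRUE, TRUE))
  expect_error(threshold_channel(st, "dapi", cfg), "unknown channel")
})

test_that("raising a threshold never increases the positive count", {
  set.seed(71)
  st <- toy_stack(nz = 2, ny = 12, nx = 12)
  st$channels$dead_apc[] <- rpois(288, 40)
  counts <- sapply(seq(0, 80, by = 10), function(th) {
    cfg <- threshold_config(c(live_green = 0, til_red = 0, dead_apc = th))
    sum(threshold_channel(st, "dead_apc", cfg))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("minimum-area filter removes exactly the small regions", {
  vs <- c(dx = 1, dy = 1, dz = 1)
  # single 2-pixel region below a 3-pixel cutoff vanishes
  m <- array(FALSE, c(1, 4, 4)); m[1, 1, 1:2] <- TRUE
  cfg <- threshold_config(c(0, 0, 0), min_area = 3)
  expect_equal(sum(filter_min_area(m, cfg, vs)), 0)
  # min_area = 0 is the identity
  cfg0 <- threshold_config(c(0, 0, 0), min_area = 0)
  expect_identical(filter_min_area(m, cfg0, vs), m)
  # regions of 2, 5 and 9 pixels with a 4-pixel cutoff leave 14 pixels
  sl <- array(FALSE, c(1, 10, 10))
  sl[1, 1, 1:2] <- TRUE                 # 2 px
  sl[1, 3:4, 4:5] <- TRUE; sl[1, 5, 4] <- TRUE   # 5 px
  sl[1, 7:9, 7:9] <- TRUE               # 9 px
  cfg4 <- threshold_config(c(0, 0, 0), min_area = 4)
  expect_equal(sum(filter_min_area(sl, cfg4, vs)), 14)
  # brute-force cross-check of the region sizes used above
  lab <- flood_fill_label(sl[1, , ], 8)
  expect_equal(sort(tabulate(lab)), c(2, 5, 9))
})

test_that("component labeling agrees with exhaustive flood fill", {
  set.seed(5)
  for (i in 1:50) {
    m <- matrix(runif(256) < 0.45, 16, 16)
    for (conn in c(4, 8))
      expect_true(same_partition(label_components(m, conn),
                                 flood_fill_label(m, conn)))
  }
})

test_that("3D labeling modes differ exactly at diagonal contacts", {
  m <- array(FALSE, c(2, 2, 2))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 6)), 2)   # corner voxels separate
  expect_equal(max(label_components(m, 26)), 1)  # diagonal joins them
})

test_that("co-localization classes follow the dye logic", {
  g <- function(...) array(c(...), c(1, 1, 8))
  # all 8 combinations of (green, red, apc)
  green <- g(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  red   <- g(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  apc   <- g(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  cv <- classify_voxels(list(live_green = green, til_red = red,
                             dead_apc = apc),
                        voxel_size = c(dx = 1, dy = 1, dz = 1))
  expect_equal(cv$classes[as.vector(cv$labels)],
               c("background", "live", "til", "til_on_live",
                 "dead", "dying", "dying_til", "dying_til"))
  # partition: counts sum to grid size
  expect_equal(sum(cv$counts), 8)
  expect_equal(unname(cv$volumes_um3), unname(cv$counts))
})

test_that("classification recovers noise-free simulator truth exactly", {
  p <- small_params(noise_sd = 0, noise_dispersion = 0, background_level = 0,
                    green_bleach_rate = 0, til_surface_rate = 0,
                    time_points = c(0, 10, 20), seed = 6)
  s <- simulate_fragment(p)
  cfg <- threshold_config(c(live_green = 1000, til_red = 1000,
                            dead_apc = 1000))
  for (i in seq_along(s$stacks)) {
    cv <- classify_stack(s$stacks[[i]], cfg)
    truth <- s$truth$labels[[i]]
    expect_equal(sum(cv$labels == match("live", TK_CLASSES)),
                 sum(truth == 1L))
    expect_equal(sum(cv$labels == match("dying", TK_CLASSES)),
                 sum(truth == 2L))
    expect_equal(sum(cv$labels == match("dead", TK_CLASSES)),
                 sum(truth == 3L))
  }
})

test_that("masked volume tracks truth within 5% at signal-to-background 10", {
  p <- small_params(time_points = c(0, 12), seed = 8)  # base 2000, bg 200
  s <- simulate_fragment(p)
  thr <- (200 + 2000 * exp(-0.01 * 12)) / 2
  cfg <- threshold_config(c(live_green = thr, til_red = 1100,
                            dead_apc = 1100), min_area = 0)
  m <- threshold_channel(s$stacks[[2]], "live_green", cfg)
  true_green <- sum(s$truth$labels[[2]] %in% c(1L, 2L))
  expect_lt(abs(sum(m) - true_green) / true_green, 0.05)
})

test_that("auto_thresholds lands between background and signal", {
  p <- small_params(time_points = 0, seed = 12)
  s <- simulate_fragment(p)
  th <- auto_thresholds(s$stacks)
  expect_gt(th["dead_apc"] + th["live_green"], 0)  # named, numeric
  expect_true(th["live_green"] > 300 && th["live_green"] < 1900)
})
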