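test_that("dying fraction follows its definition on prescribed counts", {
  cv <- classified_from_counts(c(live = 20, dying = 5, dead = 10, til = 7))
  rec <- dying_fraction(cv)
  expect_equal(rec$dying_fraction, 5 / 25)
  expect_equal(rec$total_tumor_volume_um3, 25)
  # the alternative denominator counts dead tissue too
  expect_equal(dying_fraction(cv, "all_tumor")$dying_fraction, 5 / 35)
  # no dying voxels -> 0, not NA
  cv0 <- classified_from_counts(c(live = 10, dead = 3))
  expect_equal(dying_fraction(cv0)$dying_fraction, 0)
})

test_that("an empty tumor mask is flagged, never fabricated", {
  cv <- classified_from_counts(c(background = 5, til = 2, dead = 4))
  rec <- dying_fraction(cv)
  expect_true(is.na(rec$dying_fraction))
  expect_match(rec$qc_flags, "empty_tumor_mask")
})

test_that("dying fraction is invariant to uniform voxel rescaling", {
  counts <- c(live = 12, dying = 4, til_on_live = 2, dead = 6)
  a <- dying_fraction(classified_from_counts(counts,
                                             c(dx = 1, dy = 1, dz = 1)))
  b <- dying_fraction(classified_from_counts(counts,
                                             c(dx = 3, dy = 3, dz = 12)))
  expect_equal(a$dying_fraction, b$dying_fraction)
  expect_equal(b$total_tumor_volume_um3, a$total_tumor_volume_um3 * 108)
})

make_records <- function(frs, fracs, time_h = 0) {
  do.call(rbind, lapply(seq_along(frs), function(i)
    data.frame(fragment_id = frs[i], time_h = time_h,
               dying_volume_um3 = fracs[i], total_tumor_volume_um3 = 1,
               dying_fraction = fracs[i], denominator = "green_tumor",
               qc_flags = "")))
}

test_that("trajectory means and standard errors are right", {
  layout <- toy_layout(data.frame(fragment_id = c("a", "b", "c"),
                                  condition = "isotype"),
                       time_points = 0)
  # zero variance
  ts <- dying_timeseries(make_records(c("a", "b", "c"), c(.08, .08, .08)),
                         layout)
  expect_equal(ts$conditions$mean_fraction, 0.08)
  expect_equal(ts$conditions$se_fraction, 0)
  # sd/sqrt(3) arithmetic: {1,2,3}% -> SE 0.577%
  ts <- dying_timeseries(make_records(c("a", "b", "c"), c(.01, .02, .03)),
                         layout)
  expect_equal(ts$conditions$mean_fraction, 0.02)
  expect_equal(ts$conditions$se_fraction, 0.01 / sqrt(3) * sqrt(1),
               tolerance = 1e-12)
  expect_equal(round(100 * ts$conditions$se_fraction, 3), 0.577)
})

test_that("single-fragment groups report a mean but an undefined SE", {
  layout <- toy_layout(data.frame(fragment_id = "a", condition = "isotype"),
                       time_points = 0)
  ts <- dying_timeseries(make_records("a", 0.1), layout)
  expect_equal(ts$conditions$mean_fraction, 0.1)
  expect_true(is.na(ts$conditions$se_fraction))
  expect_match(ts$conditions$qc_flags, "se_undefined")
})

test_that("gaps propagate as flagged gaps and orphans are errors", {
  layout <- toy_layout(data.frame(fragment_id = c("a", "b"),
                                  condition = "isotype"),
                       time_points = c(0, 24))
  ts <- dying_timeseries(make_records(c("a", "b"), c(.1, .2)), layout)
  miss <- ts$fragments[ts$fragments$time_h == 24, ]
  expect_true(all(is.na(miss$dying_fraction)))
  expect_true(all(miss$qc_flags == "missing_timepoint"))
  expect_error(dying_timeseries(make_records("zz", .1), layout),
               "absent from the layout")
})

test_that("trajectory summaries are invariant to fragment order", {
  layout <- toy_layout(data.frame(fragment_id = c("a", "b", "c"),
                                  condition = "anti_PD1"),
                       time_points = 0)
  r <- make_records(c("a", "b", "c"), c(.05, .10, .30))
  ts1 <- dying_timeseries(r, layout)
  ts2 <- dying_timeseries(r[c(3, 1, 2), ], layout)
  expect_equal(ts1$conditions, ts2$conditions)
})

test_that("fold increase reports both conventions", {
  # 13% over 8%: 0.625 relative increase (the '0.6-fold increase' idiom)
  f <- fold_increase(0.13, 0.08)
  expect_equal(f$relative_increase, 0.625)
  expect_equal(f$ratio, 1.625)
  expect_equal(round(f$relative_increase, 1), 0.6)
  # 25% over 8%: ratio 3.125 (the 'approximately 3-fold' idiom)
  f <- fold_increase(0.25, 0.08)
  expect_equal(f$relative_increase, 2.125)
  expect_equal(f$ratio, 3.125)
  # identity
  f <- fold_increase(0.08, 0.08)
  expect_equal(f$relative_increase, 0)
  expect_equal(f$ratio, 1)
})

test_that("fold increase is scale-invariant and flags a zero control", {
  a <- fold_increase(0.13, 0.08)
  b <- fold_increase(13, 8)  # percents instead of fractions
  expect_equal(a$relative_increase, b$relative_increase)
  expect_equal(a$ratio, b$ratio)
  z <- fold_increase(0.1, 0)
  expect_true(is.na(z$relative_increase))
  expect_match(z$qc_flags, "control_zero")
})

test_that("fold_increase_table is empty without treated conditions", {
  summ <- data.frame(condition = "isotype", time_h = c(0, 24),
                     n = 3, mean_fraction = c(.05, .06),
                     se_fraction = 0, qc_flags = "")
  expect_equal(nrow(fold_increase_table(summ)), 0)
})
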