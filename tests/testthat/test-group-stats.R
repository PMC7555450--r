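test_that("all-identical observations give H = 0, p = 1", {
  kw <- kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  expect_equal(kw$tie_correction, 0)
})

test_that("the no-ties worked example gives H = 7.2", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))
  # hand-computed from ranks: mean ranks 2, 5, 8
  H_manual <- 12 / (9 * 10) * 3 * ((2 - 5)^2 + 0 + (8 - 5)^2)
  expect_equal(kw$H, H_manual)
})

test_that("statistic and p agree with stats::kruskal.test, with ties", {
  set.seed(19)
  for (i in 1:25) {
    groups <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE),
                     function(n) sample(1:6, n, replace = TRUE))
    if (length(unique(unlist(groups))) < 2) next
    kw <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               factor(rep(seq_along(groups),
                                          lengths(groups))))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(23)
  groups <- list(rnorm(4), rnorm(5) + 1, rnorm(3))
  a <- kruskal_wallis(groups)
  b <- kruskal_wallis(lapply(groups, function(g) exp(3 * g)))
  expect_equal(a$H, b$H)
  expect_equal(a$p, b$p)
})

test_that("exact permutation p matches brute-force enumeration for k = 2", {
  x <- c(1.2, 3.4, 0.5)
  y <- c(4.1, 5.0, 2.2)
  kw <- kruskal_wallis(list(x, y), exact = TRUE)
  expect_equal(kw$exact_method, "enumeration")
  # brute force over all choose(6,3) splits of the pooled data
  pool <- c(x, y)
  splits <- utils::combn(6, 3, simplify = FALSE)
  H_of <- function(idx) {
    r <- rank(pool)
    n <- 3; N <- 6
    Rbar <- c(mean(r[idx]), mean(r[-idx]))
    12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  }
  H_all <- vapply(splits, H_of, numeric(1))
  expect_equal(kw$p_exact, mean(H_all >= H_of(1:3) - 1e-9))
})

test_that("degenerate group structures are rejected", {
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty group")
  expect_error(kruskal_wallis(list(1, 1)), "at least 3")
})

test_that("percent reduction matches its definition and is scale-invariant", {
  tab <- data.frame(
    animal_id = c("m1", "m2", "m3", "m4"),
    group = c("vehicle", "vehicle", "anti_CTLA4", "anti_CTLA4"),
    day = 28,
    volume_mm3 = c(90, 110, 15, 25))
  pr <- percent_reduction(tab, 28, "anti_CTLA4", "vehicle")
  expect_equal(pr$percent_reduction, 80)
  expect_equal(pr$n_treated, 2)
  tab2 <- tab; tab2$volume_mm3 <- tab2$volume_mm3 * 7.3
  expect_equal(percent_reduction(tab2, 28, "anti_CTLA4",
                                 "vehicle")$percent_reduction, 80)
  # equal means -> 0%
  tab3 <- tab; tab3$volume_mm3 <- 100
  expect_equal(percent_reduction(tab3, 28, "anti_CTLA4",
                                 "vehicle")$percent_reduction, 0)
  expect_error(percent_reduction(tab, 14, "anti_CTLA4", "vehicle"),
               "day 14")
})

test_that("percent reduction is recovered from a known growth model", {
  # exponential growth, treated rate halved; day chosen so the true
  # reduction is 50%: exp(r t) / exp(2 r t) = 0.5 at t = log(2) / r
  r <- 0.1
  day <- log(2) / r
  set.seed(31)
  est <- replicate(50, {
    v0 <- exp(rnorm(12, 0, 0.25))
    tab <- data.frame(
      animal_id = sprintf("m%02d", 1:12),
      group = rep(c("vehicle", "anti_PD1"), each = 6),
      day = day,
      volume_mm3 = v0 * exp(ifelse(rep(c(TRUE, FALSE), each = 6),
                                   2 * r, r) * day))
    percent_reduction(tab, day, "anti_PD1", "vehicle")$percent_reduction
  })
  expect_equal(mean(est), 50, tolerance = 0.1)
  expect_lt(sd(est), 15)
})

test_that("growth summaries honor scripted censoring patterns", {
  # 3 animals at day 0, 2 at day 7, 1 at day 14 (dropout by absence)
  tab <- data.frame(
    animal_id = c("a", "b", "c", "a", "b", "a"),
    group = "vehicle",
    day = c(0, 0, 0, 7, 7, 14),
    volume_mm3 = c(100, 100, 100, 200, 220, 400))
  gs <- group_timeseries_summary(tab)
  expect_equal(gs$n, c(3L, 2L, 1L))
  expect_equal(gs$mean_volume_mm3, c(100, 210, 400))
  expect_equal(gs$se_volume_mm3[1], 0)
  expect_true(is.na(gs$se_volume_mm3[3]))
  expect_match(gs$qc_flags[3], "se_undefined")
  # duplicated animals -> zero variance
  expect_equal(gs$se_volume_mm3[1], 0)
})

test_that("growth tables are validated", {
  tab <- data.frame(animal_id = "a", group = "placebo", day = 0,
                    volume_mm3 = 10)
  expect_error(group_timeseries_summary(tab), "unknown group")
  tab <- data.frame(animal_id = c("a", "a"), group = "vehicle", day = 0,
                    volume_mm3 = c(1, 2))
  expect_error(group_timeseries_summary(tab), "one row per animal")
})

test_that("per-day tests mirror per-day significance marks", {
  set.seed(37)
  tab <- do.call(rbind, lapply(c(0, 7, 14), function(d)
    data.frame(animal_id = sprintf("m%02d", 1:9),
               group = rep(c("vehicle", "anti_PD1", "anti_CTLA4"), each = 3),
               day = d,
               volume_mm3 = rnorm(9, 100 + d * rep(c(10, 5, 0), each = 3),
                                  5))))
  kw <- kruskal_by_day(tab)
  expect_equal(kw$day, c(0, 7, 14))
  expect_equal(kw$k, rep(3L, 3))
  expect_true(all(kw$p_holm >= kw$p))
  # day 0: all groups share one distribution; day 14 separates strongly
  expect_gt(kw$H[3], kw$H[1])
})
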