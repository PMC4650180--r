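# Additive decomposition, group trends, ECDFs and KS contrasts.

test_that("constant series decomposes to itself", {
  d <- decompose_additive(rep(3.5, 30), period = 7)
  expect_equal(d$trend, rep(3.5, 30))
  expect_equal(d$seasonal, rep(0, 30))
  expect_equal(d$remainder, rep(0, 30))
})

test_that("reconstruction identity holds exactly on random series", {
  set.seed(123)
  for (r in 1:100) {
    n <- sample(20:80, 1)
    period <- sample(c(0, 2:10), 1)
    v <- rnorm(n) + sin(seq_len(n) / 5)
    if (n < 2 * max(period, 7)) next
    d <- decompose_additive(v, period)
    expect_identical(d$observed, v)
    expect_equal(d$trend + d$seasonal + d$remainder, v, tolerance = 1e-12)
    if (period > 0) {
      # seasonal component has (near) zero mean over one period
      expect_lt(abs(mean(d$seasonal[seq_len(period)])), 1e-9)
    }
  }
})

test_that("linear series yields its slope in the interior trend", {
  b <- 0.37
  v <- 2 + b * (0:49)
  d <- decompose_additive(v, period = 7)
  interior <- which(!d$edge)
  expect_equal(diff(d$trend[interior]), rep(b, length(interior) - 1),
               tolerance = 1e-9)
  expect_equal(d$seasonal, rep(0, 50), tolerance = 1e-9)
})

test_that("interior trend matches the classical moving-average filter", {
  set.seed(4)
  v <- rnorm(60)
  d <- decompose_additive(v, period = 7)
  ref <- stats::decompose(stats::ts(v, frequency = 7))
  interior <- which(!is.na(ref$trend))
  expect_equal(d$trend[interior], as.numeric(ref$trend)[interior],
               tolerance = 1e-12)
  expect_error(decompose_additive(rnorm(10), period = 7), "too short")
})

test_that("group mean trends reduce correctly for tiny groups", {
  set.seed(11)
  days <- seq(as.Date("2010-10-01"), by = 1, length.out = 40)
  mk <- function(id, v) data.frame(bird_id = id, date = days, p_fly = v,
                                   p_rest = 1 - v, p_forage = 0,
                                   n_daytime_blocks = 72)
  v <- runif(40, 0.1, 0.3)
  prof <- rbind(mk("a", v), mk("b", v), mk("c", runif(40)))
  labels <- c(a = "SUCCESS", b = "SUCCESS", c = "SKIP")
  gm <- group_mean_trend(prof, labels, "FLY", period = 7)
  own <- decompose_additive(v, 7)$trend
  two <- gm$mean_trend[gm$mean_trend$group == "SUCCESS", ]
  expect_equal(two$mean, own[seq_len(gm$span)], tolerance = 1e-12)
  expect_equal(unique(two$n), 2)
  one <- gm$mean_trend[gm$mean_trend$group == "SKIP", ]
  expect_equal(one$mean,
               decompose_additive(prof$p_fly[prof$bird_id == "c"],
                                  7)$trend[seq_len(gm$span)],
               tolerance = 1e-12)
})

test_that("ecdf_by_group returns proper right-continuous steps", {
  fs <- ecdf_by_group(list(g1 = c(2, 1, 3), g2 = 5))
  expect_equal(fs$g1(3), 1)
  expect_equal(fs$g1(0.99), 0)
  expect_equal(fs$g1(c(1, 2, 3)), c(1, 2, 3) / 3)
  # single value: a unit step
  expect_equal(fs$g2(c(4.999, 5)), c(0, 1))
  expect_error(ecdf_by_group(list(g1 = numeric(0))), "empty")
})

test_that("KS contrasts handle degenerate and extreme cases", {
  same <- list(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4))
  r <- compare_groups(same, alpha = 0.01)
  expect_equal(r$ks_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)

  disjoint <- list(g1 = 1:5, g2 = 11:15)
  r2 <- compare_groups(disjoint)
  expect_equal(r2$ks_statistic, 1)

  const <- list(g1 = c(2, 2), g2 = c(2, 2))
  r3 <- compare_groups(const)
  expect_equal(r3$ks_statistic, 0)
  expect_equal(r3$p_value, 1)
})

test_that("exact small-sample KS p matches full enumeration", {
  set.seed(21)
  a <- rnorm(7)
  b <- rnorm(7, 0.8)
  r <- compare_groups(list(g1 = a, g2 = b), exact = TRUE)
  expect_equal(r$p_value, enumerate_ks_pvalue(a, b), tolerance = 1e-9)
})

test_that("KS statistic is invariant under monotone transforms", {
  set.seed(31)
  a <- rnorm(25); b <- rnorm(25, 0.5)
  base <- compare_groups(list(g1 = a, g2 = b))$ks_statistic
  up <- compare_groups(list(g1 = exp(a), g2 = exp(b)))$ks_statistic
  down <- compare_groups(list(g1 = -a, g2 = -b))$ks_statistic
  expect_equal(up, base, tolerance = 1e-12)
  expect_equal(down, base, tolerance = 1e-12)
})

test_that("Bonferroni threshold spans pairs x activities", {
  set.seed(41)
  vals <- list(
    FLY = list(A = rnorm(20), B = rnorm(20), C = rnorm(20)),
    REST = list(A = rnorm(20), B = rnorm(20), C = rnorm(20)))
  r <- compare_groups(vals, alpha = 0.01, correct = TRUE)
  expect_equal(nrow(r), 6L)
  expect_equal(unique(r$bonferroni_alpha), 0.01 / 6)
  raw <- compare_groups(vals, alpha = 0.01, correct = FALSE)
  expect_equal(unique(raw$bonferroni_alpha), 0.01)
  expect_equal(r$significant, r$p_value < 0.01 / 6)
})
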