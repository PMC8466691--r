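# Reliability statistics: every estimator is checked against an
# independent hand computation (direct formulas, stats::aov mean squares)
# on fixed small tables, plus distributional sanity via simulation.

test_that("coefficient of variation uses the sample SD over the mean", {
  expect_equal(cv(c(1, 2, 3)), 0.5)            # sd 1, mean 2
  expect_equal(cv(rep(4.2, 5)), 0)
  expect_equal(cv(mean = 60.27, sd = 26.66), 26.66 / 60.27)
  expect_equal(round(cv(mean = 60.27, sd = 26.66), 2), 0.44)
  expect_error(cv(c(-1, 1)), "zero mean")
  expect_error(cv(mean = 0, sd = 1), "zero mean")
  # scale invariance: cv(k x) = cv(x) for k > 0
  set.seed(40)
  x <- rlnorm(20)
  expect_equal(cv(3.7 * x), cv(x), tolerance = 1e-12)
})

test_that("paired t matches the textbook formula and handles degeneracy", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
  # identical raters
  eq <- paired_t(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # constant non-zero difference: p -> 0 limit, flagged
  expect_warning(lim <- paired_t(a, a + 1), "p = 0 limit")
  expect_equal(lim$p, 0)
})

test_that("a small systematic shift is significant at cohort scale", {
  set.seed(41)
  n <- 140
  a <- rnorm(n, 0.22, 0.03)
  b <- a + 0.01 + rnorm(n, 0, 0.01)    # FA-sized shift, sigma_diff 0.01
  expect_lt(paired_t(a, b)$p, 0.001)
})

test_that("ICC matches an independent mean-squares computation", {
  a <- c(9.1, 8.2, 7.3, 9.9, 6.4, 8.8)
  b <- c(8.9, 8.6, 7.1, 9.5, 6.9, 9.0)
  # independent oracle: two-way ANOVA via stats::aov
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_a1 <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  icc_c1 <- (msr - mse) / (msr + mse)
  expect_equal(icc(a, b, "agreement"), icc_a1, tolerance = 1e-12)
  expect_equal(icc(a, b, "consistency"), icc_c1, tolerance = 1e-12)
})

test_that("ICC behaves at the boundaries of agreement", {
  a <- c(1, 3, 5, 7, 9, 11)
  expect_equal(icc(a, a), 1)
  # constant offset: absolute agreement penalised, consistency is not
  expect_lt(icc(a, a + 2, "agreement"), icc(a, a + 2, "consistency"))
  expect_equal(icc(a, a + 2, "consistency"), 1, tolerance = 1e-12)
  expect_error(icc(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("agreement ICC never exceeds consistency ICC given a real rater effect", {
  # the ordering holds whenever the rater mean square is at least the
  # error mean square (non-negative rater variance component); a genuine
  # systematic offset between raters guarantees that regime
  set.seed(42)
  n_checked <- 0L
  for (i in 1:50) {
    a <- rnorm(8)
    b <- a + rnorm(8, sd = 0.3) + runif(1, 0.5, 1.5)
    ms <- muscledti:::two_way_ms(a, b)
    if (ms$msc < ms$mse) next
    n_checked <- n_checked + 1L
    expect_lte(icc(a, b, "agreement"), icc(a, b, "consistency") + 1e-12)
  }
  expect_gt(n_checked, 40L)
})

test_that("Cronbach's alpha matches its defining formula", {
  a <- c(2.2, 3.1, 4.7, 3.9, 5.2, 2.8)
  b <- c(2.4, 3.0, 4.5, 4.2, 5.0, 3.1)
  alpha_hand <- 2 * (1 - (var(a) + var(b)) / var(a + b))
  expect_equal(cronbach_alpha(a, b), alpha_hand, tolerance = 1e-12)
  expect_equal(cronbach_alpha(a, a), 1)
  expect_error(cronbach_alpha(rep(1, 4), rep(1, 4)), "zero total variance")
  # independent raters: alpha near zero
  set.seed(43)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(cronbach_alpha(x, y)), 0.1)
})

test_that("Bland-Altman statistics are the mean/SD of the differences", {
  a <- c(1, 2, 3, 4)
  eq <- bland_altman(a, a)
  expect_equal(eq$mean_diff, 0)
  expect_equal(c(eq$loa_low, eq$loa_high), c(0, 0))
  ba <- bland_altman(c(1, 3), c(2, 2))    # diffs -1, +1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$points$diff, c(-1, 1))
})

test_that("limits of agreement contain ~95% of Gaussian differences", {
  set.seed(44)
  n <- 1e4
  sigma <- 0.3
  a <- rnorm(n, 10, 2) ; b <- a + rnorm(n, 0, sigma * sqrt(2))
  ba <- bland_altman(a, b)
  inside <- mean(ba$points$diff >= ba$loa_low & ba$points$diff <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
  # LoA width approaches 2 * 1.96 * sigma * sqrt(2)
  expect_lt(abs((ba$loa_high - ba$loa_low) / (2 * 1.96 * sigma * sqrt(2)) - 1),
            0.05)
})

test_that("a table compared with itself is perfectly reliable", {
  tab <- data.frame(subject = rep(1:3, each = 7), muscle = rep(letters[1:7], 3),
                    md = rlnorm(21, log(1.6), 0.1))
  rep <- reliability_report(tab, tab, "md")
  expect_equal(rep$icc, 1)
  expect_equal(rep$cronbach_alpha, 1)
  expect_equal(rep$pearson_r, 1)
  expect_equal(rep$bland_altman$mean_diff, 0)
  expect_equal(rep$paired_t$p, 1)
})

test_that("reliability statistics are invariant under common affine rescaling", {
  set.seed(45)
  tab_a <- data.frame(muscle = letters[1:10], fa = rnorm(10, 0.22, 0.03))
  tab_b <- tab_a; tab_b$fa <- tab_a$fa + rnorm(10, 0, 0.01)
  r1 <- reliability_report(tab_a, tab_b, "fa")
  sc_a <- tab_a; sc_a$fa <- 5 * sc_a$fa + 2
  sc_b <- tab_b; sc_b$fa <- 5 * sc_b$fa + 2
  r2 <- reliability_report(sc_a, sc_b, "fa")
  expect_equal(r2$icc, r1$icc, tolerance = 1e-12)
  expect_equal(r2$cronbach_alpha, r1$cronbach_alpha, tolerance = 1e-12)
  expect_equal(r2$pearson_r, r1$pearson_r, tolerance = 1e-12)
})

test_that("reports align pairs on keys and support the fatty stratum", {
  tab_a <- data.frame(subject = rep(1:2, each = 4),
                      muscle = rep(c("s", "t", "u", "v"), 2),
                      md = c(1.5, 1.6, 1.7, 1.8, 1.4, 1.5, 1.6, 1.7),
                      ff = c(0.05, 0.2, 0.3, 0.05, 0.4, 0.05, 0.25, 0.06))
  tab_b <- tab_a
  tab_b$md <- tab_b$md + c(0.01, 0.012, 0.008, 0.011, 0.009, 0.013,
                           0.01, 0.007)
  rep_all <- reliability_report(tab_a, tab_b, "md")
  expect_identical(rep_all$n, 8L)
  rep_ff <- reliability_report(tab_a, tab_b, "md", ff_threshold = 0.10)
  expect_identical(rep_ff$n, 4L)       # only FF > 0.10 pairs remain
  expect_error(reliability_report(tab_a[1:2, ], tab_b[1:2, ], "md"),
               "at least 3")
  expect_error(reliability_report(tab_a, tab_b, "nope"), "missing")
  # JSON serialisation carries the headline statistics
  path <- withr::local_tempfile(fileext = ".json")
  write_reliability_json(rep_all, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$n, 8L)
  expect_equal(js$icc, rep_all$icc, tolerance = 1e-9)
})
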