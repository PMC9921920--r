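test_that("the F statistic follows the textbook sum-of-squares computation", {
  a <- c(1, 2, 3); b <- c(2, 3, 4); d <- c(6, 7, 8)
  rp <- one_way_anova(c(a, b, d), rep(c("a", "b", "d"), each = 3))
  # manual oracle
  gm <- mean(c(a, b, d))
  ssb <- 3 * ((mean(a) - gm)^2 + (mean(b) - gm)^2 + (mean(d) - gm)^2)
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2) + sum((d - mean(d))^2)
  f_manual <- (ssb / 2) / (ssw / 6)
  expect_equal(rp$F, f_manual, tolerance = 1e-12)
  expect_equal(rp$p, pf(f_manual, 2, 6, lower.tail = FALSE))

  flat <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(flat$F, 0)
  expect_error(one_way_anova(1:5, rep(1, 5)), "two groups")
})

test_that("ANOVA reduces to the squared t statistic for two groups", {
  for (s in 1:5) {
    set.seed(700 + s)
    x <- rnorm(12); y <- rnorm(15, 0.5)
    f <- one_way_anova(c(x, y), rep(1:2, c(12, 15)))$F
    t <- t.test(x, y, var.equal = TRUE)$statistic
    expect_equal(f, unname(t^2), tolerance = 1e-10)
  }
})

test_that("Tukey HSD adjusts upward from the pairwise t-test", {
  set.seed(71)
  vals <- c(rnorm(10), rnorm(10, 0.8), rnorm(10, 0.4))
  g <- rep(1:3, each = 10)
  rp <- one_way_anova(vals, g)
  tk <- tukey_hsd(rp)
  expect_equal(nrow(tk), 3)
  raw <- pairwise.t.test(vals, g, p.adjust.method = "none")$p.value
  raw_p <- c(raw[1, 1], raw[2, 1], raw[2, 2])  # 2-1, 3-1, 3-2
  expect_true(all(tk$p_adj >= raw_p - 1e-12))
  expect_true(all(tk$p_adj <= 1))

  same <- one_way_anova(rep(c(1, 2, 3), times = 3) + rnorm(9, sd = 1e-8),
                        rep(1:3, each = 3))
  # identical groups: all adjusted p near 1
  expect_true(all(tukey_hsd(same)$p_adj > 0.99))

  two <- one_way_anova(rnorm(10), rep(1:2, 5))
  expect_error(tukey_hsd(two), "t-test")
})

test_that("only the pairs involving a shifted group come out significant", {
  set.seed(72)
  vals <- c(rnorm(20), rnorm(20), rnorm(20, 3))  # 3 within-SD shift
  g <- rep(1:3, each = 20)
  tk <- tukey_hsd(one_way_anova(vals, g))
  sig <- tk$p_adj < 0.05
  names(sig) <- tk$pair
  expect_false(sig[["2-1"]])
  expect_true(sig[["3-1"]])
  expect_true(sig[["3-2"]])
})

test_that("median intervals come from binomial order-statistic ranks", {
  ci <- median_ci(1:100, 0.95)
  expect_equal(ci$lower, 40)  # largest r with pbinom(r-1,100,.5) <= .025
  expect_equal(ci$upper, 61)
  expect_true(ci$lower < 50.5 && ci$upper > 50.5)
  expect_gte(ci$coverage, 0.95)

  same <- median_ci(rep(7, 20))
  expect_equal(same$lower, same$upper)
  expect_error(median_ci(1:5), "6")
  expect_error(median_ci(1:6, level = 0.999), "achievable")
})

test_that("median interval coverage meets the nominal level", {
  hits <- vapply(1:400, function(s) {
    set.seed(7200 + s)
    x <- rnorm(50)
    ci <- median_ci(x, 0.95)
    ci$lower <= 0 && ci$upper >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.95 - 3 * sqrt(0.95 * 0.05 / 400))
})

test_that("the agreement regression detects shifts and nothing else", {
  set.seed(73)
  w <- runif(20, 60, 95)
  b <- 5 + 0.25 * w + rnorm(20)
  # exact copy: zero contrasts with p = 1
  rp <- agreement_regression(c(b, b), c(w, w),
                             rep(c("self_report", "measured"), each = 20))
  expect_equal(rp$coefficients$self_report, rp$coefficients$measured)
  expect_equal(rp$intercept_diff_p, 1)
  expect_equal(rp$slope_diff_p, 1)

  # planted +5 shift at sd 1 is detected decisively
  b2 <- b + 5 + rnorm(20, 0, 1)
  rp2 <- agreement_regression(c(b, b2), c(w, w),
                              rep(c("self_report", "measured"), each = 20))
  expect_lt(rp2$intercept_diff_p, 0.001)

  expect_error(agreement_regression(c(b, b), c(w, w), rep("self_report", 40)),
               "source")
  expect_error(agreement_regression(rnorm(8), rep(70, 8),
                                    rep(c("self_report", "measured"), 4)),
               "singular|constant")
})

test_that("descriptive comparisons dispatch to the right test", {
  set.seed(74)
  x <- rnorm(30)
  same <- descriptive_compare(x, x, "normal")
  expect_equal(same$p, 1)
  expect_equal(same$test, "Student t")

  # 2x2 diagonal table: chi-square = n by the hand formula, no correction
  ct <- descriptive_compare(rbind(c(10, 0), c(0, 10)),
                            variable_kind = "categorical")
  expect_equal(ct$statistic, 20, tolerance = 1e-12)

  # disjoint ranges: exact two-sided Mann-Whitney p = 2 / choose(8, 4)
  mw <- descriptive_compare(1:4, 11:14, "nonnormal")
  expect_equal(mw$p, 2 / choose(8, 4), tolerance = 1e-12)

  # Shapiro-Wilk gating sends a heavily skewed sample to the rank test
  sk <- descriptive_compare(exp(rnorm(40, 0, 1.5)), exp(rnorm(40, 0, 1.5)))
  expect_equal(sk$test, "Mann-Whitney U")
  expect_error(descriptive_compare(numeric(0), 1:3, "normal"), "non-empty")
})

test_that("the descriptive table mirrors the cohort characteristics layout", {
  co <- small_cohort(seed = 77)
  tab <- descriptive_table(co)
  expect_true(all(c("variable", "male.mean", "male.ci_lower",
                    "female.median", "female.iqr", "p") %in% names(tab)))
  expect_true(all(tab$male.ci_lower <= tab$male.mean &
                    tab$male.mean <= tab$male.ci_upper))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  # spot-check one row against direct computation
  bmi_m <- co$bmi[co$sex == "male"]
  row <- tab[tab$variable == "bmi", ]
  expect_equal(row$male.mean, mean(bmi_m))
  expect_equal(row$male.median, median(bmi_m))
})
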