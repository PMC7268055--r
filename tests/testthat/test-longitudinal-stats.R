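# Small fully specified worked dataset: 2 groups x 3 subjects x 3 timepoints,
# integer values. The oracle is base R's aov() error-stratum decomposition,
# an implementation independent of the package's sums-of-squares code.
worked_Y <- matrix(c(3, 4, 6,
                     2, 4, 5,
                     4, 5, 7,
                     6, 6, 7,
                     5, 7, 8,
                     7, 8, 8), nrow = 6, byrow = TRUE)
worked_group <- rep(c("a", "b"), each = 3)

aov_oracle <- function(Y, group, timepoints = paste0("t", seq_len(ncol(Y)))) {
  d <- make_long_data(Y, group, timepoints)
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$time <- factor(d$time, levels = timepoints)
  s <- summary(aov(y ~ group * time + Error(subject), data = d))
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  c(group = between["group", "F value"],
    time = within["time", "F value"],
    interaction = within["group:time", "F value"])
}

test_that("mixed ANOVA F values match the independent aov oracle exactly", {
  d <- make_long_data(worked_Y, worked_group)
  fit <- rm_anova(d, y, subject, group, time)
  ours <- setNames(tidy(fit)$statistic, c("group", "time", "interaction"))
  expect_equal(ours, aov_oracle(worked_Y, worked_group), tolerance = 1e-10)

  # unbalanced groups too (the study's 21 vs 17 shape, scaled down)
  set.seed(21)
  Y <- matrix(rnorm(13 * 3), 13, 3)
  grp <- rep(c("patient", "control"), c(7, 6))
  d2 <- make_long_data(Y, grp)
  fit2 <- rm_anova(d2, y, subject, group, time)
  ours2 <- setNames(tidy(fit2)$statistic, c("group", "time", "interaction"))
  expect_equal(ours2, aov_oracle(Y, grp), tolerance = 1e-10)
})

test_that("sums of squares are additive across all strata", {
  set.seed(5)
  for (k in 1:10) {
    Y <- matrix(rnorm(10 * 3), 10, 3)
    grp <- rep(c("a", "b"), c(6, 4))
    fit <- rm_anova(make_long_data(Y, grp), y, subject, group, time)
    parts <- sum(fit$effects$ss) +
      fit$effects$ss_error[fit$effects$effect == "group"] +
      fit$effects$ss_error[fit$effects$effect == "time"]
    expect_equal(parts, fit$ss_total, tolerance = 1e-9)
  }
})

test_that("degenerate designs behave: group-separated data, missing cells", {
  # observations near their group mean, groups far apart: huge group F,
  # near-zero interaction F
  set.seed(2)
  Y <- matrix(rep(rep(c(0, 10), each = 4), 3), 8, 3) + rnorm(24, sd = 1e-3)
  grp <- rep(c("a", "b"), each = 4)
  fit <- rm_anova(make_long_data(Y, grp), y, subject, group, time)
  td <- tidy(fit)
  expect_gt(td$statistic[td$term == "group"], 1e4)
  expect_lt(td$statistic[td$term == "group:time"], 5)

  d <- make_long_data(Y, grp)
  expect_error(rm_anova(d[-1, ], y, subject, group, time),
               class = "longconn_incomplete")

  flat <- make_long_data(matrix(1, 6, 3), rep(c("a", "b"), each = 3))
  expect_error(rm_anova(flat, y, subject, group, time),
               class = "longconn_zero_variance")
})

test_that("null data give roughly uniform p values for every effect", {
  set.seed(31)
  n_rep <- 400
  rej <- matrix(FALSE, n_rep, 3)
  template <- make_long_data(matrix(0, 14, 3), rep(c("a", "b"), c(8, 6)))
  for (k in seq_len(n_rep)) {
    Y <- matrix(rnorm(14 * 3), 14, 3)
    rej[k, ] <- longconn:::rm_anova_core(Y, rep(c("a", "b"), c(8, 6)))$effects$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.09))
})

test_that("post hoc tests: cross-sectional t, within-group time F, t^2 == F", {
  # identical groups at a timepoint -> t = 0, p = 1
  Y <- cbind(c(1, 2, 3, 1, 2, 3), c(4, 5, 6, 7, 8, 9), c(1, 1, 2, 2, 3, 3))
  grp <- rep(c("a", "b"), each = 3)
  ph <- posthoc_tests(make_long_data(Y, grp), y, subject, group, time)
  t1 <- ph[ph$contrast == "cross-sectional" & ph$level == "t1", ]
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p, 1)

  # values constant over time within a group -> time F = 0
  Yc <- matrix(rep(c(1, 2, 3), 3), 3, 3)
  one <- longconn:::rm_anova_oneway_core(Yc)
  expect_equal(one$F, 0)
  expect_equal(one$p, 1)

  # two-group cross-sectional t-test squared equals the one-way ANOVA F
  set.seed(6)
  y1 <- rnorm(8); y2 <- rnorm(9) + 1
  tt <- t.test(y1, y2, var.equal = TRUE)
  Fv <- anova(lm(c(y1, y2) ~ rep(c("a", "b"), c(8, 9))))$`F value`[1]
  expect_equal(unname(tt$statistic)^2, Fv, tolerance = 1e-10)
  d <- make_long_data(cbind(c(y1, y2), c(y1, y2), c(y1, y2)) +
                        matrix(rnorm(51, sd = 0.1), 17, 3),
                      rep(c("a", "b"), c(8, 9)))
  ph2 <- posthoc_tests(d, y, subject, group, time)
  row1 <- ph2[ph2$contrast == "cross-sectional" & ph2$level == "t1", ]
  Y1 <- tidyr::pivot_wider(dplyr::transmute(d, subject, time, y),
                           names_from = "time", values_from = "y")$t1
  F1 <- anova(lm(Y1 ~ rep(c("a", "b"), c(8, 9))))$`F value`[1]
  expect_equal(row1$statistic^2, F1, tolerance = 1e-10)
})

test_that("post hoc power: a 2-sigma shift at n = 15/group is almost always seen", {
  set.seed(17)
  hits <- replicate(200, {
    Y <- cbind(rnorm(30), rnorm(30), rnorm(30))
    Y[1:15, ] <- Y[1:15, ] + 2
    ph <- posthoc_tests(make_long_data(Y, rep(c("a", "b"), each = 15)),
                        y, subject, group, time)
    all(ph$p[ph$contrast == "cross-sectional"] < 0.05)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("false-positive adjustment is 1/family-size", {
  expect_equal(round(false_positive_adjust(90), 3), 0.011)
  expect_equal(false_positive_adjust(1), 1)
  expect_equal(false_positive_adjust(26), 1 / 26)
  expect_error(false_positive_adjust(0))
  expect_error(false_positive_adjust(-3))
})

test_that("change-score correlations recover planted relationships", {
  set.seed(23)
  n <- 21
  a1 <- rnorm(n); a2 <- rnorm(n)
  d <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:n), 2),
    time = rep(c("baseline", "1-month"), each = n),
    a = c(a1, a2),
    b2 = 2 * c(a1, a2),          # delta_b = 2 * delta_a -> r = 1
    bneg = -c(a1, a2) + rnorm(2 * n, sd = 0.1 * sd(c(a2 - a1))))
  r1 <- change_score_correlation(d, a, b2, "baseline", "1-month", subject, time)
  expect_equal(r1$r, 1)
  rn <- change_score_correlation(d, a, bneg, "baseline", "1-month", subject, time)
  expect_lt(rn$r, -0.9)

  # independent deltas: |r| below the n = 21 critical value 95% of the time
  inside <- replicate(120, {
    dd <- d
    dd$b2 <- rnorm(2 * n)
    abs(change_score_correlation(dd, a, b2, "baseline", "1-month",
                                 subject, time)$r) < 0.433
  })
  expect_gte(mean(inside), 0.88)

  dz <- d; dz$b2 <- rep(c(1, 2), each = n)
  expect_error(change_score_correlation(dz, a, b2, "baseline", "1-month",
                                        subject, time),
               class = "longconn_zero_variance")
})

test_that("permutation test: exact enumeration, identities, invariances", {
  # element-for-element identical groups: every split beats the observed 0
  expect_equal(permutation_test_group_metric(c(1, 2, 3), c(1, 2, 3)), 1)

  # 3 vs 3 exact p matches an independent enumeration of all 20 splits
  a <- c(0.3, 1.2, 2.1); b <- c(1.0, 2.5, 3.3)
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  cmb <- combn(6, 3)
  ref <- mean(apply(cmb, 2, function(ia)
    abs(mean(pooled[ia]) - mean(pooled[-ia]))) >= obs - 1e-12)
  expect_equal(permutation_test_group_metric(a, b), ref)

  # label exchange leaves the exact p unchanged
  x <- rnorm(5); y <- rnorm(7) + 0.5
  expect_equal(permutation_test_group_metric(x, y),
               permutation_test_group_metric(y, x))

  # clearly separated groups: tiny p
  set.seed(9)
  g1 <- rnorm(10); g2 <- rnorm(10) + 5
  p <- permutation_test_group_metric(g1, g2, n_perm = 10000, seed = 1,
                                     exact = FALSE)
  expect_lte(p, 0.01)

  expect_error(permutation_test_group_metric(numeric(0), g2))
})

test_that("Greenhouse-Geisser epsilon is 1 under compound symmetry, sane otherwise", {
  set.seed(12)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  fit <- longconn:::rm_anova_core(Y, rep(c("a", "b"), each = 20))
  expect_gt(fit$epsilon_gg, 1 / (3 - 1))  # lower bound 1/(T-1)
  expect_lte(fit$epsilon_gg, 1 + 1e-9)
})
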