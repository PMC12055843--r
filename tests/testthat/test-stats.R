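test_that("Mann-Whitney U handles separation, identity and ties", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_lt(sep$Z, 0)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)

  const <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_equal(const$Z, 0)
  expect_equal(const$p, 1)
})

test_that("U matches exhaustive pairwise enumeration for small samples", {
  set.seed(41)
  for (rep in 1:60) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    # integer draws force ties regularly
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$U, oracle_u(x, y),
                 info = paste("rep", rep))
  }
})

test_that("the normal-approximation p agrees with the reference rank test", {
  set.seed(42)
  for (rep in 1:10) {
    x <- stats::rnorm(12); y <- stats::rnorm(10, 0.8)
    mine <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Pearson correlation matches the longhand formula and its limits", {
  a <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  b <- c(10.1, 14.3, 12.9, 21.8, 16.0)
  r_long <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- pearson_correlation(a, b)
  expect_equal(res$r, r_long, tolerance = 1e-12)

  expect_equal(pearson_correlation(a, 2 * a + 1)$r, 1)
  expect_equal(pearson_correlation(a, -a)$r, -1)
  expect_true(is.na(pearson_correlation(a, rep(3, 5))$r))
})

make_summary <- function(values, groups) {
  # values: matrix participants x 2 (correct, incorrect)
  n <- nrow(values)
  tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:n), each = 2),
    group = rep(groups, each = 2),
    response_type = rep(c("correct", "incorrect"), n),
    n_trials = 10L,
    M = as.vector(t(values)))
}

test_that("mixed ANOVA reproduces the textbook sums-of-squares decomposition", {
  set.seed(55)
  n <- 6  # per group, balanced
  cell_means <- matrix(c(10, 18, 8, 12), 2, byrow = TRUE)  # NPH, HE x C, I
  vals <- rbind(
    cbind(cell_means[1, 1] + stats::rnorm(n), cell_means[1, 2] + stats::rnorm(n)),
    cbind(cell_means[2, 1] + stats::rnorm(n), cell_means[2, 2] + stats::rnorm(n)))
  sm <- make_summary(vals, rep(c("NPH", "HE"), each = n))
  res <- mixed_anova(sm, "M")

  d <- data.frame(participant_id = sm$participant_id, group = sm$group,
                  response_type = sm$response_type, value = sm$M)
  orc <- oracle_mixed_anova(d)
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "group"], orc$F_group, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "response_type"], orc$F_resp, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "interaction"], orc$F_int, tolerance = 1e-8)
  expect_equal(eff$df1, rep(1, 3))
  expect_equal(eff$df2, rep(2 * n - 2, 3))
  expect_equal(nrow(res$posthoc), 2L)
  expect_true(all(res$posthoc$p_bonferroni <= 1))
})

test_that("mixed ANOVA is location-invariant and zero on constant data", {
  set.seed(56)
  vals <- matrix(stats::rnorm(20, 10), 10, 2)
  sm <- make_summary(vals, rep(c("NPH", "HE"), each = 5))
  f1 <- mixed_anova(sm, "M")$effects$F
  sm2 <- sm; sm2$M <- sm2$M + 1000
  f2 <- mixed_anova(sm2, "M")$effects$F
  expect_equal(f1, f2, tolerance = 1e-6)

  smc <- make_summary(matrix(5, 8, 2), rep(c("NPH", "HE"), each = 4))
  expect_equal(mixed_anova(smc, "M")$effects$F, rep(0, 3))

  # participants missing a cell are excluded with a warning
  sm3 <- sm[-1, ]
  expect_warning(res3 <- mixed_anova(sm3, "M"), "P01")
  expect_equal(res3$n_participants, 9L)
  expect_error(mixed_anova(sm[sm$group == "NPH", ][1:4, ], "M"),
               "analysis error")
})

test_that("group-effect rejections are calibrated at the nominal level", {
  set.seed(60)
  n_rep <- 800; n <- 6
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    subj <- stats::rnorm(2 * n, sd = 1)
    vals <- cbind(subj + stats::rnorm(2 * n), subj + 2 + stats::rnorm(2 * n))
    sm <- make_summary(vals, rep(c("NPH", "HE"), each = n))
    p <- mixed_anova(sm, "M")$effects
    rejections <- rejections + (p$p[p$effect == "group"] < 0.05)
  }
  rate <- rejections / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("power functions hit their boundary values and are monotone", {
  expect_equal(power_two_sample(0, 14, 12)$power, 0.05, tolerance = 1e-6)
  d_grid <- seq(0.1, 2, by = 0.1)
  pw <- sapply(d_grid, function(d) power_two_sample(d, 14, 12)$power)
  expect_true(all(diff(pw) > 0))
  # the efficiency correction can only cost power
  expect_lt(power_two_sample(1, 14, 12, are_correction = TRUE)$power,
            power_two_sample(1, 14, 12)$power)

  expect_equal(power_correlation(0, 26)$power, 0.05, tolerance = 1e-9)
  expect_lt(power_correlation(0.5, 26)$power, power_correlation(0.5, 36)$power)
  # direct evaluation of the Fisher-z formula at r = 0.569, n = 26
  expect_equal(power_correlation(0.569, 26)$power, 0.8727, tolerance = 1e-3)

  expect_equal(observed_power_f(0, 1, 24)$power, 0.05, tolerance = 1e-9)
  fcrit <- stats::qf(0.95, 1, 24)
  expect_gt(observed_power_f(fcrit, 1, 24)$power, 0.5)
  expect_lt(observed_power_f(fcrit, 1, 24)$power, 0.7)
  expect_gt(observed_power_f(60.922, 1, 24)$power, 0.99)
})

test_that("pooled-SD effect sizes reproduce published-scale magnitudes", {
  d <- cohens_d(52.14, 16.88, 14, 84.17, 7.26, 12)
  expect_equal(d, 2.3976, tolerance = 1e-3)
  expect_gt(power_two_sample(d, 14, 12, are_correction = TRUE)$power, 0.90)
})
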