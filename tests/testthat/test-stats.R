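test_that("Grubbs gate agrees with the critical-value formula", {
  keep <- grubbs_outliers(c(8, 9, 10, 11))
  expect_length(keep$removed, 0L)
  expect_false(oracle_grubbs_flags(c(8, 9, 10, 11))$reject)

  out <- grubbs_outliers(c(8, 9, 10, 50))
  expect_equal(out$removed, 50)
  expect_equal(sort(out$retained), c(8, 9, 10))
  o <- oracle_grubbs_flags(c(8, 9, 10, 50))
  expect_true(o$reject)
  expect_equal(out$log$G[1], o$G)
  expect_equal(out$log$G_crit[1], o$G_crit)

  expect_error(grubbs_outliers(c(1, 2)), class = "ais_bad_input")
})

test_that("removing the Grubbs-flagged point shrinks the max |z| score", {
  for (i in 1:20) {
    set.seed(i)
    x <- c(rnorm(12), rnorm(1, 6))
    g <- grubbs_outliers(x)
    if (length(g$removed) > 0) {
      z_before <- max(abs(x - mean(x))) / sd(x)
      kept1 <- x[-which.max(abs(x - mean(x)))]
      z_after <- max(abs(kept1 - mean(kept1))) / sd(kept1)
      expect_lt(z_after, z_before + 1e-12)
    }
  }
})

test_that("two-group branch picks t-test or Mann-Whitney by normality", {
  x <- c(5.1, 4.9, 5.0, 5.2, 5.3, 4.8, 5.05, 5.15, 4.95, 5.02)
  r <- compare_groups(c(x, x), rep(c("a", "b"), each = 10))
  expect_equal(r$test_name, "unpaired t-test")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(2)
  skewed <- rexp(30)^3
  r2 <- compare_groups(c(skewed, skewed + 0.1), rep(c("a", "b"), each = 30))
  expect_equal(r2$test_name, "Mann-Whitney")

  expect_error(compare_groups(1:4, rep("a", 4)), class = "ais_bad_input")
  expect_error(compare_groups(1:3, c("a", "a", "b")), class = "ais_bad_input")
})

test_that("t statistic matches the hand formula at n = 3", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  r <- compare_groups(c(a, b), rep(c("a", "b"), each = 3), force_test = "t")
  sp <- sqrt(((3 - 1) * var(a) + (3 - 1) * var(b)) / (3 + 3 - 2))
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 4))
})

test_that("Mann-Whitney agrees with exact enumeration at n <= 6", {
  a <- c(1.2, 3.4, 5.6, 7.1)
  b <- c(2.3, 4.5, 6.7, 8.9, 10.1)
  r <- compare_groups(c(a, b), rep(c("a", "b"), c(4, 5)), force_test = "mw")
  o <- oracle_mann_whitney(a, b)
  expect_equal(unname(r$statistic), o$U)
  expect_equal(r$p_value, o$p)
})

test_that("multi-group branches run ANOVA+Tukey or Kruskal+Dunn", {
  set.seed(8)
  g <- rep(c("a", "b", "c"), each = 20)
  x <- rnorm(60)
  x[g == "c"] <- x[g == "c"] + 3  # one group shifted by 3 SD
  r <- compare_groups(x, g)
  expect_equal(r$test_name, "one-way ANOVA + Tukey")
  expect_lt(r$p_value, 0.001)
  sig <- r$posthoc$p_adj < 0.05
  expect_equal(sort(r$posthoc$contrast[sig]), c("c-a", "c-b"))

  skew <- rexp(60)^3
  skew[g == "c"] <- skew[g == "c"] + 50
  r2 <- compare_groups(skew, g)
  expect_equal(r2$test_name, "Kruskal-Wallis + Dunn")
  expect_true(all(r2$posthoc$p_adj >= 0) && all(r2$posthoc$p_adj <= 1))
  sig2 <- r2$posthoc$p_adj < 0.05
  expect_true(all(grepl("c", r2$posthoc$contrast[sig2])))
})

test_that("p-values are invariant under group relabeling", {
  set.seed(12)
  x <- rnorm(40); g <- rep(c("a", "b"), each = 20)
  p1 <- compare_groups(x, g)$p_value
  p2 <- compare_groups(x, ifelse(g == "a", "b", "a"))$p_value
  expect_equal(p1, p2)
})

test_that("the two-sample gate holds its nominal type-I rate", {
  set.seed(100)
  rej <- mean(vapply(1:1000, function(i) {
    compare_groups(rnorm(100), rep(c("a", "b"), each = 50))$p_value < 0.05
  }, TRUE))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("paired mode requires complete pairs and respects pairing", {
  v <- c(1, 2, 3, 1.4, 2.7, 3.6)
  g <- rep(c("w1", "w2"), each = 3)
  r <- compare_groups(v, g, pairing_ids = c(1, 2, 3, 1, 2, 3))
  expect_equal(r$test_name, "paired t-test")
  d <- v[1:3] - v[4:6]  # first group minus second, as the test differences
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(3)))
  expect_error(compare_groups(v[-1], g[-1], pairing_ids = c(2, 3, 1, 2, 3)),
               class = "ais_bad_input")

  # constant differences: statistic undefined, flagged not computed
  vc <- c(1, 2, 3, 1.5, 2.5, 3.5)
  rc <- compare_groups(vc, g, pairing_ids = c(1, 2, 3, 1, 2, 3))
  expect_true(grepl("degenerate", rc$test_name))
  expect_true(is.na(rc$p_value))
})

test_that("longitudinal analysis handles identity, null and noise designs", {
  w <- c(15, 17, 19, 21, 18, 16)
  same <- longitudinal_analysis(w, w)
  expect_true(grepl("degenerate", same$comparison$test_name))
  expect_true(is.na(same$comparison$p_value))
  expect_equal(same$regression$r_squared, 1)

  set.seed(55)
  rej <- mean(vapply(1:1000, function(i) {
    w1 <- rnorm(30, 17.3, 3.9)
    w2 <- w1 + rnorm(30, 0, 1)
    longitudinal_analysis(w1, w2)$comparison$p_value < 0.05
  }, TRUE))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)

  set.seed(56)
  r2s <- vapply(1:200, function(i) {
    longitudinal_analysis(rnorm(30), rnorm(30))$regression$r_squared
  }, 0)
  expect_lt(mean(r2s), 0.05)
})

test_that("plasticity summary aggregates per OTC and compares conditions", {
  set.seed(21)
  mk <- function(cond, mu) data.frame(condition = cond,
                                      otc = rep(1:6, each = 50),
                                      length = rnorm(300, mu, 3))
  two <- rbind(mk("ctrl", 27.9), mk("mgso4", 32.1))
  s <- plasticity_summary(two)
  expect_equal(s$table$n, c(6L, 6L))
  d <- s$table$mean[s$table$condition == "mgso4"] -
    s$table$mean[s$table$condition == "ctrl"]
  se_diff <- sqrt(2) * (3 / sqrt(50)) / sqrt(6)
  expect_lt(abs(d - 4.2), 3 * se_diff)
  expect_equal(s$comparison$test_name, "unpaired t-test")

  d0 <- mk("a", 30)
  dup <- rbind(d0, transform(d0, condition = "b"))  # literally identical
  s2 <- plasticity_summary(dup)
  expect_equal(diff(s2$table$mean), 0)
  expect_equal(s2$comparison$p_value, 1)

  one <- rbind(mk("ctrl", 27.9),
               data.frame(condition = "tiny", otc = 1, length = rnorm(50, 30, 3)))
  s3 <- plasticity_summary(one)
  expect_null(s3$comparison)
  expect_equal(nrow(s3$table), 2L)
  expect_true(any(grepl("tiny", s3$notes)))
})
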