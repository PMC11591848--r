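test_that("t intervals reproduce published-style descriptive rows", {
  expect_equal(round_half_up(ci_mean(6.35, 0.95, 11), 2), c(5.71, 6.99))
  ci2 <- ci_mean(6.87, 0.76, 8)
  expect_equal(round_half_up(ci2[1], 2), 6.23)
  expect_equal(round_half_up(ci2[2], 1), 7.5)   # upper limit printed at 1 dp
  expect_equal(round_half_up(ci_mean(6.27, 1.20, 18), 2), c(5.67, 6.87))
  expect_equal(ci_mean(5, 0, 10), c(5, 5))       # sd = 0 collapses
  expect_error(ci_mean(5, 1, 1), "n < 2")
})

test_that("describe_scores matches direct mean/sd/t-quantile arithmetic", {
  set.seed(3)
  x <- rnorm(23, 7, 0.8)
  d <- describe_scores(x)
  expect_equal(d$mean, mean(x))
  expect_equal(d$sd, sd(x))
  expect_equal(d$ci_low, mean(x) - qt(0.975, 22) * sd(x) / sqrt(23))
  expect_error(describe_scores(c(1, 2, 3), c("a", "a", "b")), "n < 2")
})

test_that("pooled means recover whole-group means from subgroup rows", {
  expect_equal(round_half_up(pooled_mean(c(6.87, 7.10), c(8, 23)), 2), 7.04)
  expect_equal(round_half_up(pooled_mean(c(6.35, 6.27), c(11, 18)), 2), 6.30)
  expect_equal(pooled_mean(4.2, 17), 4.2)
  expect_error(pooled_mean(numeric(0), numeric(0)), "empty")
})

test_that("partial eta squared is recoverable from F and its dfs", {
  expect_equal(round_half_up(partial_eta_sq(7.52, 1, 56), 3), 0.118)
  expect_equal(round_half_up(partial_eta_sq(8.25, 1, 56), 3), 0.128)
  expect_equal(round_half_up(partial_eta_sq(2.17, 1, 56), 3), 0.037)
})

test_that("ANCOVA partial F matches an explicit normal-equation oracle", {
  set.seed(42)
  n <- 12
  df <- data.frame(
    group = rep(c("musician", "non_musician"), each = n / 2),
    sex = rep(c("female", "male"), n / 2),
    age = round(runif(n, 19, 40)),
    final_score = round(runif(n, 4, 10), 2)
  )
  a <- cbt_ancova(df, "final_score", "group", c("sex", "age"))
  X <- cbind(1, df$group == "non_musician", df$sex == "male", df$age)
  y <- df$final_score
  for (j in 2:4) {
    o <- oracle_partial_f(X, y, j)
    row <- a$table[a$table$term == c("group", "sex", "age")[j - 1], ]
    expect_equal(row$F, o$F, tolerance = 1e-10)
    expect_equal(row$p, o$p, tolerance = 1e-10)
    expect_equal(row$eta_p_sq, o$ss / (o$ss + o$sse), tolerance = 1e-10)
  }
  expect_equal(a$df_residual, n - 4)
})

test_that("ANCOVA without covariates reduces to one-way ANOVA", {
  set.seed(7)
  df <- data.frame(group = rep(c("a", "b"), each = 10),
                   final_score = rnorm(20, rep(c(5, 6), each = 10)))
  a <- cbt_ancova(df, "final_score", "group", character(0))
  o <- oracle_one_way(df$final_score, df$group)
  expect_equal(a$table$F, o$F, tolerance = 1e-12)
  expect_equal(a$table$p, o$p, tolerance = 1e-12)
})

test_that("group sum of squares is unchanged by a factor-orthogonal covariate", {
  # covariate constructed orthogonal to the group dummy
  df <- data.frame(group = rep(c("a", "b"), each = 6),
                   cov = rep(c(-1, 0, 1), 4),
                   final_score = c(4, 5, 6, 5, 6, 7, 7, 8, 9, 8, 9, 10))
  a <- cbt_ancova(df, "final_score", "group", "cov")
  grand <- mean(df$final_score)
  ssb <- sum(tapply(df$final_score, df$group,
                    function(v) length(v) * (mean(v) - grand)^2))
  expect_equal(a$table$ss[a$table$term == "group"], ssb, tolerance = 1e-10)
})

test_that("ANCOVA flags degenerate designs", {
  df <- data.frame(group = rep(c("a", "b"), each = 5),
                   dup = rep(c(0, 1), each = 5),
                   final_score = rnorm(10))
  expect_error(cbt_ancova(df, "final_score", "group", "dup"),
               "rank deficient")
  df1 <- data.frame(group = rep("a", 6), final_score = rnorm(6))
  expect_error(cbt_ancova(df1, "final_score", "group", character(0)),
               ">= 2 levels")
})

test_that("identical outcomes give a null group effect", {
  df <- data.frame(group = rep(c("a", "b"), each = 6),
                   sex = rep(c("male", "female"), 6),
                   age = rep(20:25, 2),
                   final_score = rep(6.5, 12))
  a <- cbt_ancova(df)
  expect_equal(a$table$F, rep(0, 3))
})

test_that("Levene's test matches a by-hand ANOVA on absolute deviations", {
  x <- c(1, 2, 6, 4, 5, 9)
  g <- rep(c("a", "b"), each = 3)
  lv <- levene_test(x, g)
  z <- abs(x - ave(x, g))
  o <- oracle_one_way(z, g)
  expect_equal(lv$value, o$F, tolerance = 1e-12)
  expect_equal(lv$p, o$p, tolerance = 1e-12)

  same <- levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$value, 0)

  set.seed(5)
  base <- rnorm(20)
  wide <- c(base[1:10], base[11:20] * 4)
  g2 <- rep(c("a", "b"), each = 10)
  expect_gt(levene_test(wide, g2)$value,
            levene_test(base, g2)$value)
})

test_that("Levene's test agrees with car::leveneTest", {
  skip_if_not_installed("car")
  set.seed(17)
  x <- rnorm(40, sd = rep(c(1, 2), each = 20))
  g <- rep(c("a", "b"), each = 20)
  ours <- levene_test(x, g, center = "median")
  ref <- car::leveneTest(x, factor(g), center = "median")
  expect_equal(ours$value, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("slopes-homogeneity F is null-calibrated and detects divergent slopes", {
  set.seed(2718)
  # null: identical slopes in both groups -> p uniform on [0, 1]
  pvals <- replicate(500, {
    n <- 200
    g <- rep(c("a", "b"), each = n / 2)
    age <- runif(n, 18, 40)
    y <- 5 + 0.05 * age + rnorm(n)
    slopes_homogeneity(data.frame(group = g, age = age, final_score = y))$p
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)

  # strong slope difference (+1 vs -1 per year) is detected
  n <- 200
  g <- rep(c("a", "b"), each = n / 2)
  age <- runif(n, 18, 40)
  y <- ifelse(g == "a", age, -age) + rnorm(n)
  expect_lt(slopes_homogeneity(
    data.frame(group = g, age = age, final_score = y))$p, 0.001)

  flat <- data.frame(group = g, age = age, final_score = rep(5, n))
  expect_lt(abs(slopes_homogeneity(flat)$value), 1e-10)
})

test_that("covariate independence is a one-way ANOVA of the covariate", {
  df <- data.frame(group = rep(c("a", "b"), each = 4),
                   age = c(20, 22, 24, 26, 21, 23, 25, 27))
  res <- covariate_independence(df, "age", "group")
  o <- oracle_one_way(df$age, df$group)
  expect_equal(res$value, o$F, tolerance = 1e-12)

  same <- data.frame(group = rep(c("a", "b"), each = 3),
                     age = rep(c(20, 25, 30), 2))
  expect_equal(covariate_independence(same, "age", "group")$value, 0)

  shifted <- df
  shifted$age[shifted$group == "b"] <- shifted$age[shifted$group == "b"] + 10
  expect_gt(covariate_independence(shifted, "age", "group")$value,
            res$value)
})

test_that("Pearson correlation matches covariance arithmetic and cor.test", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 7, 8, 9)
  res <- pearson_test(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$value, r_hand, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(res$value, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  expect_equal(pearson_test(x, x)$value, 1)
  expect_equal(pearson_test(x, -x)$value, -1)
  expect_error(pearson_test(c(1, 1, 1), y[1:3]), "zero variance")
})

test_that("chi-square on count tables matches hand computation", {
  tab <- matrix(c(10, 20, 20, 10), 2)      # expecteds are all 15
  res <- chisq_table(tab)
  expect_equal(res$value, 4 * 25 / 15, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$value, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  prop <- matrix(c(10, 20, 30, 60), 2)     # proportional rows
  expect_equal(chisq_table(prop)$value, 0)
  expect_error(chisq_table(matrix(c(0, 0, 1, 2), 2)), "zero margin")
  # upper-tail p of the published-style statistic
  expect_equal(round_half_up(pchisq(14.43, 4, lower.tail = FALSE), 3), 0.006)
})

test_that("Mann-Whitney exact enumeration behaves and approximation agrees", {
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$method, "exact")
  expect_equal(same$p, 1)

  sep <- mann_whitney(1:5, 6:10)
  expect_true(sep$value %in% c(0, 25))

  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(8)
    y <- rnorm(8)
    exact_p <- corsiblocks:::mw_exact_p(rank(c(x, y))[1:8], rank(c(x, y)), 8)
    approx_p <- mann_whitney(x, y)$p     # n = 16 uses the approximation
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("Mann-Whitney agrees with wilcox.test", {
  set.seed(9)
  x <- rnorm(15)
  y <- rnorm(18, 0.5)
  ours <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(ours$value, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
})

test_that("two-sample t matches hand-pooled arithmetic and t.test", {
  x <- c(5, 6, 7, 8)
  y <- c(4, 5, 5, 6)
  res <- two_sample_t(x, y)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$value, t_hand, tolerance = 1e-12)
  expect_equal(res$d, (mean(x) - mean(y)) / sqrt(sp2), tolerance = 1e-12)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-12)

  expect_equal(two_sample_t(x, x)$value, 0)
  expect_equal(two_sample_t(x, x)$d, 0)
  swapped <- two_sample_t(y, x)
  expect_equal(swapped$value, -res$value)
  expect_equal(swapped$d, -res$d)

  w <- two_sample_t(x, c(y, 10, 12), variant = "welch")
  refw <- t.test(x, c(y, 10, 12))
  expect_equal(w$value, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-12)
})

test_that("student t squared equals the one-way ANOVA F", {
  set.seed(33)
  x <- rnorm(9, 6)
  y <- rnorm(7, 7)
  tt <- two_sample_t(x, y)
  o <- oracle_one_way(c(x, y), rep(c("x", "y"), c(9, 7)))
  expect_equal(tt$value^2, o$F, tolerance = 1e-10)
})

test_that("metacompetence percentages follow the claim-good denominator", {
  df <- data.frame(
    group = rep(c("musician", "non_musician"), c(31, 29)),
    self_assessment = c(rep("good", 23), rep("bad", 8),
                        rep("good", 18), rep("bad", 11)),
    final_score = c(rep(8, 19), rep(6, 4), rep(8, 2), rep(6, 6),   # musicians
                    rep(8, 6), rep(6, 12), rep(8, 5), rep(6, 6))   # non-musicians
  )
  mt <- metacompetence_table(df, threshold = 7)
  expect_identical(mt$denominator_n, 41L)
  expect_equal(unname(mt$counts[, "good_good"]), c(19, 6))
  expect_equal(unname(mt$counts[, "good_poor"]), c(4, 12))
  expect_equal(round_half_up(unname(mt$percentages[, "good_good"]), 2),
               c(46.34, 14.63))
  expect_equal(round_half_up(unname(mt$percentages[, "good_poor"]), 2),
               c(9.76, 29.27))
  # marginal conservation: row sums equal the claim counts
  expect_equal(unname(rowSums(mt$counts)), c(31, 29))
  expect_equal(sum(mt$percentages, na.rm = TRUE), 100)
})

test_that("all-accurate claim-good musicians fill their cell", {
  df <- data.frame(group = rep("musician", 5),
                   self_assessment = rep("good", 5),
                   final_score = rep(9, 5))
  df <- rbind(df, data.frame(group = "non_musician",
                             self_assessment = "bad", final_score = 5))
  mt <- metacompetence_table(df)
  expect_equal(unname(mt$percentages["musician", "good_good"]), 100)
})

test_that("experience split ANOVA matches hand ANOVA and t-squared identity", {
  df <- data.frame(years_reading = c(2, 4, 5, 7, 9, 11, 14, 20),
                   final_score = c(7.2, 6.8, 7.5, 7.0, 6.5, 6.9, 6.2, 6.6))
  res <- experience_split_anova(df, cut = 7)
  o <- oracle_one_way(df$final_score,
                      ifelse(df$years_reading <= 7, "low", "high"))
  expect_equal(res$value, o$F, tolerance = 1e-12)
  tt <- two_sample_t(df$final_score[df$years_reading <= 7],
                     df$final_score[df$years_reading > 7])
  expect_equal(tt$value^2, res$value, tolerance = 1e-10)

  same <- data.frame(years_reading = c(1, 2, 10, 12),
                     final_score = rep(6, 4))
  expect_equal(experience_split_anova(same)$value, 0)
  expect_error(experience_split_anova(
    data.frame(years_reading = c(1, 2), final_score = c(5, 6)), cut = 7),
    "stratum is empty")
})
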