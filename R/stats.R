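#' Student-t confidence interval from summary statistics
#'
#' @param mean,sd,n sample mean, SD (n-1 denominator) and size.
#' @param level confidence level.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' ci_mean(6.35, 0.95, 11)  # [5.71, 6.99] at 2 dp
#' @export
ci_mean <- function(mean, sd, n, level = 0.95) {
  if (n < 2) stop("confidence interval undefined for n < 2")
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' Descriptive statistics with t intervals
#'
#' Mean, SD and two-sided 95% Student-t confidence limits per group,
#' unrounded (round at report time only).
#'
#' @param x numeric scores.
#' @param by grouping labels (same length as `x`); a single group when
#'   omitted.
#' @param level confidence level.
#' @return Data frame with columns `label`, `n`, `mean`, `sd`, `ci_low`,
#'   `ci_high`.
#' @export
describe_scores <- function(x, by = NULL, level = 0.95) {
  by <- by %||% rep("all", length(x))
  stopifnot(length(by) == length(x))
  groups <- split(x, by)
  out <- lapply(names(groups), function(lab) {
    v <- groups[[lab]]
    if (length(v) < 2) stop("group '", lab, "' has n < 2; interval undefined")
    ci <- ci_mean(mean(v), stats::sd(v), length(v), level)
    data.frame(label = lab, n = length(v), mean = mean(v), sd = stats::sd(v),
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample-size weighted pooled mean
#'
#' @param means subgroup means.
#' @param ns subgroup sizes.
#' @return `sum(ns * means) / sum(ns)`.
#' @examples
#' pooled_mean(c(6.87, 7.10), c(8, 23))  # 7.04 at 2 dp
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) == 0L) stop("empty subgroup list")
  stopifnot(length(means) == length(ns), all(ns > 0))
  sum(ns * means) / sum(ns)
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, the effect size recoverable from a
#' reported F test and its degrees of freedom; identical to
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param f F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(7.52, 1, 56)  # 0.118 at 3 dp
#' @export
partial_eta_sq <- function(f, df1, df2) {
  f * df1 / (f * df1 + df2)
}

# Dummy-code a working frame: the factor becomes a factor(), 2-level
# character covariates become 0/1 (alphabetical reference level), numeric
# covariates pass through.
ancova_frame <- function(data, dv, group, covariates) {
  df <- as.data.frame(data)
  missing_cols <- setdiff(c(dv, group, covariates), names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  wf <- data.frame(.y = as.numeric(df[[dv]]))
  fac <- df[[group]]
  if (length(unique(fac)) < 2L) stop("factor '", group, "' needs >= 2 levels")
  wf[[group]] <- factor(fac)
  for (cv in covariates) {
    v <- df[[cv]]
    if (is.numeric(v)) {
      wf[[cv]] <- v
    } else {
      lev <- sort(unique(as.character(v)))
      if (length(lev) != 2L) {
        stop("covariate '", cv, "' must be numeric or two-level")
      }
      wf[[cv]] <- as.numeric(as.character(v) == lev[2])
      attr(wf, paste0("coding_", cv)) <- stats::setNames(c(0, 1), lev)
    }
  }
  wf
}

# Partial (drop-one) F tests from nested OLS fits.
partial_f_table <- function(wf, group, covariates) {
  terms <- c(group, covariates)
  full <- stats::lm(stats::reformulate(terms, ".y"), data = wf)
  b <- stats::coef(full)
  if (anyNA(b)) {
    stop("design matrix is rank deficient; collinear columns: ",
         paste(names(b)[is.na(b)], collapse = ", "))
  }
  sse_full <- sum(stats::residuals(full)^2)
  df_res <- stats::df.residual(full)
  # scale-aware tolerance for a degenerate (perfectly fit) outcome
  tol <- 1e-12 * max(1, sum(wf$.y^2))
  rows <- lapply(terms, function(tm) {
    rest <- setdiff(terms, tm)
    red <- stats::lm(
      if (length(rest)) stats::reformulate(rest, ".y") else .y ~ 1,
      data = wf
    )
    ss <- max(sum(stats::residuals(red)^2) - sse_full, 0)
    df1 <- stats::df.residual(red) - df_res
    f <- if (ss < tol) 0 else (ss / df1) / (sse_full / df_res)
    data.frame(term = tm, df1 = df1, df2 = df_res, ss = ss, F = f,
               p = stats::pf(f, df1, df_res, lower.tail = FALSE),
               eta_p_sq = ss / (ss + sse_full), stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), fit = full, sse = sse_full,
       df_res = df_res)
}

#' ANCOVA with partial F tests and partial eta squared
#'
#' Ordinary least squares of the outcome on one grouping factor plus
#' covariates (dummy-coded). Each term's F is the partial
#' (Type-III-equivalent) F comparing the full model against the model
#' without that term — with a single factor and continuous covariates this
#' is order-invariant. Effect sizes are partial eta squared
#' `SS_term / (SS_term + SS_residual)`. Adjusted group means evaluate the
#' fit at each factor level with every covariate held at its sample mean.
#'
#' With `covariates = character(0)` this reduces exactly to classical
#' one-way ANOVA.
#'
#' @param data data frame (e.g. a `cbt_study`).
#' @param dv name of the numeric outcome column.
#' @param group name of the factor column.
#' @param covariates character vector of covariate columns; numeric or
#'   two-level categorical (dummy-coded 0/1, alphabetical reference).
#' @return A `cbt_ancova`: list with `table` (term, df1, df2, ss, F, p,
#'   eta_p_sq), `adjusted_means`, `df_residual`, `n`.
#' @export
cbt_ancova <- function(data, dv = "final_score", group = "group",
                       covariates = c("sex", "age")) {
  wf <- ancova_frame(data, dv, group, covariates)
  pf <- partial_f_table(wf, group, covariates)
  lev <- levels(wf[[group]])
  newdata <- data.frame(factor(lev, levels = lev))
  names(newdata) <- group
  for (cv in covariates) newdata[[cv]] <- mean(wf[[cv]])
  adj <- stats::predict(pf$fit, newdata = newdata)
  structure(
    list(table = pf$table,
         adjusted_means = stats::setNames(as.numeric(adj), lev),
         df_residual = pf$df_res, sse = pf$sse, n = nrow(wf),
         dv = dv, group = group, covariates = covariates),
    class = "cbt_ancova"
  )
}

#' @export
print.cbt_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA: %s ~ %s%s (n = %d)\n", x$dv, x$group,
              if (length(x$covariates)) {
                paste0(" + ", paste(x$covariates, collapse = " + "))
              } else "",
              x$n))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s F(%d,%d) = %.2f, p = %.3f, eta_p^2 = %.3f\n",
                tab$term[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                tab$eta_p_sq[i]))
  }
  cat("  adjusted means:",
      paste(sprintf("%s = %.2f", names(x$adjusted_means), x$adjusted_means),
            collapse = ", "), "\n")
  invisible(x)
}

# one-way ANOVA via OLS; returns the classical F decomposition
one_way_f <- function(x, g, term = "group") {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 1L)) stop("empty group")
  if (stats::var(x) < 1e-12 * max(1, mean(x)^2)) {
    # constant outcome: no variance to apportion
    return(data.frame(term = term, df1 = nlevels(g) - 1L,
                      df2 = length(x) - nlevels(g), F = 0, p = 1,
                      eta_p_sq = 0, stringsAsFactors = FALSE))
  }
  fit <- stats::lm(x ~ g)
  a <- stats::anova(fit)
  f <- a$`F value`[1]
  data.frame(term = term, df1 = a$Df[1], df2 = a$Df[2], F = f,
             p = a$`Pr(>F)`[1],
             eta_p_sq = a$`Sum Sq`[1] / sum(a$`Sum Sq`),
             stringsAsFactors = FALSE)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA F on absolute deviations from the group centre. The
#' classic test centres on the group mean (default); the Brown-Forsythe
#' variant centres on the median.
#'
#' @param x numeric values.
#' @param g group labels.
#' @param center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return A `cbt_test` list: `statistic = "F_levene"`, `value`, `df1`,
#'   `df2`, `p`.
#' @export
levene_test <- function(x, g, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(g)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("Levene's test needs >= 2 groups with n >= 2 each")
  }
  ctr <- if (center == "mean") {
    stats::ave(x, g, FUN = mean)
  } else {
    stats::ave(x, g, FUN = stats::median)
  }
  z <- abs(x - ctr)
  res <- one_way_f(z, g)
  structure(list(statistic = "F_levene", value = res$F, df1 = res$df1,
                 df2 = res$df2, p = res$p, center = center),
            class = "cbt_test")
}

#' Homogeneity-of-regression-slopes check
#'
#' Partial F for the factor-by-covariate interaction added to the model
#' `dv ~ factor + covariate`. A small p is evidence that covariate slopes
#' differ between groups, violating the ANCOVA assumption.
#'
#' @inheritParams cbt_ancova
#' @param covariate single covariate column name.
#' @return A `cbt_test` with `value` (F), `df1`, `df2`, `p`, `eta_p_sq`.
#' @export
slopes_homogeneity <- function(data, dv = "final_score", group = "group",
                               covariate = "age") {
  wf <- ancova_frame(data, dv, group, covariate)
  full <- stats::lm(stats::as.formula(
    paste(".y ~", group, "*", covariate)), data = wf)
  if (anyNA(stats::coef(full))) stop("design matrix is rank deficient")
  red <- stats::lm(stats::as.formula(
    paste(".y ~", group, "+", covariate)), data = wf)
  sse_f <- sum(stats::residuals(full)^2)
  sse_r <- sum(stats::residuals(red)^2)
  df1 <- stats::df.residual(red) - stats::df.residual(full)
  df2 <- stats::df.residual(full)
  ss <- max(sse_r - sse_f, 0)
  tol <- 1e-12 * max(1, sum(wf$.y^2))
  f <- if (ss < tol) 0 else (ss / df1) / (sse_f / df2)
  structure(list(statistic = "F", value = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE),
                 eta_p_sq = if (ss < tol) 0 else ss / sse_r),
            class = "cbt_test")
}

#' Covariate-factor independence check
#'
#' One-way ANOVA of the covariate on the grouping factor; a large p
#' supports the ANCOVA assumption that the covariate does not differ
#' between groups.
#'
#' @inheritParams slopes_homogeneity
#' @return A `cbt_test` with `value` (F), `df1`, `df2`, `p`, `eta_p_sq`.
#' @export
covariate_independence <- function(data, covariate = "age", group = "group") {
  df <- as.data.frame(data)
  res <- one_way_f(as.numeric(df[[covariate]]), df[[group]])
  structure(list(statistic = "F", value = res$F, df1 = res$df1,
                 df2 = res$df2, p = res$p, eta_p_sq = res$eta_p_sq),
            class = "cbt_test")
}

#' Pearson correlation with t test
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-degenerate.
#' @return A `cbt_test` with `statistic = "r"`, `value` (r), `df`
#'   (`n - 2`), `p` (two-sided), `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  structure(list(statistic = "r", value = r, df = n - 2,
                 t = tstat, p = 2 * stats::pt(-abs(tstat), n - 2), n = n),
            class = "cbt_test")
}

#' Pearson chi-square test on an r x c count table
#'
#' Expected counts from the product of the margins; upper-tail p on
#' `(r - 1)(c - 1)` degrees of freedom. No continuity correction.
#'
#' @param counts matrix of non-negative counts with non-zero margins.
#' @return A `cbt_test` with `statistic = "chi2"`, `value`, `df`, `p`,
#'   `expected`.
#' @examples
#' chisq_table(matrix(c(10, 20, 20, 10), 2))  # chi2 = 6.667, df = 1
#' @export
chisq_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  e <- outer(rs, cs) / sum(counts)
  x2 <- sum((counts - e)^2 / e)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(statistic = "chi2", value = x2, df = df,
                 p = stats::pchisq(x2, df, lower.tail = FALSE),
                 expected = e),
            class = "cbt_test")
}

# exact two-sided permutation p for the Mann-Whitney U via enumeration of
# all group assignments of the pooled ranks (ties handled naturally)
mw_exact_p <- function(rx, pooled_ranks, n1) {
  n <- length(pooled_ranks)
  n2 <- n - n1
  centre <- n1 * n2 / 2
  u_obs <- sum(rx) - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_obs - centre)
  combos <- utils::combn(n, n1)
  devs <- apply(combos, 2, function(idx) {
    abs(sum(pooled_ranks[idx]) - n1 * (n1 + 1) / 2 - centre)
  })
  mean(devs >= dev_obs - 1e-9)
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. For combined n of at most 10
#' the two-sided p comes from exhaustive enumeration of all group
#' assignments of the pooled ranks (exact even under ties); otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @return A `cbt_test` with `statistic = "U"`, `value` (U for sample
#'   `x`), `p` (two-sided), `method`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= 10L) {
    p <- mw_exact_p(r[seq_len(n1)], r, n1)
    method <- "exact"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- abs(u - n1 * n2 / 2)
    z <- max(dev - 0.5, 0) / sqrt(sigma2)  # continuity-corrected
    p <- min(2 * stats::pnorm(-z), 1)
    method <- "normal_approx"
  }
  structure(list(statistic = "U", value = u, p = p, n1 = n1, n2 = n2,
                 method = method),
            class = "cbt_test")
}

#' Two-sample t test with Cohen's d
#'
#' Student (pooled-variance) or Welch t test on two independent samples,
#' with Cohen's d computed on the pooled SD and a confidence interval for
#' the mean difference `mean(x) - mean(y)`.
#'
#' @param x,y numeric samples, each n >= 2.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @param level confidence level for the mean-difference interval.
#' @return A `cbt_test` with `value` (t), `df`, `p`, `d`, `diff`,
#'   `ci_low`, `ci_high`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch"),
                         level = 0.95) {
  variant <- match.arg(variant)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs n >= 2")
  m1 <- mean(x)
  m2 <- mean(y)
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (variant == "student") {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  half <- stats::qt(1 - (1 - level) / 2, df) * se
  structure(list(statistic = "t", value = tstat, df = df,
                 p = 2 * stats::pt(-abs(tstat), df),
                 d = (m1 - m2) / sqrt(sp2), diff = m1 - m2,
                 ci_low = m1 - m2 - half, ci_high = m1 - m2 + half,
                 variant = variant),
            class = "cbt_test")
}

#' @export
print.cbt_test <- function(x, ...) {
  df_txt <- if (!is.null(x$df1)) {
    sprintf("(%g,%g)", x$df1, x$df2)
  } else if (!is.null(x$df)) {
    sprintf("(%g)", x$df)
  } else ""
  cat(sprintf("%s%s = %.3f, p = %.4f\n", x$statistic, df_txt, x$value, x$p))
  invisible(x)
}

#' Metacompetence accuracy table
#'
#' Cross-classifies participants by group and by the combination of their
#' self-assessment claim ("good" / "bad") with their measured performance
#' label ("good" / "poor" at `threshold`). Rows with "normal" or "unable"
#' self-assessments must be excluded upstream (they are dropped here with
#' a check). Percentages are computed with a configurable denominator:
#' `"claim_good"` (default) divides the four claim-good cells by the total
#' number of claim-good participants so those four percentages sum to
#' 100; `"all"` divides every cell by the full filtered sample.
#'
#' @param data a `cbt_study` or data frame with `group`,
#'   `self_assessment`, `final_score`.
#' @param threshold performance cutoff for [classify_performance()].
#' @param denominator `"claim_good"` or `"all"`.
#' @return A `cbt_metacomp`: list with `counts` (group x claim_perf
#'   matrix), `percentages`, `claim_good_accuracy` per group, `threshold`,
#'   `denominator`.
#' @export
metacompetence_table <- function(data, threshold = 7,
                                 denominator = c("claim_good", "all")) {
  denominator <- match.arg(denominator)
  df <- as.data.frame(data)
  df <- df[df$self_assessment %in% c("good", "bad"), , drop = FALSE]
  if (nrow(df) == 0L) stop("no participants with good/bad self-assessments")
  perf <- classify_performance(df$final_score, threshold)
  cell <- factor(paste(df$self_assessment, perf, sep = "_"),
                 levels = c("good_good", "good_poor", "bad_good", "bad_poor"))
  grp <- factor(df$group, levels = c("musician", "non_musician"))
  counts <- table(grp, cell)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  denom <- switch(denominator,
    claim_good = sum(counts[, c("good_good", "good_poor")]),
    all = sum(counts)
  )
  pct <- 100 * counts / denom
  if (denominator == "claim_good") {
    pct[, c("bad_good", "bad_poor")] <- NA_real_
  }
  acc_den <- rowSums(counts[, c("good_good", "good_poor"), drop = FALSE])
  accuracy <- ifelse(acc_den > 0, counts[, "good_good"] / acc_den, NA_real_)
  structure(list(counts = counts, percentages = pct,
                 claim_good_accuracy = accuracy, denominator = denominator,
                 denominator_n = denom, threshold = threshold),
            class = "cbt_metacomp")
}

#' @export
print.cbt_metacomp <- function(x, ...) {
  cat("Metacompetence table (counts):\n")
  print(x$counts)
  cat(sprintf("claim-good accuracy: %s\n",
              paste(sprintf("%s = %.1f%%", names(x$claim_good_accuracy),
                            100 * x$claim_good_accuracy), collapse = ", ")))
  invisible(x)
}

#' One-way ANOVA across experience strata
#'
#' Splits the musician rows at `cut` years of music reading (at most
#' `cut` years versus more) and compares mean CBT scores with a one-way
#' ANOVA.
#'
#' @param data data frame with `years_reading` and the score column; only
#'   musician rows are used when a `group` column is present.
#' @param cut stratum boundary in years (default: 7, i.e. 1-7 vs 8+).
#' @param dv score column name.
#' @return A `cbt_test` with `value` (F), `df1`, `df2`, `p`, `eta_p_sq`,
#'   plus the per-stratum `n`.
#' @export
experience_split_anova <- function(data, cut = 7, dv = "final_score") {
  df <- as.data.frame(data)
  if ("group" %in% names(df)) df <- df[df$group == "musician", , drop = FALSE]
  stratum <- ifelse(df$years_reading <= cut, "low", "high")
  if (length(unique(stratum)) < 2L) {
    stop("one experience stratum is empty at cut = ", cut)
  }
  res <- one_way_f(as.numeric(df[[dv]]), stratum, term = "experience")
  structure(list(statistic = "F", value = res$F, df1 = res$df1,
                 df2 = res$df2, p = res$p, eta_p_sq = res$eta_p_sq,
                 cut = cut, n = table(stratum)),
            class = "cbt_test")
}
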