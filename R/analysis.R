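#' Run the full study analysis pipeline
#'
#' Executes the complete inferential pipeline on a scored study dataset,
#' in the order: exclusion filter ("normal" / "unable" self-assessments
#' are dropped from inference), sample matching checks (age t test, sex
#' Mann-Whitney), ANCOVA assumption checks (Levene on the outcome,
#' covariate-factor independence for age, homogeneity of regression
#' slopes for age), the group ANCOVA controlling for sex and age,
#' age-score correlations (overall and within groups), the metacompetence
#' contingency analysis with its chi-square, and the experience-split
#' one-way ANOVA with the years-score correlation among musicians.
#'
#' @param study a `cbt_study` (or any data frame with columns `group`,
#'   `sex`, `age`, `years_reading`, `self_assessment`, `final_score`).
#' @param threshold good/poor performance cutoff.
#' @param levene_center `"mean"` or `"median"`.
#' @param experience_cut years-of-reading stratum boundary.
#' @param denominator percentage denominator for
#'   [metacompetence_table()].
#' @return A `cbt_report` (nested list of results), printable as a text
#'   summary and serializable with [write_report()].
#' @export
run_full_analysis <- function(study, threshold = 7,
                              levene_center = "mean", experience_cut = 7,
                              denominator = "claim_good") {
  df <- as.data.frame(study)
  req <- c("group", "sex", "age", "years_reading", "self_assessment",
           "final_score")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(df$group)) < 2L) {
    stop("both groups (musician, non_musician) are required")
  }
  retained <- df[df$self_assessment %in% c("good", "bad"), , drop = FALSE]
  excluded <- nrow(df) - nrow(retained)
  mus <- retained[retained$group == "musician", , drop = FALSE]
  non <- retained[retained$group == "non_musician", , drop = FALSE]
  if (nrow(mus) < 3L || nrow(non) < 3L) {
    stop("too few retained participants per group after exclusions")
  }

  sample_checks <- list(
    n_musicians = nrow(mus), n_non_musicians = nrow(non),
    n_excluded = excluded,
    age_t = two_sample_t(mus$age, non$age, "student"),
    sex_mw = mann_whitney(as.numeric(mus$sex == "male"),
                          as.numeric(non$sex == "male"))
  )
  assumptions <- list(
    levene = levene_test(retained$final_score, retained$group,
                         levene_center),
    age_independence = covariate_independence(retained, "age", "group"),
    slopes = slopes_homogeneity(retained, "final_score", "group", "age")
  )
  ancova <- cbt_ancova(retained, "final_score", "group", c("sex", "age"))

  descriptives <- list(
    by_group = describe_scores(retained$final_score, retained$group),
    by_group_claim = describe_scores(
      retained$final_score,
      paste(retained$group, retained$self_assessment, sep = ":")),
    by_sex = describe_scores(retained$final_score, retained$sex)
  )

  correlations <- list(
    age_overall = pearson_test(retained$age, retained$final_score),
    age_musicians = pearson_test(mus$age, mus$final_score),
    age_non_musicians = pearson_test(non$age, non$final_score),
    years_musicians = pearson_test(mus$years_reading, mus$final_score)
  )

  meta <- metacompetence_table(retained, threshold, denominator)
  metacompetence <- list(
    table = meta,
    chi_square = chisq_table(meta$counts),
    claim_comparison = {
      r <- one_way_f(retained$final_score, retained$self_assessment)
      structure(list(statistic = "F", value = r$F, df1 = r$df1,
                     df2 = r$df2, p = r$p, eta_p_sq = r$eta_p_sq),
                class = "cbt_test")
    }
  )

  experience <- experience_split_anova(retained, experience_cut)

  structure(
    list(sample = sample_checks, assumptions = assumptions,
         ancova = ancova, descriptives = descriptives,
         correlations = correlations, metacompetence = metacompetence,
         experience = experience,
         options = list(threshold = threshold,
                        levene_center = levene_center,
                        experience_cut = experience_cut,
                        denominator = denominator)),
    class = "cbt_report"
  )
}

#' Render a report as text lines
#'
#' @param report a `cbt_report`.
#' @return Character vector of formatted lines (values rounded half-up
#'   at 2-3 decimals for display only).
#' @export
report_text <- function(report) {
  r2 <- function(x) format(round_half_up(x, 2), nsmall = 2)
  fmt_f <- function(t) {
    sprintf("F(%g,%g) = %s, p = %.3f%s", t$df1, t$df2, r2(t$value), t$p,
            if (!is.null(t$eta_p_sq)) {
              sprintf(", eta_p^2 = %.3f", t$eta_p_sq)
            } else "")
  }
  s <- report$sample
  d <- report$descriptives$by_group
  lines <- c(
    "== Sample ==",
    sprintf("retained: %d musicians, %d non-musicians (%d excluded as normal/unable)",
            s$n_musicians, s$n_non_musicians, s$n_excluded),
    sprintf("age matching: t(%g) = %s, p = %.2f, d = %s",
            s$age_t$df, r2(s$age_t$value), s$age_t$p, r2(s$age_t$d)),
    sprintf("sex matching: Mann-Whitney U = %g, p = %.2f",
            s$sex_mw$value, s$sex_mw$p),
    "== Assumption checks ==",
    sprintf("Levene (%s-centred): F(%g,%g) = %s, p = %.2f",
            report$assumptions$levene$center,
            report$assumptions$levene$df1, report$assumptions$levene$df2,
            r2(report$assumptions$levene$value),
            report$assumptions$levene$p),
    sprintf("age/group independence: %s", fmt_f(report$assumptions$age_independence)),
    sprintf("homogeneity of slopes (age): %s", fmt_f(report$assumptions$slopes)),
    "== ANCOVA (score ~ group + sex + age) =="
  )
  tab <- report$ancova$table
  lines <- c(lines, vapply(seq_len(nrow(tab)), function(i) {
    sprintf("%s: F(%d,%d) = %s, p = %.3f, eta_p^2 = %.3f",
            tab$term[i], tab$df1[i], tab$df2[i], r2(tab$F[i]), tab$p[i],
            tab$eta_p_sq[i])
  }, character(1)))
  lines <- c(lines, "== Descriptives (final score) ==")
  lines <- c(lines, vapply(seq_len(nrow(d)), function(i) {
    sprintf("%s: M = %s, SD = %s, 95%% CI [%s, %s], n = %d",
            d$label[i], r2(d$mean[i]), r2(d$sd[i]), r2(d$ci_low[i]),
            r2(d$ci_high[i]), d$n[i])
  }, character(1)))
  co <- report$correlations
  lines <- c(lines,
    "== Correlations ==",
    sprintf("age vs score (all): r(%d) = %s, p = %.2f", co$age_overall$n,
            r2(co$age_overall$value), co$age_overall$p),
    sprintf("age vs score (musicians): r(%d) = %s, p = %.2f",
            co$age_musicians$n, r2(co$age_musicians$value),
            co$age_musicians$p),
    sprintf("age vs score (non-musicians): r(%d) = %s, p = %.2f",
            co$age_non_musicians$n, r2(co$age_non_musicians$value),
            co$age_non_musicians$p),
    sprintf("years reading vs score (musicians): r = %s, p = %.2f",
            r2(co$years_musicians$value), co$years_musicians$p),
    "== Metacompetence ==")
  mt <- report$metacompetence$table
  pc <- mt$percentages
  lines <- c(lines,
    sprintf("claim good & perform good: musicians %s%%, non-musicians %s%% (of %d claim-good)",
            r2(pc["musician", "good_good"]),
            r2(pc["non_musician", "good_good"]), mt$denominator_n),
    sprintf("claim good & perform poor: musicians %s%%, non-musicians %s%%",
            r2(pc["musician", "good_poor"]),
            r2(pc["non_musician", "good_poor"])),
    sprintf("chi-square: chi2 = %s, df = %d, p = %.3f",
            r2(report$metacompetence$chi_square$value),
            report$metacompetence$chi_square$df,
            report$metacompetence$chi_square$p),
    sprintf("claim good vs bad scores: %s",
            fmt_f(report$metacompetence$claim_comparison)),
    "== Experience split (musicians) ==",
    sprintf("<= %g vs > %g years: %s", report$experience$cut,
            report$experience$cut, fmt_f(report$experience))
  )
  lines
}

#' @export
print.cbt_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

# strip classes recursively so jsonlite serializes the report plainly
report_as_list <- function(x) {
  if (is.matrix(x)) {
    return(list(dimnames = dimnames(x),
                values = as.data.frame(as.table(x))))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), report_as_list))
  if (is.table(x)) return(as.list(x))
  x
}
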