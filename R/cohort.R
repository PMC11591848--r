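#' Latent-span respondent model
#'
#' A synthetic respondent recalls each position of a length-`k` sequence
#' independently with probability
#' `(1 - lapse) * plogis((span - k) / tau)`: a soft threshold at the
#' latent span, sharpened as `tau` shrinks, with a floor-level lapse rate
#' for wholly inattentive behaviour. `meta_sigma` is the standard
#' deviation of the noise on the respondent's own perception of their
#' span, used by [self_assess()]. This is a generative stand-in for
#' serial-recall behaviour, not a cognitive claim.
#'
#' @param span latent capacity in blocks.
#' @param tau softness of the span threshold (> 0), blocks.
#' @param lapse probability in `[0, 1)` that attention fails on an item.
#' @param meta_sigma metacognitive noise (>= 0), blocks.
#' @return A `cbt_respondent` list.
#' @export
respondent_model <- function(span, tau = 0.4, lapse = 0.01, meta_sigma = 1) {
  if (!is_number(span)) stop("span must be a number")
  if (!is_number(tau) || tau <= 0) stop("tau must be > 0")
  if (!is_number(lapse) || lapse < 0 || lapse >= 1) stop("lapse must be in [0, 1)")
  if (!is_number(meta_sigma) || meta_sigma < 0) stop("meta_sigma must be >= 0")
  structure(list(span = span, tau = tau, lapse = lapse,
                 meta_sigma = meta_sigma),
            class = "cbt_respondent")
}

#' Per-item recall probability
#'
#' @param k sequence length (vectorized).
#' @param model a [respondent_model()].
#' @return `(1 - lapse) * plogis((span - k) / tau)`; strictly decreasing
#'   in `k` and increasing in `span`.
#' @examples
#' p_item(4, respondent_model(span = 6, tau = 0.75, lapse = 0.02))
#' @export
p_item <- function(k, model) {
  stopifnot(all(k >= 1))
  (1 - model$lapse) * stats::plogis((model$span - k) / model$tau)
}

#' Simulate a respondent's click sequence
#'
#' Each position of the target is reproduced correctly with probability
#' [p_item()] for the target's length; a failed position is replaced by a
#' uniformly chosen wrong block not yet used in the response. The response
#' always has the same length as the target, so partial-credit scoring
#' sees a full-length sequence with positionally independent errors.
#'
#' When every still-unused block equals the target block (possible only at
#' the final position of a board-length sequence), the substitution falls
#' back to the unused set.
#'
#' @param target integer vector of target block ids.
#' @param model a [respondent_model()].
#' @param board the `cbt_board` supplying the block universe.
#' @return Integer vector of block ids, same length as `target`.
#' @export
generate_response <- function(target, model, board = default_board()) {
  k <- length(target)
  ok <- stats::runif(k) < p_item(k, model)
  if (all(ok)) {
    return(as.integer(target))
  }
  ids <- board$blocks$id
  resp <- integer(k)
  for (i in seq_len(k)) {
    if (ok[i]) {
      resp[i] <- target[i]
      next
    }
    used <- resp[seq_len(i - 1L)]
    cand <- setdiff(ids, c(used, target[i]))
    if (length(cand) == 0L) cand <- setdiff(ids, used)
    resp[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  resp
}

#' Simulate a self-assessment label
#'
#' The respondent perceives their span with Gaussian noise
#' (`meta_sigma`) and claims `"good"` visuospatial capability when the
#' perceived span reaches the reference cutoff, `"bad"` otherwise. With
#' small configured probabilities the label is overridden to `"normal"`
#' or `"unable"` (to assess), mirroring interview answers that are
#' excluded from inference downstream.
#'
#' @param model a [respondent_model()].
#' @param spec a [cohort_spec()] (supplies `meta_reference`, `p_normal`,
#'   `p_unable`).
#' @return One of `"good"`, `"bad"`, `"normal"`, `"unable"`.
#' @export
self_assess <- function(model, spec = cohort_spec()) {
  perceived <- model$span + stats::rnorm(1, 0, model$meta_sigma)
  label <- if (perceived >= spec$meta_reference) "good" else "bad"
  u <- stats::runif(1)
  if (u < spec$p_normal) {
    label <- "normal"
  } else if (u < spec$p_normal + spec$p_unable) {
    label <- "unable"
  }
  label
}

#' Cohort specification for the synthetic study
#'
#' Defines the generative model of a two-group (musician / non-musician)
#' cohort: group sizes, per-group age and sex composition, the latent-span
#' model linking group, sex and age to CBT capacity, and the metacognition
#' parameters behind the self-assessment labels.
#'
#' The latent span of a participant is
#' `base_span + delta_group * musician + delta_sex * male +
#'  beta_age * (age - age_ref) + Normal(0, span_sd[group])`.
#'
#' Defaults emulate the reference study conditions: retained groups of
#' 31 musicians and 29 non-musicians; musician ages about 23.6 (SD 3.6,
#' range 19-35) and non-musician ages about 24.6 (SD 6.2, range 18-40);
#' close to half of each group male; musician years of music reading
#' lognormal with mean about 8.25 and SD about 5.25, clipped to 1-25 and
#' uncorrelated with span; no age effect (`beta_age = 0`); span
#' parameters calibrated so that simulated final scores have group means
#' near 7.04 (musicians) and 6.30 (non-musicians) with SDs near 0.78 and
#' 1.10, and a male-female difference near 0.72; musicians carry less
#' metacognitive noise than non-musicians, so their self-assessments
#' track performance better; and about 11.8% / 2.6% of labels are
#' overridden to "normal" / "unable".
#'
#' @param n_musicians,n_non_musicians group sizes.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age parameters,
#'   named vectors with entries `musician` and `non_musician`.
#' @param prop_male probability of a male participant per group.
#' @param base_span latent span of a female non-musician of reference age.
#' @param delta_group musician shift in latent span (blocks).
#' @param delta_sex male shift in latent span (blocks).
#' @param beta_age span slope per year of age.
#' @param age_ref reference age the slope is centred on.
#' @param span_sd between-participant span SD per group.
#' @param tau,lapse respondent model parameters shared by everyone.
#' @param meta_sigma metacognitive noise per group, blocks.
#' @param meta_reference perceived-span cutoff for claiming "good".
#' @param p_normal,p_unable probabilities of overriding a self-assessment
#'   to "normal" / "unable".
#' @param years_meanlog,years_sdlog,years_min,years_max lognormal years of
#'   music reading for musicians (clipped); non-musicians get 0.
#' @param rng_seed optional integer master seed for [sample_cohort()] and
#'   [simulate_study()].
#' @return A `cbt_cohort_spec` list.
#' @export
cohort_spec <- function(n_musicians = 31L, n_non_musicians = 29L,
                        age_mean = c(musician = 23.6, non_musician = 24.62),
                        age_sd = c(musician = 3.6, non_musician = 6.17),
                        age_min = c(musician = 19, non_musician = 18),
                        age_max = c(musician = 35, non_musician = 40),
                        prop_male = c(musician = 0.475, non_musician = 0.48),
                        base_span = 6.49, delta_group = 0.76,
                        delta_sex = 0.75, beta_age = 0, age_ref = 24.1,
                        span_sd = c(musician = 0.66, non_musician = 1.04),
                        tau = 0.4, lapse = 0.01,
                        meta_sigma = c(musician = 0.4, non_musician = 3.5),
                        meta_reference = 7.2,
                        p_normal = 0.118, p_unable = 0.026,
                        years_meanlog = 1.940, years_sdlog = 0.583,
                        years_min = 1, years_max = 25,
                        rng_seed = NULL) {
  grp <- function(x, what) {
    if (length(x) == 1L) x <- c(musician = unname(x), non_musician = unname(x))
    if (!all(c("musician", "non_musician") %in% names(x))) {
      stop(what, " must be named with 'musician' and 'non_musician'")
    }
    x[c("musician", "non_musician")]
  }
  if (!is_count(n_musicians) || !is_count(n_non_musicians)) {
    stop("group sizes must be non-negative integers")
  }
  prop_male <- grp(prop_male, "prop_male")
  if (any(prop_male < 0 | prop_male > 1)) stop("prop_male must lie in [0, 1]")
  span_sd <- grp(span_sd, "span_sd")
  age_sd <- grp(age_sd, "age_sd")
  if (any(span_sd < 0) || any(age_sd < 0)) stop("standard deviations must be >= 0")
  meta_sigma <- grp(meta_sigma, "meta_sigma")
  if (any(meta_sigma < 0)) stop("meta_sigma must be >= 0")
  if (!is_number(tau) || tau <= 0) stop("tau must be > 0")
  if (!is_number(lapse) || lapse < 0 || lapse >= 1) stop("lapse must be in [0, 1)")
  if (p_normal < 0 || p_unable < 0 || p_normal + p_unable >= 1) {
    stop("override probabilities must be >= 0 and sum below 1")
  }
  structure(
    list(n_musicians = as.integer(n_musicians),
         n_non_musicians = as.integer(n_non_musicians),
         age_mean = grp(age_mean, "age_mean"), age_sd = age_sd,
         age_min = grp(age_min, "age_min"), age_max = grp(age_max, "age_max"),
         prop_male = prop_male,
         base_span = base_span, delta_group = delta_group,
         delta_sex = delta_sex, beta_age = beta_age, age_ref = age_ref,
         span_sd = span_sd, tau = tau, lapse = lapse,
         meta_sigma = meta_sigma, meta_reference = meta_reference,
         p_normal = p_normal, p_unable = p_unable,
         years_meanlog = years_meanlog, years_sdlog = years_sdlog,
         years_min = years_min, years_max = years_max,
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "cbt_cohort_spec"
  )
}

#' @export
print.cbt_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "CBT cohort spec: %d musicians + %d non-musicians; span = %.2f + %.2f*musician + %.2f*male\n",
    x$n_musicians, x$n_non_musicians, x$base_span, x$delta_group, x$delta_sex))
  invisible(x)
}

# inverse-CDF truncated normal; parameters recycle elementwise
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  out <- stats::qnorm(p, mean, sd)
  degenerate <- rep_len(sd, n) == 0
  if (any(degenerate)) out[degenerate] <- rep_len(mean, n)[degenerate]
  out
}

#' Sample a synthetic cohort
#'
#' Draws participant attributes and the latent respondent model for each
#' participant. Deterministic given `spec$rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A `cbt_cohort` data frame with one row per participant: `id`,
#'   `group`, `sex`, `age`, `years_reading`, `self_assessment`, plus the
#'   respondent-model columns `span`, `tau`, `lapse`, `meta_sigma`.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cbt_cohort_spec"))
  if (!is.null(spec$rng_seed)) {
    return(with_seed(spec$rng_seed, sample_cohort_impl(spec)))
  }
  sample_cohort_impl(spec)
}

sample_cohort_impl <- function(spec) {
  n <- spec$n_musicians + spec$n_non_musicians
  group <- rep(c("musician", "non_musician"),
               c(spec$n_musicians, spec$n_non_musicians))
  out <- data.frame(id = if (n) sprintf("P%03d", seq_len(n)) else character(0),
                    group = group, stringsAsFactors = FALSE)
  g <- group  # per-row lookup key into the named parameter vectors
  out$sex <- ifelse(stats::runif(n) < spec$prop_male[g], "male", "female")
  out$age <- rtrunc_norm(n, spec$age_mean[g], spec$age_sd[g],
                         spec$age_min[g], spec$age_max[g])
  yrs <- exp(stats::rnorm(n, spec$years_meanlog, spec$years_sdlog))
  yrs <- pmin(pmax(yrs, spec$years_min), spec$years_max)
  out$years_reading <- ifelse(group == "musician", yrs, 0)
  out$span <- spec$base_span +
    spec$delta_group * (group == "musician") +
    spec$delta_sex * (out$sex == "male") +
    spec$beta_age * (out$age - spec$age_ref) +
    stats::rnorm(n, 0, 1) * spec$span_sd[g]
  out$tau <- rep(spec$tau, n)
  out$lapse <- rep(spec$lapse, n)
  out$meta_sigma <- unname(spec$meta_sigma[g])
  out$self_assessment <- vapply(seq_len(n), function(i) {
    self_assess(respondent_model(out$span[i], out$tau[i], out$lapse[i],
                                 out$meta_sigma[i]), spec)
  }, character(1))
  class(out) <- c("cbt_cohort", "data.frame")
  out
}

#' Simulate a full CBT study
#'
#' Samples a cohort, administers one seeded CBT session per participant
#' (the respondent callback is [generate_response()] under that
#' participant's latent model) and scores every session. Fully
#' reproducible from `(spec, seed)`.
#'
#' @param spec a [cohort_spec()]; `spec$rng_seed` (or `seed`) drives all
#'   randomness.
#' @param config a [session_config()].
#' @param board a `cbt_board`.
#' @param seed optional override of `spec$rng_seed`.
#' @param keep_transcripts retain the per-participant transcripts in the
#'   `"transcripts"` attribute (off by default; large).
#' @return A `cbt_study` data frame: cohort columns plus `highest_level`,
#'   `av_level_score`, `final_score`, `session_seed`. Attributes `spec`,
#'   `seed` and `config` record provenance.
#' @examples
#' study <- simulate_study(cohort_spec(n_musicians = 5, n_non_musicians = 5,
#'                                     rng_seed = 7))
#' summary(study$final_score)
#' @export
simulate_study <- function(spec = cohort_spec(), config = session_config(),
                           board = default_board(), seed = NULL,
                           keep_transcripts = FALSE) {
  seed <- seed %||% spec$rng_seed
  if (!is.null(seed)) {
    spec$rng_seed <- NULL  # already applied at the study level
    return(with_seed(seed, simulate_study_impl(spec, config, board, seed,
                                               keep_transcripts)))
  }
  simulate_study_impl(spec, config, board, NULL, keep_transcripts)
}

simulate_study_impl <- function(spec, config, board, seed, keep_transcripts) {
  cohort <- sample_cohort_impl(spec)
  n <- nrow(cohort)
  session_seeds <- if (n) sample.int(2147483646L, n) else integer(0)
  scores <- vector("list", n)
  transcripts <- if (keep_transcripts) vector("list", n) else NULL
  for (i in seq_len(n)) {
    model <- respondent_model(cohort$span[i], cohort$tau[i],
                              cohort$lapse[i], cohort$meta_sigma[i])
    cfg <- config
    cfg$rng_seed <- session_seeds[i]
    tr <- run_session(function(target) generate_response(target, model, board),
                      cfg, board)
    if (keep_transcripts) transcripts[[i]] <- tr
    scores[[i]] <- score_session(tr, cfg)
  }
  cohort$highest_level <- vapply(scores, `[[`, integer(1), "highest_level")
  cohort$av_level_score <- vapply(scores, `[[`, numeric(1), "av_level_score")
  cohort$final_score <- vapply(scores, `[[`, numeric(1), "final_score")
  cohort$session_seed <- session_seeds
  attr(cohort, "spec") <- spec
  attr(cohort, "seed") <- seed
  attr(cohort, "config") <- config
  if (keep_transcripts) attr(cohort, "transcripts") <- transcripts
  class(cohort) <- c("cbt_study", "data.frame")
  cohort
}

#' @export
summary.cbt_study <- function(object, ...) {
  df <- as.data.frame(object)
  out <- do.call(rbind, lapply(split(df$final_score, df$group), function(x) {
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "n", "mean", "sd")]
}
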