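#' Score one trial with positional partial credit
#'
#' One item credit is earned for every serial position at which the
#' response reproduces the target block exactly (same block, same position
#' in the sequence). Credits are computed over the overlap of the two
#' sequences only: missing positions earn nothing, and extra clicks beyond
#' the target length earn nothing and void full correctness. A block
#' recalled in the wrong position earns no credit.
#'
#' @param target integer vector of target block ids.
#' @param response integer vector of clicked block ids (may be empty).
#' @return A `cbt_trial` list with `target`, `response`, `item_credits`
#'   and `fully_correct`.
#' @examples
#' score_trial(c(1, 2, 3), c(2, 1, 3))  # only the third position matches
#' @export
score_trial <- function(target, response) {
  target <- as.integer(target)
  response <- as.integer(response)
  if (length(target) < 1L) stop("target must be non-empty")
  m <- min(length(target), length(response))
  credits <- if (m == 0L) 0L else sum(target[seq_len(m)] == response[seq_len(m)])
  structure(
    list(target = target, response = response,
         item_credits = as.integer(credits),
         fully_correct = length(response) == length(target) &&
           credits == length(target)),
    class = "cbt_trial"
  )
}

#' Average item credits over the trials of a level
#'
#' @param trials either a list of `cbt_trial` objects (all from the same
#'   level) or a numeric vector of item credits.
#' @return The mean item credit per trial, unrounded.
#' @examples
#' level_average(c(2, 2, 1))  # 1.666...
#' @export
level_average <- function(trials) {
  credits <- if (is.numeric(trials)) {
    trials
  } else {
    if (length(trials) == 0L) stop("empty trial list")
    vapply(trials, function(t) as.numeric(t$item_credits), numeric(1))
  }
  if (length(credits) == 0L) stop("empty trial list")
  mean(credits)
}

#' Final CBT score from the terminal level
#'
#' The session score is `L - 1 + avLevelScore / L`, where `L` is the
#' highest (last administered) level and `avLevelScore` the average item
#' credit over the trials at that level. With `avLevelScore` in `[0, L]`
#' the score lies in `[L - 1, L]`, so the integer part identifies the
#' terminal level and the fraction grades performance within it.
#'
#' @param L highest level reached (last level administered, including a
#'   failed final level).
#' @param av_level_score average item credits at level `L`.
#' @param check validate `0 <= av_level_score <= L` (disabled internally
#'   for the non-default averaging convention, which can exceed `L`).
#' @return The final score, unrounded. Round with [round_half_up()] at
#'   report time.
#' @examples
#' final_result(3, 1.67)  # 2.5567 -> prints as 2.56
#' @export
final_result <- function(L, av_level_score, check = TRUE) {
  if (!is_count(L, 1L)) stop("L must be a positive integer")
  if (!is_number(av_level_score)) stop("av_level_score must be a number")
  if (check && (av_level_score < 0 || av_level_score > L)) {
    stop("av_level_score must lie in [0, L]")
  }
  L - 1 + av_level_score / L
}

#' Score a full session transcript
#'
#' Computes per-level results and the final score of a session. The
#' highest level `L` is the last level administered — the failed level
#' for `failed_level` terminations, or `max_level` when the whole test was
#' passed. `avLevelScore` averages item credits over the trials at `L`.
#'
#' The averaging divisor is the number of trials at the terminal level
#' (`divisor = "trials"`, the default). The alternative reading
#' `"sequence_length"` divides the summed credits by `L` instead; the two
#' coincide when `L` equals the number of trials per level.
#'
#' @param transcript a `cbt_transcript` from [run_session()].
#' @param config the session config (defaults to the transcript snapshot).
#' @param divisor averaging convention, see Details.
#' @return A `cbt_session_score`: list with `highest_level`,
#'   `av_level_score`, `final_score` and `per_level` (level, credits per
#'   trial, passed flag).
#' @export
score_session <- function(transcript, config = transcript$config,
                          divisor = c("trials", "sequence_length")) {
  stopifnot(inherits(transcript, "cbt_transcript"))
  divisor <- match.arg(divisor)
  if (length(transcript$levels) == 0L) stop("transcript has no levels")
  per_level <- lapply(transcript$levels, function(lv) {
    scored <- lapply(lv$trials, function(t) score_trial(t$target, t$response))
    credits <- vapply(scored, `[[`, integer(1), "item_credits")
    n_full <- sum(vapply(scored, `[[`, logical(1), "fully_correct"))
    list(level = lv$level, item_credits = credits,
         n_fully_correct = n_full,
         passed = n_full >= config$pass_min_correct)
  })
  last <- per_level[[length(per_level)]]
  L <- last$level
  av <- switch(divisor,
    trials = mean(last$item_credits),
    sequence_length = sum(last$item_credits) / L
  )
  structure(
    list(highest_level = L, av_level_score = av,
         final_score = final_result(L, av, check = divisor == "trials"),
         divisor = divisor, per_level = per_level,
         termination = transcript$termination),
    class = "cbt_session_score"
  )
}

#' @export
print.cbt_session_score <- function(x, ...) {
  cat(sprintf("CBT session: L = %d, avLevelScore = %s, final score = %s\n",
              x$highest_level,
              format(round_half_up(x$av_level_score, 2), nsmall = 2),
              format(round_half_up(x$final_score, 2), nsmall = 2)))
  invisible(x)
}

#' Label a final score as good or poor
#'
#' The split used by the metacompetence analysis. The protocol itself does
#' not define "good performance"; the default cutoff of 7 matches the
#' binning used when relating scores to experience (under 7 / 7-8 / over
#' 8), and scores equal to the threshold count as good.
#'
#' @param final_score numeric vector of final scores.
#' @param threshold performance cutoff.
#' @return Character vector, `"good"` or `"poor"`.
#' @export
classify_performance <- function(final_score, threshold = 7) {
  ifelse(final_score >= threshold, "good", "poor")
}
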