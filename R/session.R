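#' Session configuration for the computerized CBT
#'
#' Bundles the administration parameters of one Corsi block-tapping
#' session. Defaults follow the standard computerized protocol: sequences
#' start at two blocks, three trials are given per sequence length, one
#' fully correct trial out of three is enough to advance, and each block
#' highlights for 1 s with 0.5 s between blocks after a 5 s preparation
#' delay. Timing fields are recorded metadata only; the engine is
#' callback-driven and never sleeps, because it simulates respondents
#' rather than presenting stimuli to humans.
#'
#' @param start_length length of the first sequences (blocks).
#' @param trials_per_level trials administered at each sequence length.
#' @param pass_min_correct fully correct trials needed to advance a level.
#' @param max_level longest sequence administered. Sequences never repeat a
#'   block, so this may not exceed the number of blocks on the board.
#' @param highlight_s,inter_block_s,prep_delay_s presentation timing in
#'   seconds (metadata).
#' @param rng_seed optional integer seed; when set, [run_session()] is
#'   bit-reproducible and leaves the global RNG stream untouched.
#' @return An object of class `cbt_config` (a list).
#' @export
session_config <- function(start_length = 2L, trials_per_level = 3L,
                           pass_min_correct = 1L, max_level = 10L,
                           highlight_s = 1.0, inter_block_s = 0.5,
                           prep_delay_s = 5.0, rng_seed = NULL) {
  if (!is_count(start_length, 1L)) stop("start_length must be an integer >= 1")
  if (!is_count(trials_per_level, 1L)) stop("trials_per_level must be an integer >= 1")
  if (!is_count(pass_min_correct, 1L) || pass_min_correct > trials_per_level) {
    stop("pass_min_correct must satisfy 1 <= pass_min_correct <= trials_per_level")
  }
  if (!is_count(max_level, 1L) || max_level < start_length) {
    stop("max_level must be an integer >= start_length")
  }
  structure(
    list(start_length = as.integer(start_length),
         trials_per_level = as.integer(trials_per_level),
         pass_min_correct = as.integer(pass_min_correct),
         max_level = as.integer(max_level),
         highlight_s = highlight_s, inter_block_s = inter_block_s,
         prep_delay_s = prep_delay_s,
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "cbt_config"
  )
}

#' @export
print.cbt_config <- function(x, ...) {
  cat(sprintf(
    "CBT session config: levels %d..%d, %d trials/level, pass >= %d correct\n",
    x$start_length, x$max_level, x$trials_per_level, x$pass_min_correct))
  invisible(x)
}

#' Draw a random target sequence
#'
#' Uniformly samples an ordered selection of `level` distinct block ids
#' from the board (a sequence never revisits a block). Uses the current
#' RNG state, so results are reproducible under [set.seed()].
#'
#' @param level sequence length.
#' @param board a `cbt_board`.
#' @return Integer vector of block ids of length `level`.
#' @examples
#' set.seed(1)
#' generate_sequence(3, default_board())
#' @export
generate_sequence <- function(level, board = default_board()) {
  n <- nrow(board$blocks)
  if (!is_count(level, 1L)) stop("level must be a positive integer")
  if (level > n) {
    stop("impossible sequence length: level ", level,
         " exceeds the ", n, "-block board")
  }
  # sample() on the id vector directly would misbehave for 1-block boards,
  # but boards always have >= 2 blocks
  sample(board$blocks$id, level)
}

#' Administer one CBT session
#'
#' Runs the level-progression state machine against a respondent callback.
#' At each sequence length the engine presents `trials_per_level` fresh
#' random sequences (all trials are administered before the pass decision),
#' counts trials reproduced fully correctly (exact ids, order and length),
#' and advances one level iff at least `pass_min_correct` trials were fully
#' correct. The session ends at the first failed level
#' (`termination = "failed_level"`) or after passing `max_level`
#' (`termination = "reached_max"`).
#'
#' @param respond function taking a target sequence (integer vector of
#'   block ids) and returning the respondent's click sequence (integer
#'   vector of block ids; may be empty or of any length).
#' @param config a [session_config()].
#' @param board a `cbt_board`.
#' @return A `cbt_transcript`: list with the config snapshot, the seed,
#'   a `levels` list (each with `level`, `trials` of `(target, response)`
#'   pairs, and `passed`) and the `termination` reason.
#' @examples
#' echo <- function(target) target
#' tr <- run_session(echo, session_config(rng_seed = 42))
#' tr$termination
#' @export
run_session <- function(respond, config = session_config(),
                        board = default_board()) {
  if (!is.function(respond)) stop("`respond` must be a function")
  if (config$max_level > nrow(board$blocks)) {
    stop("max_level (", config$max_level, ") exceeds the number of blocks (",
         nrow(board$blocks), "); sequences never repeat a block")
  }
  if (!is.null(config$rng_seed)) {
    return(with_seed(config$rng_seed, run_session_impl(respond, config, board)))
  }
  run_session_impl(respond, config, board)
}

run_session_impl <- function(respond, config, board) {
  ids <- board$blocks$id
  levels <- list()
  level <- config$start_length
  repeat {
    trials <- vector("list", config$trials_per_level)
    n_ok <- 0L
    for (j in seq_len(config$trials_per_level)) {
      target <- generate_sequence(level, board)
      response <- respond(target)
      if (!(is.numeric(response) || length(response) == 0L)) {
        stop("respondent callback must return a vector of block ids")
      }
      response <- as.integer(response)
      if (length(response) && !all(response %in% ids)) {
        stop("response contains unknown block ids: ",
             paste(unique(setdiff(response, ids)), collapse = ", "))
      }
      if (length(response) == level && all(response == target)) {
        n_ok <- n_ok + 1L
      }
      trials[[j]] <- list(target = target, response = response)
    }
    passed <- n_ok >= config$pass_min_correct
    levels[[length(levels) + 1L]] <-
      list(level = level, trials = trials, passed = passed)
    if (!passed) {
      termination <- "failed_level"
      break
    }
    if (level >= config$max_level) {
      termination <- "reached_max"
      break
    }
    level <- level + 1L
  }
  structure(
    list(config = config, seed = config$rng_seed, levels = levels,
         termination = termination),
    class = "cbt_transcript"
  )
}

#' @export
print.cbt_transcript <- function(x, ...) {
  lv <- vapply(x$levels, `[[`, integer(1), "level")
  cat(sprintf("CBT transcript: levels %d..%d, termination: %s\n",
              min(lv), max(lv), x$termination))
  invisible(x)
}

transcript_levels <- function(transcript) {
  vapply(transcript$levels, `[[`, integer(1), "level")
}
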