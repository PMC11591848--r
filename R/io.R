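#' Read and write participant tables
#'
#' Participants CSV: UTF-8, comma-separated, header row, columns `id`,
#' `group`, `sex`, `age`, `years_reading`, `self_assessment`. Group and
#' sex are stored as lowercase strings, never integer codes.
#'
#' @param data data frame with at least the participant columns.
#' @param path file path.
#' @return `read_participants()` returns a data frame; the writers return
#'   `path` invisibly.
#' @export
write_participants <- function(data, path) {
  df <- as.data.frame(data)
  cols <- c("id", "group", "sex", "age", "years_reading", "self_assessment")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("id", "group", "sex", "age", "years_reading", "self_assessment")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("malformed participants file, missing: ",
         paste(missing_cols, collapse = ", "))
  }
  df$id <- as.character(df$id)
  df
}

#' Read and write score tables
#'
#' Scores CSV columns: `id` (when available), `highest_level`,
#' `av_level_score`, `final_score`, `performance_label`.
#'
#' @param data a `cbt_study` or data frame with score columns.
#' @param path file path.
#' @param threshold cutoff for the performance label.
#' @return `read_scores()` returns a data frame; `write_scores()` returns
#'   `path` invisibly.
#' @export
write_scores <- function(data, path, threshold = 7) {
  df <- as.data.frame(data)
  cols <- c("highest_level", "av_level_score", "final_score")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    id = if ("id" %in% names(df)) df$id else sprintf("P%03d", seq_len(nrow(df))),
    highest_level = df$highest_level,
    av_level_score = df$av_level_score,
    final_score = df$final_score,
    performance_label = classify_performance(df$final_score, threshold),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "final_score") %in% names(df))) {
    stop("malformed scores file: needs id and final_score columns")
  }
  df$id <- as.character(df$id)
  df
}

#' Serialize session transcripts as JSON lines
#'
#' One session per line so cohorts of any size stream. Each line holds
#' the participant id, the seed, a config snapshot, the ordered trials
#' (`level`, `target`, `response`) and the termination reason.
#'
#' @param transcripts list of `cbt_transcript` objects.
#' @param path file path.
#' @param ids optional character vector of participant ids.
#' @return `read_sessions()` returns a list of `cbt_transcript`s (with an
#'   `id` field); `write_sessions()` returns `path` invisibly.
#' @export
write_sessions <- function(transcripts, path, ids = NULL) {
  ids <- ids %||% sprintf("P%03d", seq_along(transcripts))
  stopifnot(length(ids) == length(transcripts))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(transcripts)) {
    tr <- transcripts[[i]]
    trials <- do.call(c, lapply(tr$levels, function(lv) {
      lapply(lv$trials, function(t) {
        list(level = lv$level, target = as.integer(t$target),
             response = as.integer(t$response))
      })
    }))
    line <- jsonlite::toJSON(
      list(id = ids[i], seed = tr$seed,
           config = unclass(tr$config)[c("start_length", "trials_per_level",
                                         "pass_min_correct", "max_level")],
           termination = tr$termination, trials = trials),
      auto_unbox = TRUE, null = "null", digits = NA
    )
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    j <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed session JSON at line ", i, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    for (fld in c("config", "trials", "termination")) {
      if (is.null(j[[fld]])) {
        stop("malformed session at line ", i, ": missing field '", fld, "'",
             call. = FALSE)
      }
    }
    cfg <- session_config(
      start_length = j$config$start_length,
      trials_per_level = j$config$trials_per_level,
      pass_min_correct = j$config$pass_min_correct,
      max_level = j$config$max_level,
      rng_seed = j$seed
    )
    lv_ids <- vapply(j$trials, function(t) {
      if (is.null(t$level) || is.null(t$target)) {
        stop("malformed trial at line ", i, ": missing level/target",
             call. = FALSE)
      }
      as.integer(t$level)
    }, integer(1))
    levels <- lapply(unique(lv_ids), function(lv) {
      trs <- j$trials[lv_ids == lv]
      trials <- lapply(trs, function(t) {
        list(target = as.integer(unlist(t$target)),
             response = as.integer(unlist(t$response)))
      })
      n_ok <- sum(vapply(trials, function(t) {
        length(t$response) == length(t$target) &&
          all(t$response == t$target)
      }, logical(1)))
      list(level = as.integer(lv), trials = trials,
           passed = n_ok >= cfg$pass_min_correct)
    })
    structure(list(id = j$id, config = cfg, seed = j$seed, levels = levels,
                   termination = j$termination),
              class = "cbt_transcript")
  })
}

#' Simulate a study and write its dataset to files
#'
#' Runs [simulate_study()] and writes `participants.csv`, `scores.csv`,
#' `sessions.jsonl` and `provenance.json` (seed, package version and full
#' cohort spec) into `out_dir`. Byte-identical outputs for identical
#' `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param config a [session_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; mandatory here so simulated datasets are
#'   always reproducible.
#' @param threshold performance cutoff recorded in the scores file.
#' @return Invisibly, the named vector of file paths.
#' @export
simulate_to_files <- function(spec = cohort_spec(),
                              config = session_config(), out_dir,
                              seed = spec$rng_seed, threshold = 7) {
  if (is.null(seed)) stop("a seed is mandatory for simulate commands")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(spec, config, seed = seed, keep_transcripts = TRUE)
  paths <- c(
    participants = file.path(out_dir, "participants.csv"),
    scores = file.path(out_dir, "scores.csv"),
    sessions = file.path(out_dir, "sessions.jsonl"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_participants(study, paths["participants"])
  write_scores(study, paths["scores"], threshold)
  write_sessions(attr(study, "transcripts"), paths["sessions"],
                 ids = study$id)
  spec_plain <- unclass(spec)
  spec_plain <- lapply(spec_plain, function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(
    list(tool = "corsiblocks",
         version = as.character(utils::packageVersion("corsiblocks")),
         seed = seed, threshold = threshold, cohort_spec = spec_plain),
    paths["provenance"], auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}

#' Score a session-log file
#'
#' Reads a JSON-lines session log, scores every session and writes a
#' scores CSV. Malformed lines are reported with their line number.
#'
#' @param sessions_path input JSON-lines file.
#' @param out_path output CSV path.
#' @param threshold performance cutoff.
#' @param divisor averaging convention, see [score_session()].
#' @return Invisibly, the scores data frame.
#' @export
score_sessions_file <- function(sessions_path, out_path, threshold = 7,
                                divisor = "trials") {
  transcripts <- read_sessions(sessions_path)
  if (length(transcripts) == 0L) {
    df <- data.frame(id = character(0), highest_level = integer(0),
                     av_level_score = numeric(0), final_score = numeric(0),
                     performance_label = character(0))
    utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  scored <- lapply(transcripts, function(tr) {
    score_session(tr, divisor = divisor)
  })
  df <- data.frame(
    id = vapply(transcripts, function(tr) tr$id %||% NA_character_,
                character(1)),
    highest_level = vapply(scored, `[[`, integer(1), "highest_level"),
    av_level_score = vapply(scored, `[[`, numeric(1), "av_level_score"),
    final_score = vapply(scored, `[[`, numeric(1), "final_score"),
    stringsAsFactors = FALSE
  )
  df$performance_label <- classify_performance(df$final_score, threshold)
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Join participant and score files and run the full analysis
#'
#' @param participants_path participants CSV.
#' @param scores_path scores CSV.
#' @param out_json path for the machine-readable report (JSON).
#' @param out_txt optional path for the plain-text summary.
#' @param out_descriptives optional path for a descriptives CSV (group by
#'   self-assessment rows with t intervals).
#' @param ... options passed to [run_full_analysis()].
#' @return The `cbt_report`, invisibly.
#' @export
analyze_files <- function(participants_path, scores_path, out_json,
                          out_txt = NULL, out_descriptives = NULL, ...) {
  participants <- read_participants(participants_path)
  scores <- read_scores(scores_path)
  unmatched <- c(setdiff(participants$id, scores$id),
                 setdiff(scores$id, participants$id))
  if (length(unmatched)) {
    stop("unmatched ids between participants and scores: ",
         paste(unique(unmatched), collapse = ", "))
  }
  joined <- merge(participants, scores, by = "id")
  report <- run_full_analysis(joined, ...)
  write_report(report, out_json, out_txt)
  if (!is.null(out_descriptives)) {
    utils::write.csv(report$descriptives$by_group_claim, out_descriptives,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

#' Write an analysis report to disk
#'
#' @param report a `cbt_report`.
#' @param json_path JSON output path.
#' @param txt_path optional plain-text summary path.
#' @return Invisibly, `json_path`.
#' @export
write_report <- function(report, json_path, txt_path = NULL) {
  jsonlite::write_json(report_as_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  if (!is.null(txt_path)) writeLines(report_text(report), txt_path)
  invisible(json_path)
}

#' Monte-Carlo rejection rates for the ANCOVA terms
#'
#' Simulates replicate studies under a cohort spec, applies the pipeline's
#' exclusion filter, runs the group ANCOVA (with sex and age covariates)
#' on each replicate and reports per-term rejection rates at `alpha` with
#' their Monte-Carlo standard errors. With a null spec
#' (`delta_group = 0`) the group-term rate estimates the type-I error;
#' with an effect spec it estimates power.
#'
#' @param spec a [cohort_spec()].
#' @param config a [session_config()].
#' @param replicates number of simulated studies.
#' @param alpha significance level.
#' @param seed integer seed for the whole harness.
#' @return Data frame with `term`, `rejections`, `replicates`, `rate`,
#'   `mc_se`.
#' @export
power_analysis <- function(spec = cohort_spec(), config = session_config(),
                           replicates = 100, alpha = 0.05, seed = 1) {
  stopifnot(replicates >= 1)
  with_seed(seed, {
    rep_seeds <- sample.int(2147483646L, replicates)
    terms <- c("group", "sex", "age")
    hits <- matrix(0L, nrow = replicates, ncol = length(terms),
                   dimnames = list(NULL, terms))
    for (r in seq_len(replicates)) {
      study <- simulate_study(spec, config, seed = rep_seeds[r])
      retained <- study[study$self_assessment %in% c("good", "bad"), ,
                        drop = FALSE]
      a <- cbt_ancova(retained, "final_score", "group", c("sex", "age"))
      p <- stats::setNames(a$table$p, a$table$term)
      hits[r, ] <- as.integer(p[terms] < alpha)
    }
    rate <- colMeans(hits)
    data.frame(term = terms, rejections = colSums(hits),
               replicates = replicates, rate = rate,
               mc_se = sqrt(rate * (1 - rate) / replicates),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}
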