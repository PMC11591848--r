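# Respondent callbacks -------------------------------------------------

echo_respondent <- function(target) target
empty_respondent <- function(target) integer(0)

# echoes targets up to length s, otherwise responds with nothing
span_respondent <- function(s) {
  function(target) if (length(target) <= s) target else integer(0)
}

# Independent oracles ---------------------------------------------------

# positional scorer written as a direct loop, independent of score_trial
brute_force_credits <- function(target, response) {
  credits <- 0L
  for (i in seq_along(target)) {
    if (i <= length(response) && response[i] == target[i]) {
      credits <- credits + 1L
    }
  }
  credits
}

# OLS through explicit normal equations; returns the residual sum of
# squares for a response and design matrix
oracle_sse <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

# partial F for dropping the columns `drop` from design X (intercept in
# column 1), computed entirely from normal-equation arithmetic
oracle_partial_f <- function(X, y, drop) {
  sse_full <- oracle_sse(X, y)
  sse_red <- oracle_sse(X[, -drop, drop = FALSE], y)
  df1 <- length(drop)
  df2 <- nrow(X) - ncol(X)
  f <- ((sse_red - sse_full) / df1) / (sse_full / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ss = sse_red - sse_full, sse = sse_full)
}

# hand-rolled one-way ANOVA from sums of squares
oracle_one_way <- function(x, g) {
  g <- as.character(g)
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(lapply(split(x, g), function(v) sum((v - mean(v))^2))))
  df1 <- length(unique(g)) - 1
  df2 <- length(x) - length(unique(g))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Fixtures --------------------------------------------------------------

# transcript reproducing the worked scoring example: a passed level 2,
# then a failed level 3 whose trials earn credits 2, 2 and 1
worked_example_transcript <- function() {
  lvl2 <- list(level = 2L,
               trials = list(list(target = c(1L, 2L), response = c(1L, 2L)),
                             list(target = c(3L, 4L), response = c(3L, 1L)),
                             list(target = c(5L, 6L), response = c(6L, 5L))),
               passed = TRUE)
  lvl3 <- list(level = 3L,
               trials = list(
                 list(target = c(1L, 2L, 3L), response = c(1L, 2L, 4L)),
                 list(target = c(4L, 5L, 6L), response = c(4L, 1L, 6L)),
                 list(target = c(7L, 8L, 9L), response = c(7L, 9L, 8L))),
               passed = FALSE)
  structure(list(config = session_config(), seed = NULL,
                 levels = list(lvl2, lvl3), termination = "failed_level"),
            class = "cbt_transcript")
}

# tiny three-block board for exhaustive sequence enumeration
tiny_board <- function(n = 3) {
  board_layout(data.frame(id = seq_len(n),
                          x_cm = seq(2, by = 4, length.out = n),
                          y_cm = rep(2, n)),
               window_w_cm = 4 * n + 2, window_h_cm = 4)
}

random_trial_pair <- function(board_n = 10) {
  k <- sample(1:board_n, 1)
  target <- sample.int(board_n, k)
  response <- sample.int(board_n, sample(0:board_n, 1))
  list(target = target, response = response)
}
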