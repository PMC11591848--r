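test_that("per-item recall probability matches the logistic formula", {
  m0 <- respondent_model(span = 5, tau = 1, lapse = 0)
  expect_equal(p_item(5, m0), 0.5)            # logistic midpoint
  m_step <- respondent_model(span = 5, tau = 1e-9, lapse = 0)
  expect_equal(p_item(4, m_step), 1)          # step-function limit
  expect_equal(p_item(6, m_step), 0)
  m <- respondent_model(span = 6, tau = 0.75, lapse = 0.02)
  # independent arithmetic evaluation of the same formula
  expect_equal(p_item(4, m), 0.98 * (1 / (1 + exp(-(6 - 4) / 0.75))))
  expect_true(all(diff(p_item(1:10, m)) < 0))
})

test_that("responses echo the target when recall is certain and never match when impossible", {
  b <- default_board()
  sure <- respondent_model(span = 50, tau = 0.1, lapse = 0)
  set.seed(8)
  for (i in 1:20) {
    target <- generate_sequence(5, b)
    expect_identical(generate_response(target, sure, b), target)
  }
  never <- respondent_model(span = -50, tau = 0.1, lapse = 0)
  for (i in 1:20) {
    target <- generate_sequence(4, b)
    resp <- generate_response(target, never, b)
    expect_length(resp, 4)
    expect_true(all(resp != target))          # wrong-block substitution
    expect_false(anyDuplicated(resp) > 0)
  }
})

test_that("item accuracy concentrates around p_item (Monte Carlo)", {
  b <- default_board()
  m <- respondent_model(span = 5, tau = 0.5, lapse = 0)
  p <- p_item(4, m)
  n <- 10000
  set.seed(99)
  hits <- numeric(n)
  for (i in seq_len(n)) {
    target <- generate_sequence(4, b)
    resp <- generate_response(target, m, b)
    hits[i] <- score_trial(target, resp)$item_credits / 4
  }
  se <- sqrt(p * (1 - p) / (4 * n))
  expect_lt(abs(mean(hits) - p), 3 * se)
})

test_that("self-assessment tracks the latent span when noise-free", {
  spec <- cohort_spec(p_normal = 0, p_unable = 0)
  confident <- respondent_model(span = spec$meta_reference + 1, tau = 0.4,
                                lapse = 0, meta_sigma = 0)
  doubtful <- respondent_model(span = spec$meta_reference - 1, tau = 0.4,
                               lapse = 0, meta_sigma = 0)
  set.seed(1)
  expect_identical(self_assess(confident, spec), "good")
  expect_identical(self_assess(doubtful, spec), "bad")
})

test_that("huge metacognitive noise degrades self-assessment to a coin flip", {
  spec <- cohort_spec(p_normal = 0, p_unable = 0)
  m <- respondent_model(span = spec$meta_reference + 0.5, tau = 0.4,
                        lapse = 0, meta_sigma = 1e6)
  set.seed(13)
  labels <- replicate(10000, self_assess(m, spec))
  agree <- mean(labels == "good")   # truth is "good" (span above reference)
  expect_lt(abs(agree - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("cohort sampling honours the spec and the seed", {
  flat <- cohort_spec(n_musicians = 15, n_non_musicians = 15,
                      delta_group = 0, delta_sex = 0, beta_age = 0,
                      span_sd = c(musician = 0, non_musician = 0),
                      rng_seed = 4)
  co <- sample_cohort(flat)
  expect_equal(nrow(co), 30)
  expect_true(all(co$span == flat$base_span))
  expect_true(all(co$years_reading[co$group == "musician"] >= 1))
  expect_true(all(co$years_reading[co$group == "non_musician"] == 0))
  expect_true(all(co$age >= 18 & co$age <= 40))
  expect_true(all(co$self_assessment %in% c("good", "bad", "normal", "unable")))

  co2 <- sample_cohort(flat)
  expect_identical(co, co2)                 # same seed, same cohort
  expect_error(cohort_spec(span_sd = c(musician = -1, non_musician = 1)),
               ">= 0")
})

test_that("extreme respondents hit the score floor and ceiling", {
  perfect <- cohort_spec(n_musicians = 4, n_non_musicians = 4,
                         base_span = 12, delta_group = 0, delta_sex = 0,
                         span_sd = c(musician = 0, non_musician = 0),
                         tau = 1e-6, lapse = 0, rng_seed = 9)
  st <- simulate_study(perfect)
  expect_true(all(st$final_score == 10))

  floor_spec <- cohort_spec(n_musicians = 4, n_non_musicians = 4,
                            base_span = 0, delta_group = 0, delta_sex = 0,
                            span_sd = c(musician = 0, non_musician = 0),
                            tau = 1e-6, lapse = 0, rng_seed = 10)
  st0 <- simulate_study(floor_spec)
  expect_true(all(st0$final_score == 1))
  expect_true(all(st0$highest_level == 2))
})

test_that("studies are reproducible from (spec, seed) and scores stay in [1, 10]", {
  spec <- cohort_spec(n_musicians = 10, n_non_musicians = 10, rng_seed = 77)
  a <- simulate_study(spec)
  b <- simulate_study(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$final_score >= 1 & a$final_score <= 10))
})

test_that("a larger musician shift increases the musician mean (common random numbers)", {
  base <- cohort_spec(n_musicians = 400, n_non_musicians = 400,
                      delta_group = 0.3)
  more <- cohort_spec(n_musicians = 400, n_non_musicians = 400,
                      delta_group = 1.2)
  a <- as.data.frame(simulate_study(base, seed = 1234))
  b <- as.data.frame(simulate_study(more, seed = 1234))
  expect_gt(mean(b$final_score[b$group == "musician"]),
            mean(a$final_score[a$group == "musician"]))
})

test_that("study-size replicates keep group means inside the plausible envelope", {
  # Monte-Carlo envelope from the calibration: group means 7.04 / 6.30
  # with SEs 0.78/sqrt(31) ~ 0.14 and 1.10/sqrt(29) ~ 0.20, so a joint
  # 95% envelope needs ~2.3 SEs around the wider non-musician mean:
  # [6.30 - 0.46, 7.04 + 0.33] -> [5.84, 7.37], padded to [5.8, 7.6]
  spec <- cohort_spec()                     # default calibrated conditions
  set.seed(2024)
  seeds <- sample.int(2^31 - 2, 200)
  inside <- logical(200)
  for (i in seq_along(seeds)) {
    st <- as.data.frame(simulate_study(spec, seed = seeds[i]))
    m <- tapply(st$final_score, st$group, mean)
    inside[i] <- all(m >= 5.8 & m <= 7.6)
  }
  expect_gte(mean(inside), 0.95)
})
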