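test_that("trials to criterion counts the trailing correct run", {
  expect_equal(trials_to_criterion(rep(TRUE, 6), 6), 6L)
  expect_equal(trials_to_criterion(c(FALSE, rep(TRUE, 6)), 6), 7L)
  expect_true(is.na(trials_to_criterion(rep(c(TRUE, FALSE), 10), 6)))
  # the criterion trials are included: perfect run == criterion, any criterion
  for (k in 1:10)
    expect_equal(trials_to_criterion(rep(TRUE, k + 3), k), k)
  expect_error(trials_to_criterion(logical(0)), "non-empty")
})

test_that("perseverative errors count early incorrect choices per reversal", {
  # immediate switch at the reversal
  s <- make_session(choice = c(rep(0L, 6), rep(1L, 6)),
                    win = rep(TRUE, 12),
                    stage_index = rep(1:2, each = 6),
                    correct = rep(TRUE, 12))
  expect_equal(unname(perseverative_errors(s)), 0L)

  # full perseveration through the window
  s2 <- make_session(choice = rep(0L, 14),
                     win = rep(TRUE, 14),
                     stage_index = rep(1:2, each = 7),
                     correct = c(rep(TRUE, 7), rep(FALSE, 7)))
  expect_equal(unname(perseverative_errors(s2)), 6L)

  # truncated reversal stage clips the window
  s3 <- make_session(choice = rep(0L, 9),
                     win = rep(TRUE, 9),
                     stage_index = c(rep(1L, 6), rep(2L, 3)),
                     correct = c(rep(TRUE, 6), rep(FALSE, 3)))
  expect_equal(unname(perseverative_errors(s3)), 3L)
  expect_error(perseverative_errors(s3[s3$stage_index == 1L, ]), "2 stages")
})

test_that("win-stay / lose-shift matches the hand enumeration", {
  # choices A,A,B,A with outcomes win,win,loss,-
  s <- make_session(choice = c(0L, 0L, 1L, 0L),
                    win = c(TRUE, TRUE, FALSE, FALSE))
  w <- win_stay_lose_shift(s)
  expect_equal(w$win_stay, 1 / 2)
  expect_equal(w$lose_shift, 1 / 1)
  expect_equal(w$n_win, 2L)
  expect_equal(w$n_loss, 1L)

  # all-win constant choice: win-stay 1, lose-shift undefined
  s2 <- make_session(rep(1L, 5), rep(TRUE, 5))
  w2 <- win_stay_lose_shift(s2)
  expect_equal(w2$win_stay, 1)
  expect_true(is.na(w2$lose_shift))
  expect_equal(w2$n_loss, 0L)

  # strict alternation with all wins
  s3 <- make_session(rep(c(0L, 1L), 4), rep(TRUE, 8))
  expect_equal(win_stay_lose_shift(s3)$win_stay, 0)
})

test_that("WSLS equals brute-force pair enumeration on random sessions", {
  brute <- function(session, within_stage = FALSE) {
    ws_n <- ws_d <- ls_n <- ls_d <- 0
    for (t in seq_len(nrow(session) - 1L)) {
      if (within_stage &&
          session$stage_index[t] != session$stage_index[t + 1L]) next
      stay <- session$choice[t + 1L] == session$choice[t]
      if (session$win[t]) {
        ws_d <- ws_d + 1; ws_n <- ws_n + stay
      } else {
        ls_d <- ls_d + 1; ls_n <- ls_n + !stay
      }
    }
    c(ws = if (ws_d) ws_n / ws_d else NA_real_,
      ls = if (ls_d) ls_n / ls_d else NA_real_)
  }
  set.seed(7)
  for (i in 1:30) {
    s <- random_session(n = sample(10:80, 1))
    for (within in c(FALSE, TRUE)) {
      got <- win_stay_lose_shift(s, within_stage = within)
      want <- brute(s, within)
      expect_equal(got$win_stay, unname(want["ws"]))
      expect_equal(got$lose_shift, unname(want["ls"]))
    }
    # credit strata recompose the unstratified totals
    by_cr <- win_stay_lose_shift(s, by_credit = TRUE)
    if (!is.null(by_cr$by_credit)) {
      expect_equal(sum(by_cr$by_credit$n), by_cr$n_win)
      expect_equal(sum(by_cr$by_credit$win_stay * by_cr$by_credit$n),
                   by_cr$win_stay * by_cr$n_win)
    }
  }
})

test_that("devaluation metrics compute rates and bias", {
  blocks <- data.frame(block = 1:10, valued_responses = rep(3, 10),
                       devalued_responses = rep(1, 10))
  m <- devaluation_metrics(deval_session(blocks))
  expect_equal(m$bias, 0.75)
  expect_equal(m$valued_rate, 30 / 120)

  blocks$devalued_responses <- rep(3, 10)
  expect_equal(devaluation_metrics(deval_session(blocks))$bias, 0.5)

  blocks$valued_responses <- rep(12, 10)
  expect_equal(devaluation_metrics(deval_session(blocks))$valued_rate, 1.0)

  zero <- data.frame(block = 1:10, valued_responses = 0,
                     devalued_responses = 0)
  expect_true(is.na(devaluation_metrics(deval_session(zero))$bias))

  d <- deval_session(blocks, rating_pre = c(valued = 5, devalued = 5),
                     rating_post = c(valued = 5, devalued = 2))
  expect_equal(devaluation_metrics(d)$rating_change,
               c(valued = 0, devalued = -3))
  expect_error(deval_session(blocks, rating_pre = c(valued = 9)), "1..7")
})

test_that("behavior_summary aggregates phases and flags incompleteness", {
  task <- prl_task()
  s <- run_session(task, perfect_policy(task), subject_id = "perfect",
                   seed = 41)
  b <- behavior_summary(s)
  expect_equal(b$ttc_discrimination, 6)
  expect_equal(b$ttc_first_reversal, 6)
  expect_equal(b$ttc_srl1_mean, 6)
  expect_equal(b$ttc_srl2_mean, 6)
  expect_equal(b$n_srl1_incomplete, 0L)
  # an omniscient switcher breaks win-stay only at stage boundaries,
  # which count as applicable pairs by design
  expect_equal(win_stay_lose_shift(s, within_stage = TRUE)$win_stay, 1)
  expect_lt(b$win_stay, 1)

  # greedy exploiting agent: SRL1 win-stay at the exploitation limit
  g <- simulate_agent(ewa_params(0.5, 0.5, 100), seed = 42)
  bg <- behavior_summary(g)
  expect_gt(bg$win_stay_srl1, 0.95)

  # an always-wrong session is incomplete from stage 1
  s0 <- run_session(prl_task(max_trials = 30L), function(h) 1L, seed = 43)
  b0 <- behavior_summary(s0)
  expect_identical(b0$incomplete_from, 1L)
  expect_true(is.na(b0$ttc_discrimination))
})
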