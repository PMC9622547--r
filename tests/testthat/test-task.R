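test_that("default task has the 11-stage structure with alternating targets", {
  task <- prl_task()
  expect_length(task$stages, 11L)
  labels <- vapply(task$stages, `[[`, "", "stage_label")
  expect_identical(labels, c("discrimination", "first_reversal",
                             paste0("SRL1_", 1:5), paste0("SRL2_", 1:4)))
  targets <- vapply(task$stages, `[[`, 0L, "target_option")
  expect_true(all(diff(targets) != 0))  # every boundary is a reversal
  expect_identical(targets[1L], 0L)
  for (k in 1:7) {
    st <- task$stages[[k]]
    expect_equal(st$p_reward_target, 0.80)
    expect_equal(st$p_reward_nontarget, 0.20)
    expect_equal(st$win_credits, 1)
  }
  for (k in 8:11) {
    st <- task$stages[[k]]
    expect_equal(st$p_reward_nontarget, 0.40)
    expect_equal(sort(st$win_credits), c(2, 6))
    expect_equal(st$win_probs, c(0.5, 0.5))
  }
  expect_true(all(vapply(task$stages, `[[`, 0L, "criterion_consecutive") == 6L))
  task1 <- prl_task(initial_target = 1L)
  expect_identical(task1$stages[[1L]]$target_option, 1L)
})

test_that("stage specs reject inconsistent contingencies", {
  expect_error(stage_spec("s", 0, 0.4, 0.8), "strictly below")
  expect_error(stage_spec("s", 2, 0.8, 0.2), "option index")
  expect_error(stage_spec("s", 0, 0.8, 0.2, win_credits = c(2, 6),
                          win_probs = c(0.7, 0.7)), "sum to 1")
  expect_error(stage_spec("s", 0, 0.8, 0.2, criterion_consecutive = 10,
                          max_trials = 5), "at least")
})

test_that("draw_outcome follows the stage contingencies", {
  st <- stage_spec("s", 0L, 1.0, 0.2, win_credits = c(2, 6))
  expect_true(all(draw_outcome(st, 0L, n = 50, seed = 1) > 0))
  expect_true(all(draw_outcome(st, 0L, n = 50, seed = 1) %in% c(2, 6)))
  expect_error(draw_outcome(st, 2L), "option index")

  # empirical rates converge to nominal probabilities (3-sigma band)
  task <- prl_task()
  n <- 20000
  tol <- 3 * sqrt(0.8 * 0.2 / n)
  r1 <- mean(draw_outcome(task$stages[[3]], 0L, n = n, seed = 11) > 0)
  expect_lt(abs(r1 - 0.80), tol)
  st9 <- task$stages[[9]]
  r2 <- mean(draw_outcome(st9, 1L - st9$target_option, n = n, seed = 12) > 0)
  expect_lt(abs(r2 - 0.40), 3 * sqrt(0.4 * 0.6 / n))
})

test_that("a perfect agent completes every stage in exactly the criterion run", {
  task <- prl_task()
  s <- run_session(task, perfect_policy(task), seed = 3)
  expect_equal(nrow(s), 11 * 6)
  expect_true(all(attr(s, "stage_completion")))
  expect_true(all(s$correct))
  expect_true(is.na(attr(s, "incomplete_from")))
  expect_equal(as.integer(table(s$stage_index)), rep(6L, 11))
})

test_that("criterion-unreachable policies truncate and stop the session", {
  task <- prl_task(max_trials = 50L)
  nontarget <- function(h) 1L  # stage 1 target is 0
  s <- run_session(task, nontarget, seed = 4)
  expect_equal(nrow(s), 50L)
  expect_false(attr(s, "stage_completion")[1L])
  expect_identical(attr(s, "incomplete_from"), 1L)
  expect_false(2L %in% s$stage_index)  # no truncation-advance by default

  alternating <- local({
    k <- 0L
    function(h) { k <<- k + 1L; k %% 2L }
  })
  s2 <- run_session(prl_task(max_trials = 40L), alternating, seed = 5)
  expect_false(attr(s2, "stage_completion")[1L])
  expect_equal(nrow(s2), 40L)
})

test_that("sessions replay bit-identically under the same seed", {
  pol <- function(h) sample(0:1, 1L)
  a <- run_session(prl_task(), pol, seed = 99)
  b <- run_session(prl_task(), pol, seed = 99)
  expect_identical(a, b)
  expect_error(run_session(prl_task(), function(h) stop("boom")),
               "stage 1 trial 1")
})

test_that("instrumental training ends on the question streak", {
  tr <- run_instrumental_training(1.0, seed = 6)
  expect_true(tr$complete)
  expect_equal(tr$n_questions, 6L)
  expect_true(all(tr$responses_per_token >= 5 & tr$responses_per_token <= 10))

  cfg <- deval_config(max_training_questions = 30L)
  tr0 <- run_instrumental_training(0.0, cfg, seed = 7)
  expect_false(tr0$complete)
  expect_equal(tr0$n_questions, 30L)
})

test_that("choice test counts follow the block structure and rates", {
  d <- run_choice_test(2.0, 0.5, seed = 8)
  expect_s3_class(d, "deval_session")
  expect_equal(nrow(d$blocks), 10L)

  d0 <- run_choice_test(0, 0, seed = 9)
  expect_true(all(d0$blocks$valued_responses == 0))
  expect_true(all(d0$blocks$devalued_responses == 0))
  expect_error(run_choice_test(-1, 0), "valued_rate")

  # Poisson means: rate x 12 s per block
  sims <- with(list(), {
    set.seed(10)
    replicate(300, {
      d <- run_choice_test(2.0, 0.5)
      c(mean(d$blocks$valued_responses), mean(d$blocks$devalued_responses))
    })
  })
  expect_lt(abs(mean(sims[1, ]) - 24), 0.5)
  expect_lt(abs(mean(sims[2, ]) - 6), 0.3)
})
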