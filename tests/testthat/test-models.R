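test_that("EWA update follows the experience-weighted recursion", {
  # first update reduces to the payoff regardless of phi, rho
  st <- ewa_update(model_state(), 0L, 1, ewa_params(0.3, 0.8, 1))
  expect_equal(st$values, c(1, 0))
  expect_equal(st$weights, c(1, 0))

  # phi = rho = 1 tracks the running mean
  p11 <- ewa_params(1, 1, 1)
  st <- ewa_update(model_state(), 0L, 1, p11)
  st <- ewa_update(st, 0L, -1, p11)
  expect_equal(st$values[1], 0)
  expect_equal(st$weights[1], 2)

  # hand-worked step: phi = rho = 0.5, prior A0 = 1, n0 = 1, payoff -1
  st <- list(values = c(1, 0), weights = c(1, 0))
  st <- ewa_update(st, 0L, -1, ewa_params(0.5, 0.5, 1))
  expect_equal(st$weights[1], 1.5)
  expect_equal(st$values[1], (0.5 * 1 * 1 - 1) / 1.5)  # = -1/3
  expect_equal(st$values[2], 0)  # unchosen untouched

  # memoryless limit: phi = rho = 0 makes A_c the latest payoff
  p00 <- ewa_params(0, 0, 1)
  st <- ewa_update(model_state(), 1L, 5, p00)
  st <- ewa_update(st, 1L, -2, p00)
  expect_equal(st$values[2], -2)
})

test_that("RP update applies valence-specific and fictive learning", {
  p <- rp_params(0.3, 0.2, 1)
  st <- rp_update(model_state(), 0L, 1, p)
  expect_equal(st$values, c(0.3, -0.2))

  st <- rp_update(model_state(), 0L, -1, rp_params(0.3, 0.5, 1))
  expect_equal(st$values[1], -0.5)

  # zero learning rates freeze the state
  st <- rp_update(list(values = c(0.4, -0.1), weights = c(0, 0)), 0L, 1,
                  rp_params(0, 0, 1))
  expect_equal(st$values, c(0.4, -0.1))

  # chosen-only switch leaves the unchosen value alone
  st <- rp_update(model_state(), 0L, 1, p, fictive = FALSE)
  expect_equal(st$values, c(0.3, 0))
})

test_that("softmax probabilities are exact, stable and shift-invariant", {
  expect_equal(choice_probabilities(c(0, 0), 5), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(3, -2), 0), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(1, -1), 1)[1], 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # no overflow at extreme products
  expect_equal(choice_probabilities(c(500, -500), 10), c(1, 0))

  set.seed(1)
  for (i in 1:50) {
    v <- rnorm(2, 0, 3); b <- runif(1, 0, 10); c0 <- rnorm(1, 0, 100)
    p <- choice_probabilities(v, b)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, choice_probabilities(v + c0, b), tolerance = 1e-9)
  }

  # increasing beta weakly favors the higher-valued option
  v <- c(0.8, 0.2)
  p_first <- vapply(c(0, 0.5, 1, 2, 5, 20), function(b)
    choice_probabilities(v, b)[1], 0)
  expect_true(all(diff(p_first) >= 0))
})

test_that("log-likelihood matches hand-worked and stepping computations", {
  one <- make_session(choice = 1L, win = TRUE)
  expect_equal(log_likelihood(ewa_params(0.5, 0.5, 2), one), log(0.5),
               tolerance = 1e-12)
  expect_equal(log_likelihood(rp_params(0.5, 0.5, 2), one), log(0.5),
               tolerance = 1e-12)

  # 3-trial hand-worked EWA sequence, phi = rho = 0.5, beta = 1:
  # choices 0,1,0 with payoffs +1,-1,+1; closed form worked by hand
  s3 <- make_session(choice = c(0L, 1L, 0L), win = c(TRUE, FALSE, TRUE))
  expected <- log(0.5) + log(1 / (1 + exp(1))) + log(1 / (1 + exp(-2)))
  expect_equal(log_likelihood(ewa_params(0.5, 0.5, 1), s3), expected,
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    s <- random_session(n = 40)
    pe <- ewa_params(runif(1), runif(1), runif(1, 0, 8))
    pr <- rp_params(runif(1), runif(1), runif(1, 0, 8))
    for (coding in c("sign", "magnitude")) {
      expect_equal(log_likelihood(pe, s, coding = coding, config = prl_task()),
                   ll_stepping_oracle(pe, s, coding = coding),
                   tolerance = 1e-10)
      expect_equal(log_likelihood(pr, s, coding = coding, config = prl_task()),
                   ll_stepping_oracle(pr, s, coding = coding),
                   tolerance = 1e-10)
    }
  }
  expect_error(log_likelihood(pe, make_session(integer(0), logical(0))),
               "at least one trial")
})

test_that("magnitude coding scales wins by the stage's expected credit", {
  s <- make_session(choice = c(0L, 0L, 0L), win = c(TRUE, TRUE, FALSE),
                    credits = c(2, 6, 0), stage_index = c(9L, 9L, 9L))
  expect_equal(code_payoffs(s, "sign"), c(1, 1, -1))
  expect_equal(code_payoffs(s, "magnitude", prl_task()), c(0.5, 1.5, -1))
})

test_that("simulated agents are deterministic and match the reference path", {
  p <- ewa_params(0.6, 0.3, 3)
  a <- simulate_agent(p, seed = 21)
  expect_identical(a, simulate_agent(p, seed = 21))

  # compiled fast path == R policy path, bit for bit
  b <- run_session(prl_task(), make_agent_policy(p), subject_id = "agent",
                   seed = 21)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "stage_completion"), attr(b, "stage_completion"))

  pr <- rp_params(0.4, 0.25, 2.5)
  a2 <- simulate_agent(pr, seed = 22, coding = "magnitude")
  b2 <- run_session(prl_task(), make_agent_policy(pr, coding = "magnitude"),
                    subject_id = "agent", seed = 22)
  expect_identical(as.data.frame(a2), as.data.frame(b2))
})

test_that("beta limits produce random and greedy choice behaviour", {
  # beta = 0: fair coin flips regardless of payoffs
  s <- simulate_agent(ewa_params(0.5, 0.5, 0), prl_task(max_trials = 200L),
                      seed = 23)
  frac1 <- mean(s$choice)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / nrow(s)))
  expect_lt(abs(mean(s$correct) - 0.5), 3 * sqrt(0.25 / nrow(s)))

  # near-greedy limit: huge beta exploits the learned values
  g <- simulate_agent(ewa_params(0.5, 0.5, 100), seed = 24)
  expect_true(attr(g, "stage_completion")[1L])
  expect_lte(min(which(cumsum(g$correct[g$stage_index == 1L]) >= 6)), 15L)
  expect_gt(win_stay_lose_shift(g, stages = 3:7)$win_stay, 0.95)
})
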