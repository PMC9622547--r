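#' Specify one stage of the serial-reversal task
#'
#' A stage presents the same stimulus pair on every trial; one option
#' (the target) carries the higher reward probability. A rewarded trial
#' pays a credit amount drawn from `win_credits`; an unrewarded trial
#' pays 0. The stage ends when `criterion_consecutive` correct (target)
#' choices are made in a row, or after `max_trials` trials.
#'
#' @param stage_label Character label (e.g. `"SRL1_2"`).
#' @param target_option Option index of the target stimulus (0 or 1).
#' @param p_reward_target,p_reward_nontarget Reward probabilities; must
#'   satisfy `0 <= p_reward_nontarget < p_reward_target <= 1`.
#' @param win_credits Positive integer credit values paid on a win.
#' @param win_probs Selection probabilities for `win_credits` (must sum
#'   to 1); equal by default.
#' @param criterion_consecutive Consecutive correct choices required to
#'   complete the stage.
#' @param max_trials Trial cap for the stage.
#' @return An object of class `"stage_spec"`.
#' @seealso [prl_task()], [draw_outcome()]
#' @export
stage_spec <- function(stage_label, target_option,
                       p_reward_target, p_reward_nontarget,
                       win_credits = 1L, win_probs = NULL,
                       criterion_consecutive = 6L, max_trials = 80L) {
  target_option <- assert_choice_index(target_option)
  p_reward_target <- assert_number(p_reward_target, "p_reward_target", 0, 1)
  p_reward_nontarget <- assert_number(p_reward_nontarget, "p_reward_nontarget", 0, 1)
  if (p_reward_nontarget >= p_reward_target)
    stopf("p_reward_nontarget must be strictly below p_reward_target")
  if (!is.numeric(win_credits) || length(win_credits) < 1L || any(win_credits <= 0))
    stopf("`win_credits` must be positive credit values")
  if (is.null(win_probs)) win_probs <- rep(1 / length(win_credits), length(win_credits))
  if (length(win_probs) != length(win_credits) ||
      abs(sum(win_probs) - 1) > 1e-8 || any(win_probs < 0))
    stopf("`win_probs` must be non-negative and sum to 1")
  criterion_consecutive <- assert_count(criterion_consecutive, "criterion_consecutive")
  max_trials <- assert_count(max_trials, "max_trials")
  if (max_trials < criterion_consecutive)
    stopf("`max_trials` must be at least `criterion_consecutive`")
  structure(list(
    stage_label = as.character(stage_label),
    target_option = target_option,
    p_reward_target = p_reward_target,
    p_reward_nontarget = p_reward_nontarget,
    win_credits = as.numeric(win_credits),
    win_probs = as.numeric(win_probs),
    loss_credits = 0L,
    criterion_consecutive = criterion_consecutive,
    max_trials = max_trials
  ), class = "stage_spec")
}

# Expected credit value of a win for a stage (used by magnitude payoff coding).
stage_mean_win_credit <- function(stage) {
  sum(stage$win_credits * stage$win_probs)
}

#' Build the default 11-stage serial-reversal task
#'
#' The default task comprises an initial discrimination, a first
#' reversal, five SRL1 stages and four SRL2 stages, with the target
#' option reversing at every stage boundary. Stages 1-7 use 80/20
#' reward contingencies and pay 1 credit per win; the SRL2 stages
#' (8-11) use 80/40 contingencies and pay 2 or 6 credits with equal
#' probability. Every stage requires 6 consecutive correct choices.
#'
#' @param initial_target Target option for stage 1 (0 or 1).
#' @param criterion Consecutive-correct criterion applied to all stages.
#' @param max_trials Per-stage trial cap. The cap is a simulation bound
#'   (no cap is imposed on human participants); sessions that hit it are
#'   flagged incomplete.
#' @param advance_on_truncation If `FALSE` (default) a session stops at
#'   the first truncated stage ("incomplete from stage k"); if `TRUE`
#'   the session advances through all stages regardless, which the
#'   simulation-study and fixed-length designs rely on.
#' @return An object of class `"prl_task"`: a list with `stages` (list
#'   of [stage_spec()]) and `advance_on_truncation`.
#' @examples
#' task <- prl_task()
#' length(task$stages)
#' @export
prl_task <- function(initial_target = 0L, criterion = 6L, max_trials = 80L,
                     advance_on_truncation = FALSE) {
  initial_target <- assert_choice_index(initial_target)
  labels <- c("discrimination", "first_reversal", paste0("SRL1_", 1:5),
              paste0("SRL2_", 1:4))
  stages <- vector("list", 11L)
  for (k in 1:11) {
    target <- if (k %% 2 == 1) initial_target else 1L - initial_target
    if (k <= 7) {
      stages[[k]] <- stage_spec(labels[k], target, 0.80, 0.20,
                                win_credits = 1L,
                                criterion_consecutive = criterion,
                                max_trials = max_trials)
    } else {
      stages[[k]] <- stage_spec(labels[k], target, 0.80, 0.40,
                                win_credits = c(2L, 6L),
                                criterion_consecutive = criterion,
                                max_trials = max_trials)
    }
  }
  new_prl_task(stages, advance_on_truncation)
}

new_prl_task <- function(stages, advance_on_truncation = FALSE) {
  structure(list(stages = stages,
                 advance_on_truncation = isTRUE(advance_on_truncation)),
            class = "prl_task")
}

#' Build a fixed-length reversal schedule for parameter recovery
#'
#' Long sessions sharpen likelihoods and are the standard design for
#' certifying a fitting routine. Each stage runs for exactly
#' `trials_per_stage` trials (the completion criterion equals the cap,
#' so stages essentially always truncate) and the target reverses at
#' each boundary, giving sessions of `n_stages * trials_per_stage`
#' trials.
#'
#' @param n_stages Number of reversal blocks.
#' @param trials_per_stage Trials per block.
#' @param p_target,p_nontarget Reward contingencies.
#' @param initial_target Target option for the first block.
#' @return A `"prl_task"` with `advance_on_truncation = TRUE`.
#' @export
recovery_task <- function(n_stages = 20L, trials_per_stage = 25L,
                          p_target = 0.8, p_nontarget = 0.2,
                          initial_target = 0L) {
  n_stages <- assert_count(n_stages, "n_stages")
  trials_per_stage <- assert_count(trials_per_stage, "trials_per_stage")
  stages <- lapply(seq_len(n_stages), function(k) {
    target <- if (k %% 2 == 1) initial_target else 1L - initial_target
    stage_spec(paste0("rev_", k), target, p_target, p_nontarget,
               win_credits = 1L,
               criterion_consecutive = trials_per_stage,
               max_trials = trials_per_stage)
  })
  new_prl_task(stages, advance_on_truncation = TRUE)
}

#' @export
print.prl_task <- function(x, ...) {
  s <- x$stages
  cat(sprintf("Serial-reversal task: %d stages%s\n", length(s),
              if (x$advance_on_truncation) " (advance on truncation)" else ""))
  df <- data.frame(
    stage = seq_along(s),
    label = vapply(s, `[[`, "", "stage_label"),
    target = vapply(s, `[[`, 0L, "target_option"),
    p_target = vapply(s, `[[`, 0, "p_reward_target"),
    p_nontarget = vapply(s, `[[`, 0, "p_reward_nontarget"),
    win_credits = vapply(s, function(z) paste(z$win_credits, collapse = "/"), ""),
    criterion = vapply(s, `[[`, 0L, "criterion_consecutive"),
    max_trials = vapply(s, `[[`, 0L, "max_trials"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Draw trial outcomes for a choice in a stage
#'
#' With the chosen option's reward probability, a win pays a credit
#' value drawn from the stage's `win_credits`; otherwise the trial pays
#' 0 credits.
#'
#' @param stage A [stage_spec()].
#' @param choice Option index chosen (0 or 1).
#' @param n Number of independent draws.
#' @param seed Optional seed.
#' @return Integer-valued numeric vector of credits (0 = loss).
#' @examples
#' st <- prl_task()$stages[[3]]
#' mean(draw_outcome(st, choice = st$target_option, n = 1000, seed = 1) > 0)
#' @export
draw_outcome <- function(stage, choice, n = 1L, seed = NULL) {
  stopifnot(inherits(stage, "stage_spec"))
  choice <- assert_choice_index(choice)
  if (length(choice) != 1L) stopf("`choice` must be a single option index")
  n <- assert_count(n, "n")
  p <- if (choice == stage$target_option) stage$p_reward_target else stage$p_reward_nontarget
  with_seed(seed, {
    win <- runif(n) < p
    credits <- numeric(n)
    nw <- sum(win)
    if (nw > 0) {
      # inverse-CDF draw over the win-credit distribution (one uniform
      # per win, consumed whether or not the distribution is degenerate)
      cum <- cumsum(stage$win_probs)
      idx <- findInterval(runif(nw), cum[-length(cum)]) + 1L
      credits[win] <- stage$win_credits[idx]
    }
    credits
  })
}

#' Run one subject through a reversal-learning session
#'
#' The policy is consulted before each trial and receives the session
#' history so far as a list with elements `n` (trials so far) and
#' vectors `choice`, `correct`, `credits`, `win`, `stage_index` of
#' length `n`; it must return an option index (0 or 1). Stateful agents
#' (closures) may ignore the history. Within a stage, trials accrue
#' until the last `criterion_consecutive` choices were all correct or
#' `max_trials` is reached; the target reverses at each completed stage
#' boundary.
#'
#' @param config A [prl_task()].
#' @param policy A function `history -> choice`.
#' @param subject_id,group Identifiers stored in the trial records.
#' @param seed Optional seed making the session reproducible.
#' @return A data frame of class `"prl_session"` with one row per trial
#'   (columns `subject_id`, `group`, `stage_index`, `stage_label`,
#'   `trial_in_stage`, `choice`, `correct`, `credits`, `win`) and
#'   attributes `stage_completion` (logical per run stage),
#'   `incomplete_from` (first truncated stage, or `NA`) and `config`.
#' @examples
#' s <- run_session(prl_task(), function(h) 0L, seed = 1)
#' head(s)
#' @export
run_session <- function(config, policy, subject_id = "s1", group = NA_character_,
                        seed = NULL) {
  stopifnot(inherits(config, "prl_task"), is.function(policy))
  with_seed(seed, run_session_(config, policy, subject_id, group))
}

run_session_ <- function(config, policy, subject_id, group) {
  stages <- config$stages
  cap <- sum(vapply(stages, `[[`, 0L, "max_trials"))
  choice <- integer(cap); correct <- logical(cap); credits <- numeric(cap)
  win <- logical(cap); stage_index <- integer(cap); trial_in_stage <- integer(cap)
  n <- 0L
  completion <- logical(0)
  incomplete_from <- NA_integer_
  history <- function() list(n = n, choice = choice[seq_len(n)],
                             correct = correct[seq_len(n)],
                             credits = credits[seq_len(n)],
                             win = win[seq_len(n)],
                             stage_index = stage_index[seq_len(n)])
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    run <- 0L; t_in <- 0L; done <- FALSE
    while (t_in < st$max_trials) {
      ch <- tryCatch(policy(history()), error = function(e)
        stopf("policy failed at stage %d trial %d: %s", k, t_in + 1L,
              conditionMessage(e)))
      ch <- assert_choice_index(ch)
      if (length(ch) != 1L) stopf("policy must return a single option index")
      cr <- draw_outcome(st, ch, n = 1L)
      ok <- ch == st$target_option
      run <- if (ok) run + 1L else 0L
      n <- n + 1L; t_in <- t_in + 1L
      choice[n] <- ch; correct[n] <- ok; credits[n] <- cr; win[n] <- cr > 0
      stage_index[n] <- k; trial_in_stage[n] <- t_in
      if (run >= st$criterion_consecutive) { done <- TRUE; break }
    }
    completion <- c(completion, done)
    if (!done && !config$advance_on_truncation) break
  }
  # first truncated stage, if any
  incomplete_from <- if (any(!completion)) which(!completion)[1L] else NA_integer_
  idx <- seq_len(n)
  out <- data.frame(
    subject_id = subject_id,
    group = group,
    stage_index = stage_index[idx],
    stage_label = vapply(stages, `[[`, "", "stage_label")[stage_index[idx]],
    trial_in_stage = trial_in_stage[idx],
    choice = choice[idx],
    correct = correct[idx],
    credits = credits[idx],
    win = win[idx],
    stringsAsFactors = FALSE)
  structure(out, stage_completion = completion,
            incomplete_from = incomplete_from, config = config,
            class = c("prl_session", "data.frame"))
}

#' Configure the outcome-devaluation procedure
#'
#' Instrumental training earns tokens by repeated directional responses
#' (a uniformly drawn 5-10 consecutive responses per token by default),
#' with a comprehension question after every three rounds; training ends
#' at six consecutive correct questions. The choice test presents the
#' response device for `n_blocks` blocks of `block_duration_s` seconds
#' with no feedback.
#'
#' @param n_blocks Number of choice-test blocks.
#' @param block_duration_s Block duration in seconds.
#' @param fr_min,fr_max Range of consecutive responses required per token.
#' @param training_criterion_questions Consecutive correct questions
#'   ending training.
#' @param max_training_questions Question cap for non-learners.
#' @return An object of class `"deval_config"`.
#' @export
deval_config <- function(n_blocks = 10L, block_duration_s = 12,
                         fr_min = 5L, fr_max = 10L,
                         training_criterion_questions = 6L,
                         max_training_questions = 40L) {
  n_blocks <- assert_count(n_blocks, "n_blocks")
  block_duration_s <- assert_number(block_duration_s, "block_duration_s", 0)
  fr_min <- assert_count(fr_min, "fr_min")
  fr_max <- assert_count(fr_max, "fr_max", lower = fr_min)
  structure(list(n_blocks = n_blocks, block_duration_s = block_duration_s,
                 fr_min = fr_min, fr_max = fr_max,
                 training_criterion_questions =
                   assert_count(training_criterion_questions,
                                "training_criterion_questions"),
                 max_training_questions =
                   assert_count(max_training_questions,
                                "max_training_questions")),
            class = "deval_config")
}

#' Simulate instrumental training of the devaluation task
#'
#' Rounds of token earning (each requiring a uniform draw of
#' `fr_min:fr_max` consecutive responses) are interleaved with
#' comprehension questions after every third round, answered correctly
#' with probability `accuracy`. Training completes at the configured run
#' of consecutive correct questions.
#'
#' @param accuracy Probability a comprehension question is answered
#'   correctly, in \[0, 1\].
#' @param config A [deval_config()].
#' @param seed Optional seed.
#' @return A list of class `"deval_training"`: `responses_per_token`
#'   (draws for each earning round), `questions` (logical outcomes),
#'   `n_questions`, `complete`.
#' @export
run_instrumental_training <- function(accuracy, config = deval_config(),
                                      seed = NULL) {
  accuracy <- assert_number(accuracy, "accuracy", 0, 1)
  stopifnot(inherits(config, "deval_config"))
  with_seed(seed, {
    responses <- integer(0)
    questions <- logical(0)
    streak <- 0L
    complete <- FALSE
    while (length(questions) < config$max_training_questions) {
      # three earning rounds, then one question
      responses <- c(responses,
                     sample(config$fr_min:config$fr_max, 3L, replace = TRUE))
      q <- runif(1) < accuracy
      questions <- c(questions, q)
      streak <- if (q) streak + 1L else 0L
      if (streak >= config$training_criterion_questions) {
        complete <- TRUE
        break
      }
    }
    structure(list(responses_per_token = responses, questions = questions,
                   n_questions = length(questions), complete = complete),
              class = "deval_training")
  })
}

#' Construct a devaluation choice-test record
#'
#' @param blocks Data frame with columns `block`, `valued_responses`,
#'   `devalued_responses`.
#' @param rating_pre,rating_post Named numeric Likert ratings (1-7) per
#'   token, e.g. `c(valued = 6, devalued = 6)`.
#' @param probe_correct Count of correct post-test probe answers.
#' @param devalued_token Identifier of the devalued token.
#' @return An object of class `"deval_session"`.
#' @export
deval_session <- function(blocks, rating_pre = NULL, rating_post = NULL,
                          probe_correct = NA_integer_,
                          devalued_token = NA_character_) {
  stopifnot(is.data.frame(blocks),
            all(c("block", "valued_responses", "devalued_responses") %in%
                  names(blocks)))
  if (any(blocks$valued_responses < 0) || any(blocks$devalued_responses < 0))
    stopf("response counts must be non-negative")
  for (r in list(rating_pre, rating_post))
    if (!is.null(r) && any(!is.na(r) & (r < 1 | r > 7)))
      stopf("ratings must lie in 1..7")
  structure(list(blocks = blocks, rating_pre = rating_pre,
                 rating_post = rating_post, probe_correct = probe_correct,
                 devalued_token = devalued_token),
            class = "deval_session")
}

#' Simulate the devaluation choice test
#'
#' Responses toward the valued and devalued actions are modelled as
#' independent Poisson counting processes with the given rates over each
#' block; the test presents no feedback, so the rates are constant
#' across blocks.
#'
#' @param valued_rate,devalued_rate Response rates (responses per
#'   second), non-negative.
#' @param config A [deval_config()].
#' @param seed Optional seed.
#' @return A [deval_session()] with `config$n_blocks` blocks.
#' @export
run_choice_test <- function(valued_rate, devalued_rate,
                            config = deval_config(), seed = NULL) {
  valued_rate <- assert_number(valued_rate, "valued_rate", 0)
  devalued_rate <- assert_number(devalued_rate, "devalued_rate", 0)
  stopifnot(inherits(config, "deval_config"))
  with_seed(seed, {
    mu_v <- valued_rate * config$block_duration_s
    mu_d <- devalued_rate * config$block_duration_s
    blocks <- data.frame(
      block = seq_len(config$n_blocks),
      valued_responses = rpois(config$n_blocks, mu_v),
      devalued_responses = rpois(config$n_blocks, mu_d))
    deval_session(blocks)
  })
}
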