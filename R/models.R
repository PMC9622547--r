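#' Experience-weighted attraction (EWA) model parameters
#'
#' The EWA model tracks, for each option, an attraction \eqn{A_j} and an
#' experience weight \eqn{n_j}. After choosing option c and receiving
#' payoff r:
#' \deqn{n_c \leftarrow \rho n_c + 1, \quad
#'       A_c \leftarrow (\phi\, n_c^{old} A_c + r) / n_c^{new}.}
#' `phi` is the decay of prior attraction (figures in the literature
#' often report the complementary `1 - phi` as a learning rate); `rho`
#' is the experience decay governing how quickly accumulated experience
#' is displaced by new outcomes (higher `rho` = more inertia); `beta`
#' is the softmax inverse temperature.
#'
#' @param phi Attraction decay, in \[0, 1\].
#' @param rho Experience decay, in \[0, 1\].
#' @param beta Inverse temperature, non-negative.
#' @return An object of class `"ewa_params"`.
#' @examples
#' ewa_params(phi = 0.6, rho = 0.3, beta = 6)
#' @export
ewa_params <- function(phi, rho, beta) {
  structure(list(phi = assert_number(phi, "phi", 0, 1),
                 rho = assert_number(rho, "rho", 0, 1),
                 beta = assert_number(beta, "beta", 0)),
            class = c("ewa_params", "prl_params"))
}

#' Reward/punishment (RP) model parameters
#'
#' A Rescorla-Wagner learner with separate learning rates for positive
#' and negative prediction errors. By default the unchosen option is
#' updated fictively toward the negated payoff with the
#' opposite-valence rate (the standard dual-update convention for
#' two-option reversal tasks).
#'
#' @param a_rew Reward learning rate, in \[0, 1\].
#' @param a_pun Punishment learning rate, in \[0, 1\].
#' @param beta Inverse temperature, non-negative.
#' @return An object of class `"rp_params"`.
#' @export
rp_params <- function(a_rew, a_pun, beta) {
  structure(list(a_rew = assert_number(a_rew, "a_rew", 0, 1),
                 a_pun = assert_number(a_pun, "a_pun", 0, 1),
                 beta = assert_number(beta, "beta", 0)),
            class = c("rp_params", "prl_params"))
}

#' @export
print.prl_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  print(unlist(x))
  invisible(x)
}

model_name <- function(params) {
  if (inherits(params, "ewa_params")) "ewa"
  else if (inherits(params, "rp_params")) "rp"
  else stopf("`params` must be ewa_params or rp_params")
}

#' Initial model state
#'
#' Both models start from zero values; the EWA experience weights also
#' start at zero, so the first update of an option reduces to
#' \eqn{A_c = r} regardless of `phi` and `rho`.
#'
#' @return A list with `values` (2 numbers) and `weights` (2 numbers,
#'   used by EWA only).
#' @export
model_state <- function() {
  list(values = c(0, 0), weights = c(0, 0))
}

#' One EWA update step
#'
#' Applies the experience-weighted attraction recursion to the chosen
#' option; the unchosen option is untouched.
#'
#' @param state A [model_state()].
#' @param choice Chosen option index (0 or 1).
#' @param payoff Signed payoff for the trial.
#' @param params An [ewa_params()].
#' @return The updated state.
#' @examples
#' st <- ewa_update(model_state(), choice = 0, payoff = 1,
#'                  params = ewa_params(0.5, 0.5, 1))
#' st$values  # first update reduces to the payoff
#' @export
ewa_update <- function(state, choice, payoff, params) {
  stopifnot(inherits(params, "ewa_params"))
  choice <- assert_choice_index(choice)
  i <- choice + 1L
  n_old <- state$weights[i]
  n_new <- params$rho * n_old + 1
  state$values[i] <- (params$phi * n_old * state$values[i] + payoff) / n_new
  state$weights[i] <- n_new
  state
}

#' One reward/punishment update step
#'
#' The chosen option moves toward the payoff with the reward rate
#' (payoff >= 0) or the punishment rate (payoff < 0). With
#' `fictive = TRUE` the unchosen option moves toward the negated payoff
#' with the opposite-valence rate.
#'
#' @inheritParams ewa_update
#' @param params An [rp_params()].
#' @param fictive Update the unchosen option fictively? Default `TRUE`.
#' @return The updated state (`weights` unused).
#' @export
rp_update <- function(state, choice, payoff, params, fictive = TRUE) {
  stopifnot(inherits(params, "rp_params"))
  choice <- assert_choice_index(choice)
  c_i <- choice + 1L
  u_i <- 2L - choice
  if (payoff >= 0) {
    state$values[c_i] <- state$values[c_i] +
      params$a_rew * (payoff - state$values[c_i])
    if (fictive)
      state$values[u_i] <- state$values[u_i] +
        params$a_pun * (-payoff - state$values[u_i])
  } else {
    state$values[c_i] <- state$values[c_i] +
      params$a_pun * (payoff - state$values[c_i])
    if (fictive)
      state$values[u_i] <- state$values[u_i] +
        params$a_rew * (-payoff - state$values[u_i])
  }
  state
}

#' Softmax choice probabilities
#'
#' \deqn{P(j) = \exp(\beta v_j) / \sum_k \exp(\beta v_k)}
#' computed via the log-sum-exp trick, so large `beta * values` do not
#' overflow.
#'
#' @param values Per-option values (length 2 or more).
#' @param beta Inverse temperature, non-negative.
#' @return Probability vector summing to 1.
#' @examples
#' choice_probabilities(c(1, -1), beta = 1)
#' @export
choice_probabilities <- function(values, beta) {
  beta <- assert_number(beta, "beta", 0)
  x <- beta * values
  e <- exp(x - max(x))
  e / sum(e)
}

#' Code observed credits as model payoffs
#'
#' The default `"sign"` coding maps wins to +1 and losses to -1
#' regardless of credit magnitude (the convention of the reversal
#' learning model family these models come from). The `"magnitude"`
#' coding, for sensitivity analyses, scales each win by its credits
#' relative to the stage's expected win credit (so 2 and 6 credits in an
#' SRL2 stage become 0.5 and 1.5); losses stay -1.
#'
#' @param session A `"prl_session"` data frame (or any data frame with
#'   `win`, `credits`, `stage_index` columns).
#' @param coding `"sign"` or `"magnitude"`.
#' @param config Task config supplying stage win-credit distributions;
#'   defaults to the session's `config` attribute, falling back to
#'   [prl_task()]. Only used by `"magnitude"`.
#' @return Numeric payoff vector, one per trial.
#' @export
code_payoffs <- function(session, coding = c("sign", "magnitude"),
                         config = NULL) {
  coding <- match.arg(coding)
  if (coding == "sign") return(ifelse(session$win, 1, -1))
  if (is.null(config)) config <- attr(session, "config")
  if (is.null(config)) config <- prl_task()
  mean_credit <- vapply(config$stages, stage_mean_win_credit, 0)
  ifelse(session$win, session$credits / mean_credit[session$stage_index], -1)
}

#' Session log-likelihood under an RL model
#'
#' Sum over trials of the log probability of the observed choice given
#' the model state evolved through the preceding trials; the state
#' evolves with [ewa_update()] or [rp_update()] depending on the
#' parameter class (the computation itself runs in compiled code).
#'
#' @param params [ewa_params()] or [rp_params()].
#' @param session A `"prl_session"` data frame.
#' @param coding Payoff coding, see [code_payoffs()].
#' @param config Task config for magnitude coding.
#' @param fictive RP only: fictive update of the unchosen option.
#' @return The total log-likelihood (scalar).
#' @examples
#' s <- run_session(prl_task(), function(h) sample(0:1, 1), seed = 1)
#' log_likelihood(ewa_params(0.5, 0.5, 1), s)
#' @export
log_likelihood <- function(params, session, coding = "sign", config = NULL,
                           fictive = TRUE) {
  if (is.null(session) || nrow(session) == 0L)
    stopf("`session` must contain at least one trial")
  payoffs <- code_payoffs(session, coding, config)
  choices <- assert_choice_index(session$choice)
  ll <- switch(model_name(params),
    ewa = ll_ewa_cpp(choices, payoffs, params$phi, params$rho, params$beta),
    rp = ll_rp_cpp(choices, payoffs, params$a_rew, params$a_pun, params$beta,
                   isTRUE(fictive)))
  if (!is.finite(ll))
    stopf("non-finite log-likelihood for %s at (%s)", model_name(params),
          paste(signif(unlist(params), 4), collapse = ", "))
  ll
}

#' Build a stateful agent policy for [run_session()]
#'
#' Returns a closure implementing a softmax RL agent: before each trial
#' it folds any newly observed outcomes into its internal state (using
#' the model's update rule and the chosen payoff coding) and then
#' samples a choice from [choice_probabilities()] of its current values.
#'
#' @param params [ewa_params()] or [rp_params()].
#' @param config Task config (needed for magnitude coding).
#' @param coding Payoff coding, see [code_payoffs()].
#' @param fictive RP only: fictive update of the unchosen option.
#' @return A policy function suitable for [run_session()].
#' @export
make_agent_policy <- function(params, config = NULL, coding = "sign",
                              fictive = TRUE) {
  model <- model_name(params)
  mean_credit <- NULL
  if (coding == "magnitude") {
    if (is.null(config)) config <- prl_task()
    mean_credit <- vapply(config$stages, stage_mean_win_credit, 0)
  }
  state <- model_state()
  seen <- 0L
  function(history) {
    while (seen < history$n) {
      t <- seen + 1L
      payoff <- if (coding == "sign") {
        if (history$win[t]) 1 else -1
      } else {
        if (history$win[t])
          history$credits[t] / mean_credit[history$stage_index[t]] else -1
      }
      state <<- if (model == "ewa")
        ewa_update(state, history$choice[t], payoff, params)
      else
        rp_update(state, history$choice[t], payoff, params, fictive)
      seen <<- t
    }
    p <- choice_probabilities(state$values, params$beta)
    if (runif(1) < p[2L]) 1L else 0L
  }
}

#' Simulate a model-driven agent through a task
#'
#' The agent chooses by sampling the softmax of its evolving values and
#' the environment responds via the task's reward contingencies; the
#' complete trial record is returned. A compiled fast path is used; it
#' consumes the RNG stream in the same order as the reference path
#' (`run_session(config, make_agent_policy(params, ...))`), so both
#' produce identical sessions under the same seed.
#'
#' @inheritParams make_agent_policy
#' @param config A [prl_task()].
#' @param subject_id,group Identifiers for the session.
#' @param seed Optional seed (same seed, same params: identical session).
#' @return A `"prl_session"` data frame.
#' @examples
#' s <- simulate_agent(ewa_params(0.6, 0.3, 6), seed = 1)
#' table(s$stage_label)
#' @export
simulate_agent <- function(params, config = prl_task(), subject_id = "agent",
                           group = NA_character_, coding = "sign",
                           fictive = TRUE, seed = NULL) {
  stopifnot(inherits(config, "prl_task"))
  model <- model_name(params)
  stages <- config$stages
  res <- with_seed(seed, sim_agent_cpp(
    vapply(stages, `[[`, 0, "p_reward_target"),
    vapply(stages, `[[`, 0, "p_reward_nontarget"),
    vapply(stages, `[[`, 0L, "target_option"),
    vapply(stages, `[[`, 0L, "criterion_consecutive"),
    vapply(stages, `[[`, 0L, "max_trials"),
    lapply(stages, `[[`, "win_credits"),
    lapply(stages, `[[`, "win_probs"),
    config$advance_on_truncation,
    if (model == "ewa") 0L else 1L,
    unlist(params), isTRUE(fictive),
    if (coding == "sign") 0L else 1L,
    vapply(stages, stage_mean_win_credit, 0)))
  completion <- as.logical(res$completion)
  out <- data.frame(
    subject_id = subject_id, group = group,
    stage_index = res$stage_index,
    stage_label = vapply(stages, `[[`, "", "stage_label")[res$stage_index],
    trial_in_stage = res$trial_in_stage,
    choice = res$choice, correct = res$correct,
    credits = res$credits, win = res$win, stringsAsFactors = FALSE)
  structure(out,
            stage_completion = completion,
            incomplete_from = if (any(!completion)) which(!completion)[1L]
                              else NA_integer_,
            config = config,
            class = c("prl_session", "data.frame"))
}
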