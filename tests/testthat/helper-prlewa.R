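# Shared fixtures built in code.

# Minimal hand-built session for metric and likelihood tests.
make_session <- function(choice, win,
                         credits = ifelse(win, 1, 0),
                         stage_index = rep(1L, length(choice)),
                         stage_label = sprintf("stage_%d", stage_index),
                         correct = rep(TRUE, length(choice)),
                         subject_id = "s1", group = NA_character_) {
  n <- length(choice)
  trial_in_stage <- if (n) stats::ave(seq_len(n), stage_index, FUN = seq_along)
                    else integer(0)
  structure(data.frame(subject_id = rep(subject_id, n),
                       group = rep(group, n),
                       stage_index = as.integer(stage_index),
                       stage_label = as.character(stage_label),
                       trial_in_stage = as.integer(trial_in_stage),
                       choice = as.integer(choice), correct = correct,
                       credits = credits, win = win,
                       stringsAsFactors = FALSE),
            class = c("prl_session", "data.frame"))
}

# Random session with arbitrary choice/outcome structure (not generated
# by any model), for likelihood and WSLS property tests.
random_session <- function(n = 60, credit_pool = c(1, 2, 6)) {
  choice <- sample(0:1, n, replace = TRUE)
  win <- runif(n) < 0.55
  credits <- ifelse(win, sample(credit_pool, n, replace = TRUE), 0)
  stage_index <- sort(sample(1:3, n, replace = TRUE))
  make_session(choice, win, credits, stage_index,
               correct = runif(n) < 0.6)
}

# Independent trial-stepping log-likelihood oracle built from the
# exported single-step primitives.
ll_stepping_oracle <- function(params, session, coding = "sign",
                               fictive = TRUE) {
  payoffs <- code_payoffs(session, coding)
  state <- model_state()
  ll <- 0
  for (t in seq_len(nrow(session))) {
    p <- choice_probabilities(state$values, params$beta)
    ll <- ll + log(p[session$choice[t] + 1L])
    state <- if (inherits(params, "ewa_params"))
      ewa_update(state, session$choice[t], payoffs[t], params)
    else
      rp_update(state, session$choice[t], payoffs[t], params, fictive)
  }
  ll
}

# Policy that always picks the current stage's target, assuming it has
# never erred (each stage then takes exactly `criterion` trials).
perfect_policy <- function(config) {
  targets <- vapply(config$stages, `[[`, 0L, "target_option")
  criterion <- config$stages[[1L]]$criterion_consecutive
  function(history) targets[history$n %/% criterion + 1L]
}
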