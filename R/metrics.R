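#' Trials to criterion for one stage
#'
#' The 1-based trial count at which the trailing run of correct choices
#' first reaches `criterion`; `NA` if the run never occurs (incomplete
#' stage). The criterion trials themselves are counted, so the minimum
#' observable value equals `criterion`.
#'
#' @param correct Logical (or 0/1) vector of per-trial correctness.
#' @param criterion Required run of consecutive correct choices.
#' @return Integer trial count, or `NA_integer_` if incomplete.
#' @examples
#' trials_to_criterion(c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE), 6)
#' @export
trials_to_criterion <- function(correct, criterion = 6L) {
  if (length(correct) == 0L) stopf("`correct` must be non-empty")
  criterion <- assert_count(criterion, "criterion")
  run <- 0L
  for (t in seq_along(correct)) {
    run <- if (isTRUE(as.logical(correct[t]))) run + 1L else 0L
    if (run >= criterion) return(t)
  }
  NA_integer_
}

#' Perseverative errors after each reversal
#'
#' For every stage after the first, counts the incorrect choices among
#' the first `window` trials of the stage (clipped to the trials the
#' stage actually has). Persisting with the previous target after a
#' silent reversal shows up here.
#'
#' @param session A `"prl_session"` data frame with >= 2 stages.
#' @param window Post-reversal window, default 6 trials.
#' @return Named integer vector, one element per reversal stage.
#' @export
perseverative_errors <- function(session, window = 6L) {
  window <- assert_count(window, "window")
  stages <- unique(session$stage_index)
  if (length(stages) < 2L) stopf("session must contain at least 2 stages")
  rev_stages <- stages[-1L]
  out <- vapply(rev_stages, function(k) {
    corr <- session$correct[session$stage_index == k]
    sum(!corr[seq_len(min(window, length(corr)))])
  }, 0L)
  names(out) <- session$stage_label[match(rev_stages, session$stage_index)]
  out
}

#' Win-stay / lose-shift proportions
#'
#' Over applicable consecutive trial pairs, win-stay is the proportion
#' of wins followed by repeating the same choice and lose-shift the
#' proportion of losses followed by switching. Because the stimulus
#' pair never changes and reversals are silent, pairs spanning a stage
#' boundary are applicable by default; `within_stage = TRUE` restricts
#' to pairs inside one stage. Proportions with an empty denominator are
#' `NA`, never 0/0.
#'
#' @param session A `"prl_session"` data frame (>= 2 trials).
#' @param stages Optional stage indices (or labels) restricting the
#'   analysis phase; pairs must have both trials inside the phase.
#' @param by_credit Additionally stratify win-stay by win magnitude.
#' @param within_stage Exclude pairs that span a stage boundary.
#' @return A list of class `"wsls"`: `win_stay`, `lose_shift`, their
#'   denominators `n_win`, `n_loss`, and (if `by_credit`) a data frame
#'   `by_credit` with per-magnitude win-stay and denominators.
#' @examples
#' s <- run_session(prl_task(), function(h) sample(0:1, 1), seed = 1)
#' win_stay_lose_shift(s)
#' @export
win_stay_lose_shift <- function(session, stages = NULL, by_credit = FALSE,
                                within_stage = FALSE) {
  n <- nrow(session)
  if (n < 2L) stopf("session must have at least 2 trials")
  sel <- if (is.null(stages)) rep(TRUE, n)
         else session$stage_index %in% stages | session$stage_label %in% stages
  pair <- sel[-n] & sel[-1L]
  if (within_stage)
    pair <- pair & session$stage_index[-n] == session$stage_index[-1L]
  win_t <- session$win[-n]
  stay <- session$choice[-1L] == session$choice[-n]
  ws_num <- sum(pair & win_t & stay)
  ws_den <- sum(pair & win_t)
  ls_num <- sum(pair & !win_t & !stay)
  ls_den <- sum(pair & !win_t)
  out <- list(win_stay = if (ws_den > 0) ws_num / ws_den else NA_real_,
              lose_shift = if (ls_den > 0) ls_num / ls_den else NA_real_,
              n_win = ws_den, n_loss = ls_den)
  if (by_credit) {
    creds <- sort(unique(session$credits[session$win & sel]))
    out$by_credit <- do.call(rbind, lapply(creds, function(cr) {
      hit <- pair & win_t & session$credits[-n] == cr
      data.frame(credits = cr,
                 win_stay = if (sum(hit) > 0) sum(hit & stay) / sum(hit)
                            else NA_real_,
                 n = sum(hit))
    }))
  }
  structure(out, class = "wsls")
}

#' @export
print.wsls <- function(x, digits = 3, ...) {
  cat(sprintf("win-stay %.*f (n=%d)  lose-shift %.*f (n=%d)\n",
              digits, x$win_stay, x$n_win, digits, x$lose_shift, x$n_loss))
  if (!is.null(x$by_credit)) print(x$by_credit, row.names = FALSE)
  invisible(x)
}

#' Devaluation choice-test metrics
#'
#' Response rates are totals over the whole test divided by total test
#' time; the preference ratio (response bias) is valued responses over
#' total responses, `NA` when the subject made no responses at all.
#'
#' @param deval A [deval_session()].
#' @param config The [deval_config()] that produced it.
#' @return A list of class `"deval_metrics"`: `valued_rate`,
#'   `devalued_rate` (responses/s), `bias`, `rating_change` (post - pre
#'   per token), `probe_correct`.
#' @examples
#' d <- run_choice_test(2, 0.5, seed = 1)
#' devaluation_metrics(d)
#' @export
devaluation_metrics <- function(deval, config = deval_config()) {
  stopifnot(inherits(deval, "deval_session"), inherits(config, "deval_config"))
  if (nrow(deval$blocks) != config$n_blocks)
    stopf("deval session has %d blocks; config expects %d",
          nrow(deval$blocks), config$n_blocks)
  total_s <- config$n_blocks * config$block_duration_s
  v <- sum(deval$blocks$valued_responses)
  d <- sum(deval$blocks$devalued_responses)
  rating_change <- if (!is.null(deval$rating_pre) && !is.null(deval$rating_post))
    deval$rating_post - deval$rating_pre else NULL
  structure(list(valued_rate = v / total_s, devalued_rate = d / total_s,
                 bias = if (v + d > 0) v / (v + d) else NA_real_,
                 rating_change = rating_change,
                 probe_correct = deval$probe_correct),
            class = "deval_metrics")
}

#' @export
print.deval_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("bias %s  valued %.*f/s  devalued %.*f/s\n",
              format(round(x$bias, digits)), digits, x$valued_rate,
              digits, x$devalued_rate))
  invisible(x)
}

# Stage labels of each analysis phase in the default task.
phase_stages <- list(
  discrimination = "discrimination",
  first_reversal = "first_reversal",
  SRL1 = paste0("SRL1_", 1:5),
  SRL2 = paste0("SRL2_", 1:4))

#' Per-subject behavioural summary
#'
#' Computes the model-free performance measures for one session (and
#' optionally its devaluation record): per-phase trials-to-criterion
#' aggregates, perseverative errors, win-stay/lose-shift overall, per
#' phase and (for SRL2) by win magnitude, and devaluation metrics.
#' Incomplete stages contribute their observed trials to the
#' win-stay/lose-shift proportions but are excluded from
#' trials-to-criterion phase means (counted in `n_*_incomplete`).
#'
#' @param session A `"prl_session"` data frame.
#' @param deval Optional [deval_session()].
#' @param criterion Consecutive-correct criterion used to score
#'   trials-to-criterion (taken from the session's task config when
#'   available).
#' @param deval_cfg A [deval_config()] for the devaluation metrics.
#' @param window Perseveration window.
#' @return A one-row data frame.
#' @export
behavior_summary <- function(session, deval = NULL, criterion = NULL,
                             deval_cfg = deval_config(), window = 6L) {
  config <- attr(session, "config")
  if (is.null(criterion))
    criterion <- if (!is.null(config))
      config$stages[[1L]]$criterion_consecutive else 6L
  stages <- unique(session$stage_index)
  ttc <- vapply(stages, function(k)
    trials_to_criterion(session$correct[session$stage_index == k], criterion),
    0L)
  labels <- session$stage_label[match(stages, session$stage_index)]
  phase_of <- function(lab) names(phase_stages)[vapply(phase_stages,
                                                       function(p) lab %in% p, TRUE)][1L]
  phases <- vapply(labels, phase_of, "")
  phase_mean <- function(ph) {
    v <- ttc[phases %in% ph]
    if (length(v) == 0L || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  persev <- if (length(stages) >= 2L) perseverative_errors(session, window)
            else integer(0)
  wsls_all <- win_stay_lose_shift(session)
  srl1 <- phase_stages$SRL1; srl2 <- phase_stages$SRL2
  w1 <- if (any(session$stage_label %in% srl1))
    win_stay_lose_shift(session, stages = srl1) else NULL
  w2 <- if (any(session$stage_label %in% srl2))
    win_stay_lose_shift(session, stages = srl2, by_credit = TRUE) else NULL
  ws_credit <- function(cr) {
    if (is.null(w2) || is.null(w2$by_credit)) return(NA_real_)
    i <- match(cr, w2$by_credit$credits)
    if (is.na(i)) NA_real_ else w2$by_credit$win_stay[i]
  }
  out <- data.frame(
    subject_id = session$subject_id[1L],
    group = session$group[1L],
    n_trials = nrow(session),
    incomplete_from = attr(session, "incomplete_from") %||% NA_integer_,
    ttc_discrimination = if ("discrimination" %in% phases)
      as.numeric(ttc[which(phases %in% "discrimination")][1L]) else NA_real_,
    ttc_first_reversal = if ("first_reversal" %in% phases)
      as.numeric(ttc[which(phases %in% "first_reversal")][1L]) else NA_real_,
    ttc_srl1_mean = phase_mean("SRL1"),
    ttc_srl2_mean = phase_mean("SRL2"),
    n_srl1_incomplete = sum(is.na(ttc[phases %in% "SRL1"])),
    n_srl2_incomplete = sum(is.na(ttc[phases %in% "SRL2"])),
    persev_first_reversal = if ("first_reversal" %in% names(persev))
      as.integer(persev["first_reversal"]) else NA_integer_,
    persev_mean = if (length(persev)) mean(persev) else NA_real_,
    win_stay = wsls_all$win_stay, lose_shift = wsls_all$lose_shift,
    n_win = wsls_all$n_win, n_loss = wsls_all$n_loss,
    win_stay_srl1 = if (is.null(w1)) NA_real_ else w1$win_stay,
    lose_shift_srl1 = if (is.null(w1)) NA_real_ else w1$lose_shift,
    win_stay_srl2 = if (is.null(w2)) NA_real_ else w2$win_stay,
    lose_shift_srl2 = if (is.null(w2)) NA_real_ else w2$lose_shift,
    win_stay_credit2 = ws_credit(2), win_stay_credit6 = ws_credit(6),
    stringsAsFactors = FALSE)
  if (!is.null(deval)) {
    dm <- devaluation_metrics(deval, deval_cfg)
    out$bias <- dm$bias
    out$valued_rate <- dm$valued_rate
    out$devalued_rate <- dm$devalued_rate
    rc <- dm$rating_change
    out$rating_change_valued <- if (!is.null(rc) && "valued" %in% names(rc))
      unname(rc["valued"]) else NA_real_
    out$rating_change_devalued <- if (!is.null(rc) && "devalued" %in% names(rc))
      unname(rc["devalued"]) else NA_real_
    out$probe_correct <- dm$probe_correct
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Behavioural summaries for a whole cohort
#'
#' @param sessions List of `"prl_session"` data frames.
#' @param devals Optional list of [deval_session()]s, parallel to
#'   `sessions` (or named by subject id).
#' @param ... Passed to [behavior_summary()].
#' @return Data frame with one row per subject.
#' @export
cohort_summary <- function(sessions, devals = NULL, ...) {
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    d <- if (is.null(devals)) NULL else devals[[i]]
    behavior_summary(sessions[[i]], deval = d, ...)
  }))
}
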