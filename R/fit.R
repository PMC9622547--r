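#' Weakly informative priors for MAP fitting
#'
#' Priors are placed on the unconstrained scale used by the optimizer:
#' unit-interval parameters are logit-transformed with a Normal(0,
#' `unit_sd`^2) prior (logit-normal), and the inverse temperature is
#' log-transformed with a Normal(`beta_meanlog`, `beta_sdlog`^2) prior
#' (log-normal), hard-capped at `beta_max` to keep the softmax away
#' from its saturated regime where the likelihood is flat.
#'
#' @param model `"ewa"` or `"rp"`.
#' @param unit_sd Prior SD on the logit scale for unit parameters.
#' @param beta_meanlog,beta_sdlog Prior mean and SD of `log(beta)`.
#' @param beta_max Upper cap for `beta` during fitting.
#' @return An object of class `"prl_priors"`.
#' @export
prl_priors <- function(model = c("ewa", "rp"), unit_sd = 1.5,
                       beta_meanlog = log(2), beta_sdlog = 1,
                       beta_max = 20) {
  model <- match.arg(model)
  structure(list(model = model,
                 par_names = par_names(model),
                 unit_sd = assert_number(unit_sd, "unit_sd", 1e-6),
                 beta_meanlog = assert_number(beta_meanlog, "beta_meanlog"),
                 beta_sdlog = assert_number(beta_sdlog, "beta_sdlog", 1e-6),
                 beta_max = assert_number(beta_max, "beta_max", 1e-6)),
            class = "prl_priors")
}

par_names <- function(model) {
  switch(model, ewa = c("phi", "rho", "beta"), rp = c("a_rew", "a_pun", "beta"))
}

# unconstrained z -> natural parameter object
z_to_params <- function(z, model) {
  if (model == "ewa") ewa_params(plogis(z[1]), plogis(z[2]), exp(z[3]))
  else rp_params(plogis(z[1]), plogis(z[2]), exp(z[3]))
}

params_to_z <- function(params) {
  p <- unlist(params)
  c(qlogis(p[1]), qlogis(p[2]), log(p[3]))
}

log_prior_z <- function(z, priors) {
  sum(stats::dnorm(z[1:2], 0, priors$unit_sd, log = TRUE)) +
    stats::dnorm(z[3], priors$beta_meanlog, priors$beta_sdlog, log = TRUE)
}

#' Fit an RL model to one subject's session by penalized maximum likelihood
#'
#' Maximizes log-likelihood plus log-prior over the unconstrained
#' (logit/log-transformed) parameter space with multi-start L-BFGS-B,
#' which keeps estimates inside their bounds by construction. With the
#' default priors this is maximum a posteriori estimation under weakly
#' informative priors; group-level quantities are taken as summaries of
#' these per-subject point estimates.
#'
#' @param session A `"prl_session"` data frame (>= `min_trials` trials).
#' @param model `"ewa"` or `"rp"`.
#' @param coding Payoff coding, see [code_payoffs()].
#' @param priors A [prl_priors()]; defaults for the chosen model.
#' @param n_starts Number of optimizer starts; the first is the prior
#'   mode, the rest are prior draws.
#' @param min_trials Minimum session length accepted.
#' @param config Task config (magnitude coding only).
#' @param fictive RP only: fictive update convention.
#' @param seed Optional seed controlling the random starts.
#' @return An object of class `"prl_fit"` with components
#'   `coefficients` (natural scale), `z`, `logLik`,
#'   `neg_log_posterior`, `converged`, `starts` (per-start summary),
#'   `n_trials`, plus the inputs. Equal-objective starts are broken by
#'   the lexicographically smallest parameter vector. If every start
#'   fails the fit is returned flagged (`converged = FALSE`) with `NA`
#'   estimates rather than an error.
#' @examples
#' \donttest{
#' s <- simulate_agent(ewa_params(0.6, 0.3, 6), seed = 1)
#' fit <- prl_fit(s, "ewa", n_starts = 3, seed = 2)
#' coef(fit)
#' }
#' @export
prl_fit <- function(session, model = c("ewa", "rp"), coding = "sign",
                    priors = NULL, n_starts = 10L, min_trials = 20L,
                    config = NULL, fictive = TRUE, seed = NULL) {
  model <- match.arg(model)
  if (is.null(priors)) priors <- prl_priors(model)
  stopifnot(inherits(priors, "prl_priors"), priors$model == model)
  n_starts <- assert_count(n_starts, "n_starts")
  if (is.null(session) || nrow(session) < min_trials)
    stopf("session must have at least %d trials (has %d)", min_trials,
          if (is.null(session)) 0L else nrow(session))
  if (is.null(config)) config <- attr(session, "config")
  payoffs <- code_payoffs(session, coding, config)
  choices <- assert_choice_index(session$choice)

  nlp <- function(z) {
    ll <- if (model == "ewa")
      ll_ewa_cpp(choices, payoffs, plogis(z[1]), plogis(z[2]), exp(z[3]))
    else
      ll_rp_cpp(choices, payoffs, plogis(z[1]), plogis(z[2]), exp(z[3]),
                isTRUE(fictive))
    -(ll + log_prior_z(z, priors))
  }

  upper <- c(10, 10, log(priors$beta_max))
  lower <- c(-10, -10, -10)
  starts <- with_seed(seed, {
    m <- matrix(0, n_starts, 3L)
    m[1, ] <- c(0, 0, priors$beta_meanlog)
    if (n_starts > 1L) {
      for (i in 2:n_starts)
        m[i, ] <- c(rnorm(2, 0, priors$unit_sd),
                    rnorm(1, priors$beta_meanlog, priors$beta_sdlog))
    }
    m[, 3] <- pmin(m[, 3], upper[3] - 1e-3)
    m
  })

  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    results[[i]] <- tryCatch(
      optim(starts[i, ], nlp, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500L)),
      error = function(e) NULL)
  }
  ok <- !vapply(results, is.null, TRUE)
  starts_df <- data.frame(
    start = seq_len(n_starts),
    objective = vapply(results, function(r) if (is.null(r)) NA_real_ else r$value, 0),
    converged = vapply(results, function(r) !is.null(r) && r$convergence == 0, TRUE))

  if (!any(ok)) {
    fit <- list(model = model, coding = coding, fictive = fictive,
                coefficients = setNames(rep(NA_real_, 3), par_names(model)),
                z = rep(NA_real_, 3), logLik = NA_real_,
                neg_log_posterior = NA_real_, converged = FALSE,
                starts = starts_df, n_trials = nrow(session),
                priors = priors, session = session, config = config,
                call = match.call())
    return(structure(fit, class = "prl_fit"))
  }

  vals <- starts_df$objective
  best_val <- min(vals[ok])
  cand <- which(ok & vals <= best_val + 1e-8)
  if (length(cand) > 1L) {
    # lexicographic tie-break on the natural parameter vector
    mats <- t(vapply(cand, function(i) {
      z <- results[[i]]$par
      c(plogis(z[1]), plogis(z[2]), exp(z[3]))
    }, numeric(3)))
    cand <- cand[do.call(order, as.data.frame(mats))[1L]]
  }
  best <- results[[cand[1L]]]
  z <- best$par
  params <- z_to_params(z, model)
  ll <- if (model == "ewa")
    ll_ewa_cpp(choices, payoffs, params$phi, params$rho, params$beta)
  else
    ll_rp_cpp(choices, payoffs, params$a_rew, params$a_pun, params$beta,
              isTRUE(fictive))

  structure(list(model = model, coding = coding, fictive = fictive,
                 coefficients = setNames(unlist(params), par_names(model)),
                 z = z, logLik = ll, neg_log_posterior = best$value,
                 converged = best$convergence == 0, starts = starts_df,
                 n_trials = nrow(session), priors = priors,
                 session = session, config = config, call = match.call()),
            class = "prl_fit")
}

#' Reporting convention for fitted parameters
#'
#' `convention = "reported"` returns the complements of the decay/rate
#' parameters (`1 - phi` as a learning rate for EWA; inverted learning
#' rates for RP), the convention used when such fits are displayed in
#' figures; the raw parameters always drive the internal math.
#'
#' @param object A `"prl_fit"`.
#' @param convention `"raw"` (default) or `"reported"`.
#' @param ... Unused.
#' @return Named numeric vector of parameter estimates.
#' @export
coef.prl_fit <- function(object, convention = c("raw", "reported"), ...) {
  convention <- match.arg(convention)
  co <- object$coefficients
  if (convention == "raw") return(co)
  if (object$model == "ewa")
    c(learning_rate = unname(1 - co["phi"]),
      experience_decay = unname(co["rho"]),
      inverse_temperature = unname(co["beta"]))
  else
    c(reward_learning = unname(1 - co["a_rew"]),
      punishment_learning = unname(1 - co["a_pun"]),
      inverse_temperature = unname(co["beta"]))
}

#' @export
logLik.prl_fit <- function(object, ...) {
  structure(object$logLik, df = 3L, nobs = object$n_trials, class = "logLik")
}

#' @export
print.prl_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s model fit (%s payoff coding), %d trials\n",
              toupper(x$model), x$coding, x$n_trials))
  print(round(x$coefficients, digits))
  cat(sprintf("logLik %.3f  neg. log posterior %.3f  converged: %s\n",
              x$logLik, x$neg_log_posterior, x$converged))
  invisible(x)
}

#' @export
summary.prl_fit <- function(object, ...) {
  structure(list(fit = object,
                 raw = coef(object),
                 reported = coef(object, "reported"),
                 n_starts = nrow(object$starts),
                 n_converged = sum(object$starts$converged),
                 objective_spread =
                   diff(range(object$starts$objective, na.rm = TRUE))),
            class = "summary.prl_fit")
}

#' @export
print.summary.prl_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nReporting convention:\n")
  print(round(x$reported, digits))
  cat(sprintf("\n%d/%d starts converged; objective spread %.4g\n",
              x$n_converged, x$n_starts, x$objective_spread))
  invisible(x)
}

# Per-trial state stepping in R; returns the pre-choice probability of
# option 1 and of the observed choice for each trial.
step_probabilities <- function(params, session, coding = "sign",
                               config = NULL, fictive = TRUE) {
  payoffs <- code_payoffs(session, coding, config)
  model <- model_name(params)
  state <- model_state()
  n <- nrow(session)
  p1 <- numeric(n)
  for (t in seq_len(n)) {
    p1[t] <- choice_probabilities(state$values, params$beta)[2L]
    state <- if (model == "ewa")
      ewa_update(state, session$choice[t], payoffs[t], params)
    else
      rp_update(state, session$choice[t], payoffs[t], params, fictive)
  }
  data.frame(p_choice1 = p1,
             p_observed = ifelse(session$choice == 1L, p1, 1 - p1))
}

#' Predicted per-trial choice probabilities
#'
#' @param object A `"prl_fit"`.
#' @param newdata Optional session to score; defaults to the fitted one.
#' @param ... Unused.
#' @return Data frame with `p_choice1` (probability of option 1 before
#'   each trial) and `p_observed` (probability of the observed choice).
#' @export
predict.prl_fit <- function(object, newdata = NULL, ...) {
  session <- if (is.null(newdata)) object$session else newdata
  params <- z_to_params(object$z, object$model)
  step_probabilities(params, session, object$coding, object$config,
                     object$fictive)
}

#' @param type `"response"` (choice - predicted probability) or
#'   `"pearson"`.
#' @rdname predict.prl_fit
#' @export
residuals.prl_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object)$p_choice1
  r <- (object$session$choice == 1L) - p
  if (type == "pearson") r <- r / sqrt(pmax(p * (1 - p), 1e-12))
  r
}

#' Simulate sessions from a fitted model
#'
#' @param object A `"prl_fit"`.
#' @param nsim Number of sessions.
#' @param seed Optional seed.
#' @param config Task to simulate through; defaults to the fitted
#'   session's task (or the default task).
#' @param ... Unused.
#' @return A list of `"prl_session"` data frames.
#' @export
simulate.prl_fit <- function(object, nsim = 1, seed = NULL, config = NULL, ...) {
  if (is.null(config)) config <- object$config
  if (is.null(config)) config <- prl_task()
  params <- z_to_params(object$z, object$model)
  with_seed(seed, {
    seeds <- derive_seeds(nsim)
    lapply(seq_len(nsim), function(i)
      simulate_agent(params, config, subject_id = paste0("sim", i),
                     coding = object$coding, fictive = object$fictive,
                     seed = seeds[i]))
  })
}

#' @export
plot.prl_fit <- function(x, ...) {
  pr <- predict(x)
  s <- x$session
  p_correct <- ifelse(s$correct, pr$p_observed, 1 - pr$p_observed)
  plot(seq_len(nrow(s)), p_correct, type = "l", ylim = c(0, 1),
       xlab = "trial", ylab = "P(correct choice)",
       main = sprintf("%s fit: predicted accuracy", toupper(x$model)), ...)
  points(which(s$correct), rep(1.02, sum(s$correct)), pch = "|", cex = 0.4)
  bounds <- which(diff(s$stage_index) != 0)
  abline(v = bounds + 0.5, col = "grey70", lty = 3)
  invisible(x)
}

#' Fit a cohort of sessions
#'
#' Independent per-subject fits, order preserved; a subject whose fit
#' fails is returned flagged, never dropped.
#'
#' @param sessions Non-empty list of `"prl_session"` data frames.
#' @param model,coding,priors,n_starts,min_trials,fictive See [prl_fit()].
#' @param seed Optional seed; per-subject sub-seeds are derived from it.
#' @return A list of `"prl_fit"` objects, class `"prl_fit_list"`.
#' @export
fit_cohort <- function(sessions, model = c("ewa", "rp"), coding = "sign",
                       priors = NULL, n_starts = 10L, min_trials = 20L,
                       fictive = TRUE, seed = NULL) {
  model <- match.arg(model)
  if (!is.list(sessions) || length(sessions) == 0L)
    stopf("`sessions` must be a non-empty list of sessions")
  seeds <- derive_seeds(length(sessions), seed)
  fits <- lapply(seq_along(sessions), function(i)
    prl_fit(sessions[[i]], model, coding = coding, priors = priors,
            n_starts = n_starts, min_trials = min_trials, fictive = fictive,
            seed = seeds[i]))
  names(fits) <- vapply(sessions, function(s) s$subject_id[1L], "")
  structure(fits, class = "prl_fit_list")
}

#' Tabulate cohort fit results
#'
#' @param fits A `"prl_fit_list"`.
#' @return Data frame with one row per subject: raw and
#'   reporting-convention parameters, `neg_log_posterior`, `converged`,
#'   `n_trials`.
#' @export
fit_results_table <- function(fits) {
  stopifnot(inherits(fits, "prl_fit_list"))
  do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    raw <- coef(f)
    rep_ <- coef(f, "reported")
    cbind(data.frame(subject_id = id, model = f$model,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(raw)),
          setNames(as.data.frame(as.list(rep_)),
                   paste0("reported_", names(rep_))),
          data.frame(neg_log_posterior = f$neg_log_posterior,
                     converged = f$converged, n_trials = f$n_trials))
  }))
}

#' @export
print.prl_fit_list <- function(x, ...) {
  cat(sprintf("Cohort of %d %s fits (%d converged)\n", length(x),
              toupper(x[[1L]]$model),
              sum(vapply(x, `[[`, TRUE, "converged"))))
  invisible(x)
}

#' Write cohort fit results to CSV
#'
#' @param fits A `"prl_fit_list"`.
#' @param path Output CSV path.
#' @export
write_fit_results <- function(fits, path) {
  write.csv(fit_results_table(fits), path, row.names = FALSE)
  invisible(path)
}

#' Random design of true parameters for recovery studies
#'
#' Draws generating parameters over the ranges where the task is
#' informative: `phi`, `rho` uniform on (0.05, 0.95) and `beta`
#' log-uniform on (0.5, 12).
#'
#' @param n_subjects Number of simulated subjects.
#' @param model `"ewa"` or `"rp"`.
#' @param seed Optional seed.
#' @return Data frame of true parameters, one row per subject.
#' @export
recovery_design <- function(n_subjects = 40L, model = c("ewa", "rp"),
                            seed = NULL) {
  model <- match.arg(model)
  n_subjects <- assert_count(n_subjects, "n_subjects")
  with_seed(seed, {
    df <- data.frame(a = runif(n_subjects, 0.05, 0.95),
                     b = runif(n_subjects, 0.05, 0.95),
                     beta = exp(runif(n_subjects, log(0.5), log(12))))
    names(df)[1:2] <- par_names(model)[1:2]
    df
  })
}

#' Parameter recovery study
#'
#' Simulate agents at known parameters, refit each session, and report
#' per-parameter recovery quality (Pearson correlation, bias, RMSE).
#' Long fixed-length sessions (see [recovery_task()]) certify the
#' estimator; the short 11-stage task recovers noisier estimates, and a
#' recovery report on it will show that.
#'
#' @param true_params Data frame of generating parameters (one row per
#'   subject), e.g. from [recovery_design()].
#' @param model `"ewa"` or `"rp"`.
#' @param config Task the agents play; default [recovery_task()]
#'   (~500 trials).
#' @param n_starts Optimizer starts per fit.
#' @param coding,fictive Passed through to simulation and fitting.
#' @param seed Optional seed.
#' @return Object of class `"recovery_report"`: `pairs` (true and
#'   estimated values per subject) and `summary` (per-parameter `cor`,
#'   `bias`, `rmse`), plus the design description.
#' @export
parameter_recovery <- function(true_params, model = c("ewa", "rp"),
                               config = recovery_task(), n_starts = 5L,
                               coding = "sign", fictive = TRUE, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is.data.frame(true_params),
            all(par_names(model) %in% names(true_params)))
  pn <- par_names(model)
  n <- nrow(true_params)
  seeds <- derive_seeds(2L * n, seed)
  est <- matrix(NA_real_, n, 3L, dimnames = list(NULL, pn))
  for (i in seq_len(n)) {
    p <- if (model == "ewa")
      ewa_params(true_params[i, pn[1]], true_params[i, pn[2]],
                 true_params[i, "beta"])
    else
      rp_params(true_params[i, pn[1]], true_params[i, pn[2]],
                true_params[i, "beta"])
    s <- simulate_agent(p, config, subject_id = paste0("r", i),
                        coding = coding, fictive = fictive, seed = seeds[i])
    f <- prl_fit(s, model, coding = coding, n_starts = n_starts,
                 fictive = fictive, seed = seeds[n + i], config = config)
    est[i, ] <- coef(f)
  }
  pairs <- cbind(true_params[, pn],
                 setNames(as.data.frame(est), paste0("est_", pn)))
  summ <- do.call(rbind, lapply(pn, function(nm) {
    tr <- pairs[[nm]]; e <- pairs[[paste0("est_", nm)]]
    data.frame(parameter = nm, cor = cor(tr, e, use = "complete.obs"),
               bias = mean(e - tr, na.rm = TRUE),
               rmse = sqrt(mean((e - tr)^2, na.rm = TRUE)))
  }))
  structure(list(pairs = pairs, summary = summ, model = model,
                 n_subjects = n,
                 n_trials = sum(vapply(config$stages, `[[`, 0L, "max_trials"))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat(sprintf("Parameter recovery: %s model, %d subjects, <= %d trials each\n",
              toupper(x$model), x$n_subjects, x$n_trials))
  print(transform(x$summary, cor = round(cor, digits),
                  bias = round(bias, digits), rmse = round(rmse, digits)),
        row.names = FALSE)
  invisible(x)
}
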