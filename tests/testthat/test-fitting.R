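# Penalized objective reconstructed independently of the fitter.
neg_log_post_at <- function(params, session, priors) {
  z <- c(qlogis(unlist(params)[1:2]), log(unlist(params)[3]))
  lp <- sum(dnorm(z[1:2], 0, priors$unit_sd, log = TRUE)) +
    dnorm(z[3], priors$beta_meanlog, priors$beta_sdlog, log = TRUE)
  -(log_likelihood(params, session) + lp)
}

test_that("MAP fits respect bounds, optimality and determinism", {
  true <- ewa_params(0.65, 0.35, 4)
  s <- simulate_agent(true, recovery_task(n_stages = 8L), seed = 31)
  fit <- prl_fit(s, "ewa", n_starts = 4, seed = 32)
  co <- coef(fit)
  expect_true(fit$converged)
  expect_true(co["phi"] > 0 && co["phi"] < 1)
  expect_true(co["rho"] > 0 && co["rho"] < 1)
  expect_true(co["beta"] >= 0 && co["beta"] <= fit$priors$beta_max)
  # best start dominates every other start
  expect_true(all(fit$neg_log_posterior <= fit$starts$objective + 1e-8))

  # fitted optimum at least as good as the generating parameters
  expect_lte(fit$neg_log_posterior, neg_log_post_at(true, s, fit$priors))

  expect_identical(coef(prl_fit(s, "ewa", n_starts = 4, seed = 32)), co)

  # reporting convention complements the raw decays
  rep_ <- coef(fit, "reported")
  expect_equal(unname(rep_["learning_rate"]), unname(1 - co["phi"]))
  expect_equal(unname(rep_["experience_decay"]), unname(co["rho"]))

  # re-optimizing from the returned optimum does not move it
  z <- fit$z
  refit <- optim(z, function(zz)
    neg_log_post_at(ewa_params(plogis(zz[1]), plogis(zz[2]), exp(zz[3])),
                    s, fit$priors),
    method = "L-BFGS-B", lower = c(-10, -10, -10),
    upper = c(10, 10, log(fit$priors$beta_max)))
  expect_lt(abs(refit$value - fit$neg_log_posterior), 1e-6)
})

test_that("sessions below the trial floor are rejected", {
  short <- make_session(rep(0L, 5), rep(TRUE, 5))
  expect_error(prl_fit(short, "ewa"), "at least 20 trials")
})

test_that("cohort fitting preserves order and handles duplicates", {
  s <- simulate_agent(ewa_params(0.6, 0.3, 3), seed = 33)
  fits <- fit_cohort(list(s, s), "ewa", n_starts = 2, seed = 34)
  expect_length(fits, 2L)
  expect_identical(coef(fits[[1L]]), coef(fits[[2L]]))
  expect_error(fit_cohort(list(), "ewa"), "non-empty")
  tab <- fit_results_table(fits)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("phi", "rho", "beta", "reported_learning_rate",
                    "neg_log_posterior", "converged") %in% names(tab)))
})

test_that("RP model fits recover the fitted objective structure", {
  s <- simulate_agent(rp_params(0.5, 0.3, 3), recovery_task(n_stages = 8L),
                      seed = 35)
  fit <- prl_fit(s, "rp", n_starts = 3, seed = 36)
  expect_true(fit$converged)
  expect_named(coef(fit), c("a_rew", "a_pun", "beta"))
  # stepping probabilities agree with the stored log-likelihood
  expect_equal(sum(log(predict(fit)$p_observed)), fit$logLik,
               tolerance = 1e-8)
})

test_that("prl_fit methods are coherent", {
  s <- simulate_agent(ewa_params(0.6, 0.3, 3), seed = 37)
  fit <- prl_fit(s, "ewa", n_starts = 3, seed = 38)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  pr <- predict(fit)
  expect_equal(nrow(pr), nrow(s))
  expect_true(all(pr$p_observed > 0 & pr$p_observed < 1))
  expect_equal(sum(log(pr$p_observed)), fit$logLik, tolerance = 1e-8)
  r <- residuals(fit)
  expect_equal(r, (s$choice == 1L) - pr$p_choice1)
  sims <- simulate(fit, nsim = 2, seed = 39)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1L]], "prl_session")
  expect_identical(sims, simulate(fit, nsim = 2, seed = 39))
})

test_that("recovery improves with session length and stays in bounds", {
  des <- recovery_design(16, "ewa", seed = 31)
  expect_true(all(des$phi >= 0.05 & des$phi <= 0.95))
  short <- parameter_recovery(des, "ewa",
                              config = recovery_task(n_stages = 4L),
                              n_starts = 4, seed = 32)
  long <- parameter_recovery(des, "ewa",
                             config = recovery_task(n_stages = 20L),
                             n_starts = 4, seed = 32)
  expect_true(all(is.finite(short$summary$cor)))
  expect_true(all(abs(short$summary$cor) <= 1))
  # 100-trial sessions recover every parameter more noisily than 500-trial
  cor_of <- function(rep, p) rep$summary$cor[rep$summary$parameter == p]
  for (p in c("phi", "rho", "beta"))
    expect_gte(cor_of(long, p), cor_of(short, p))
})
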