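ctrl <- ewa_params(0.60, 0.30, 3.0)
ipp <- ewa_params(0.75, 0.35, 2.5)
imp <- ewa_params(0.75, 0.75, 2.0)

test_that("substitution design enumerates 3 baselines + 3 singles + 3 pairs", {
  conds <- substitution_conditions(ctrl, ipp, imp)
  expect_length(conds, 9L)
  labs <- vapply(conds, `[[`, "", "label")
  expect_setequal(labs, c("control_intact", "pp_intact", "pp_impaired",
                          "sub_phi", "sub_rho", "sub_beta",
                          "sub_phi_rho", "sub_phi_beta", "sub_rho_beta"))
  rb <- conds[[which(labs == "sub_rho_beta")]]
  expect_identical(unname(rb$provenance),
                   c("control", "impaired", "impaired"))
  expect_equal(rb$params$phi, ctrl$phi)
  expect_equal(rb$params$rho, imp$rho)
  expect_equal(rb$params$beta, imp$beta)

  # degenerate input: control == impaired collapses all parameter values
  degen <- substitution_conditions(ctrl, ctrl, ctrl)
  vals <- t(vapply(degen, function(cn) unlist(cn$params), numeric(3)))
  expect_true(all(apply(vals, 2, function(v) diff(range(v)) == 0)))
})

test_that("run_condition simulates the requested number of agents deterministically", {
  r <- run_condition(ctrl, n_agents = 20, seed = 51)
  expect_equal(nrow(r), 20L)
  expect_true(all(r$ttc_srl1 >= 6))
  expect_true(all(r$win_stay_srl1 >= 0 & r$win_stay_srl1 <= 1, na.rm = TRUE))
  expect_identical(r, run_condition(ctrl, n_agents = 20, seed = 51))
  expect_error(run_condition(ctrl, n_agents = 1), "n_agents")
})

test_that("Dunnett comparisons reduce to the t-test at k = 1", {
  set.seed(52)
  x <- rnorm(20, 10, 2); y <- rnorm(20, 11.5, 2)
  d <- dunnett_test(c(x, y), rep(c("ctrl", "trt"), each = 20), "ctrl")
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(d$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(d$diff, mean(y) - mean(x))
})

test_that("Dunnett familywise adjustment behaves at the extremes", {
  set.seed(53)
  ctrl_v <- rnorm(20)
  # treatment identical to control: p ~ 1
  d <- dunnett_test(c(ctrl_v, ctrl_v, rnorm(20)),
                    rep(c("c", "same", "other"), each = 20), "c")
  expect_gt(d$p_adj[d$condition == "same"], 0.999)
  # huge shift: p < 0.001
  shift <- rnorm(20) + 5
  d2 <- dunnett_test(c(ctrl_v, shift, rnorm(20)),
                     rep(c("c", "far", "other"), each = 20), "c")
  expect_lt(d2$p_adj[d2$condition == "far"], 1e-3)
  # adjusted p is never smaller than the per-comparison p
  raw <- 2 * pt(-abs(d2$t), df = 57)
  expect_true(all(d2$p_adj >= raw - 1e-6))
  expect_error(dunnett_test(rep(1, 40), rep(c("c", "t"), each = 20), "c"),
               "zero within-group variance")
})

test_that("a slower-updating, noisier agent shows both SRL1 deficits directionally", {
  a <- run_condition(ctrl, n_agents = 60, seed = 54)
  b <- run_condition(ewa_params(ctrl$phi, 0.85, 1.2), n_agents = 60, seed = 55)
  expect_gt(mean(b$ttc_srl1), mean(a$ttc_srl1))
  expect_lt(mean(b$win_stay_srl1, na.rm = TRUE),
            mean(a$win_stay_srl1, na.rm = TRUE))
})

test_that("experience decay alone weakly slows reversal performance", {
  ttc <- vapply(c(0.3, 0.6, 0.9), function(rho)
    mean(run_condition(ewa_params(0.6, rho, 3), n_agents = 80,
                       seed = 56)$ttc_srl1), 0)
  expect_true(all(diff(ttc) > -0.3))
  expect_gt(ttc[3], ttc[1])
})

test_that("the full study is reproducible and separates the impaired baseline", {
  st <- run_simulation_study(ctrl, ipp, imp, n_agents = 20, seed = 7)
  expect_s3_class(st, "prl_simstudy")
  expect_equal(nrow(st$agents), 9 * 20)
  expect_equal(nrow(st$summary), 18L)
  st2 <- run_simulation_study(ctrl, ipp, imp, n_agents = 20, seed = 7)
  expect_identical(st$agents, st2$agents)
  expect_equal(st$summary$p_adj, st2$summary$p_adj, tolerance = 1e-6)

  s <- st$summary
  g <- function(cond, m, col) s[[col]][s$condition == cond & s$metric == m]
  expect_gt(g("pp_impaired", "ttc_srl1", "mean"),
            g("control_intact", "ttc_srl1", "mean"))
  expect_lt(g("pp_impaired", "win_stay_srl1", "mean"),
            g("control_intact", "win_stay_srl1", "mean"))
  expect_lt(g("pp_impaired", "ttc_srl1", "p_adj"), 0.05)
  expect_lt(g("pp_impaired", "win_stay_srl1", "p_adj"), 0.05)

  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_simstudy(st, csv, js)
  man <- jsonlite::read_json(js)
  expect_equal(man$seed, 7)
  expect_length(man$conditions, 9L)
})
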