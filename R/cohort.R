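#' Default group-level EWA parameter sets
#'
#' The generator's defaults encode the qualitative group structure of
#' the study population: both psychosis parameter sets have a higher
#' attraction decay `phi` (i.e. a lower reported learning rate) than
#' controls; the impaired set additionally has a markedly higher
#' experience decay `rho` and a lower inverse temperature `beta`. The
#' numeric values are package configuration chosen to reproduce those
#' orderings and the resulting behavioural pattern, not estimates of
#' any cohort.
#'
#' @return Named list of [ewa_params()]: `control_intact`, `pp_intact`,
#'   `pp_impaired`.
#' @export
default_group_params <- function() {
  list(control_intact = ewa_params(phi = 0.60, rho = 0.30, beta = 3.0),
       pp_intact = ewa_params(phi = 0.75, rho = 0.35, beta = 2.5),
       pp_impaired = ewa_params(phi = 0.75, rho = 0.75, beta = 2.0))
}

#' Specify one cohort group
#'
#' Each group mixes an intact and an impaired goal-directed-action
#' component: a subject's component determines both its devaluation
#' bias distribution (a Beta component of a bimodal mixture) and which
#' EWA parameter set its reversal-learning behaviour is generated from.
#'
#' @param label Group label.
#' @param n Number of subjects.
#' @param p_impaired Probability a subject belongs to the impaired
#'   component.
#' @param params_intact,params_impaired [ewa_params()] means for the
#'   two components.
#' @param dispersion Named SDs (`phi`, `rho`, `beta`) of subject-level
#'   parameter variation on the unconstrained (logit/log) scale; 0 gives
#'   every subject the component means.
#' @param bias_intact,bias_impaired `c(mean, concentration)` of the
#'   Beta bias components (intact near 1, impaired near 0.5).
#' @param rate_mean,rate_cv Mean and coefficient of variation of the
#'   subject's total devaluation response rate (responses/s, Gamma).
#' @param rating_drop_devalued Mean post-devaluation drop in the
#'   devalued token's Likert rating (intact component; the impaired
#'   component drops one point less, mirroring the blunted re-rating
#'   seen in impaired subjects).
#' @param probe_accuracy Probability each of the two probe questions is
#'   answered correctly.
#' @return An object of class `"group_spec"`.
#' @export
group_spec <- function(label, n, p_impaired,
                       params_intact, params_impaired,
                       dispersion = c(phi = 0.25, rho = 0.25, beta = 0.25),
                       bias_intact = c(mean = 0.95, conc = 40),
                       bias_impaired = c(mean = 0.50, conc = 20),
                       rate_mean = 1.5, rate_cv = 0.3,
                       rating_drop_devalued = 3, probe_accuracy = 0.95) {
  stopifnot(inherits(params_intact, "ewa_params"),
            inherits(params_impaired, "ewa_params"))
  structure(list(label = as.character(label),
                 n = assert_count(n, "n"),
                 p_impaired = assert_number(p_impaired, "p_impaired", 0, 1),
                 params_intact = params_intact,
                 params_impaired = params_impaired,
                 dispersion = dispersion,
                 bias_intact = bias_intact, bias_impaired = bias_impaired,
                 rate_mean = assert_number(rate_mean, "rate_mean", 0),
                 rate_cv = assert_number(rate_cv, "rate_cv", 0),
                 rating_drop_devalued = rating_drop_devalued,
                 probe_accuracy = assert_number(probe_accuracy,
                                                "probe_accuracy", 0, 1)),
            class = "group_spec")
}

#' Specify a whole synthetic cohort
#'
#' @param groups List of [group_spec()]s with unique labels.
#' @param task A [prl_task()].
#' @param deval A [deval_config()].
#' @param seed Master seed stored with the spec.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups, task = prl_task(), deval = deval_config(),
                        seed = 1L) {
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("group labels must be unique")
  structure(list(groups = groups, task = task, deval = deval,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The default study-sized cohort specification
#'
#' Two groups mirroring the study design: 34 controls with a 6/34
#' impaired fraction and 45 psychosis subjects with a 27/45 impaired
#' fraction. Controls' intact component uses the control parameter set;
#' psychosis subjects' intact component uses the psychosis-intact set;
#' the impaired component of either group uses the impaired set.
#'
#' @param seed Master seed.
#' @param params Group parameter sets, see [default_group_params()].
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, params = default_group_params()) {
  cohort_spec(list(
    group_spec("control", 34L, p_impaired = 6 / 34,
               params_intact = params$control_intact,
               params_impaired = params$pp_impaired),
    group_spec("psychosis", 45L, p_impaired = 27 / 45,
               params_intact = params$pp_intact,
               params_impaired = params$pp_impaired)),
    seed = seed)
}

#' Draw one subject's EWA parameters from a group component
#'
#' Component means are perturbed on the unconstrained (logit/log) scale
#' by the group's dispersion and mapped back, so draws always respect
#' the parameter bounds.
#'
#' @param group A [group_spec()].
#' @param component `"intact"` or `"impaired"`.
#' @param seed Optional seed.
#' @return An [ewa_params()].
#' @export
sample_subject_params <- function(group, component = c("intact", "impaired"),
                                  seed = NULL) {
  component <- match.arg(component)
  mu <- params_to_z(if (component == "intact") group$params_intact
                    else group$params_impaired)
  disp <- group$dispersion[c("phi", "rho", "beta")]
  with_seed(seed, {
    z <- mu + rnorm(3, 0, disp)
    ewa_params(plogis(z[1]), plogis(z[2]), exp(z[3]))
  })
}

rbeta_mc <- function(n, mean, conc) rbeta(n, mean * conc, (1 - mean) * conc)

#' Generate a complete synthetic cohort
#'
#' For every subject: an impairment component is drawn, EWA parameters
#' sampled from that component, a reversal-learning session simulated
#' through the task, and a devaluation choice test simulated with
#' response rates implied by the subject's bias draw (valued rate =
#' total rate x bias). Ground-truth components and parameters are
#' retained so downstream recovery can be scored.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed; defaults to the spec's master seed.
#' @return Object of class `"prl_cohort"`: `subjects` (ground-truth
#'   table), `sessions` and `devals` (named lists keyed by subject id),
#'   `spec`, `seed`.
#' @examples
#' \donttest{
#' co <- generate_cohort(demo_cohort_spec(), seed = 1)
#' table(co$subjects$group, co$subjects$component)
#' }
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    subjects <- list(); sessions <- list(); devals <- list()
    for (g in spec$groups) {
      for (i in seq_len(g$n)) {
        id <- sprintf("%s_%02d", g$label, i)
        component <- if (runif(1) < g$p_impaired) "impaired" else "intact"
        params <- sample_subject_params(g, component)
        session <- simulate_agent(params, spec$task, subject_id = id,
                                  group = g$label)
        bias_par <- if (component == "impaired") g$bias_impaired else g$bias_intact
        bias <- rbeta_mc(1, bias_par["mean"], bias_par["conc"])
        shape <- 1 / g$rate_cv^2
        total_rate <- rgamma(1, shape = shape, rate = shape / g$rate_mean)
        deval <- run_choice_test(total_rate * bias, total_rate * (1 - bias),
                                 spec$deval)
        pre <- c(valued = sample(4:6, 1), devalued = sample(4:6, 1))
        drop <- g$rating_drop_devalued - (component == "impaired")
        post <- c(valued = unname(pre["valued"]),
                  devalued = max(1, unname(pre["devalued"]) - drop))
        deval$rating_pre <- pre
        deval$rating_post <- post
        deval$probe_correct <- rbinom(1, 2, g$probe_accuracy)
        deval$devalued_token <- sample(c("left", "right"), 1)
        subjects[[id]] <- data.frame(
          subject_id = id, group = g$label, component = component,
          phi = params$phi, rho = params$rho, beta = params$beta,
          bias_true = bias, total_rate = total_rate,
          stringsAsFactors = FALSE)
        sessions[[id]] <- session
        devals[[id]] <- deval
      }
    }
    structure(list(subjects = do.call(rbind, c(subjects, make.row.names = FALSE)),
                   sessions = sessions, devals = devals,
                   spec = spec, seed = seed),
              class = "prl_cohort")
  })
}

#' @export
print.prl_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, seed %d\n",
              nrow(x$subjects), x$seed))
  print(table(x$subjects$group, x$subjects$component))
  invisible(x)
}

#' Small cohort specification for examples and tests
#'
#' A scaled-down cohort (26 subjects) with the full bimodal and group
#' structure of [default_cohort_spec()], generated in seconds.
#'
#' @param seed Master seed.
#' @return A [cohort_spec()].
#' @export
demo_cohort_spec <- function(seed = 1L) {
  params <- default_group_params()
  cohort_spec(list(
    group_spec("control", 12L, p_impaired = 2 / 12,
               params_intact = params$control_intact,
               params_impaired = params$pp_impaired),
    group_spec("psychosis", 14L, p_impaired = 8 / 14,
               params_intact = params$pp_intact,
               params_impaired = params$pp_impaired)),
    seed = seed)
}

#' Mean fitted parameters per ground-truth component
#'
#' Fits the cohort's sessions and averages the per-subject estimates
#' within (group, component) cells, returning the three parameter sets
#' the substitution study consumes.
#'
#' @param cohort A `"prl_cohort"`.
#' @param fits Optional precomputed `"prl_fit_list"` for the cohort's
#'   sessions (in cohort order); fitted here when omitted.
#' @param ... Passed to [fit_cohort()].
#' @return List with `control_intact`, `pp_intact`, `pp_impaired`
#'   [ewa_params()] plus the underlying `table` of per-subject
#'   estimates.
#' @export
fitted_group_params <- function(cohort, fits = NULL, ...) {
  stopifnot(inherits(cohort, "prl_cohort"))
  if (is.null(fits)) fits <- fit_cohort(cohort$sessions, "ewa", ...)
  tab <- fit_results_table(fits)
  tab <- merge(tab, cohort$subjects[, c("subject_id", "group", "component")],
               by = "subject_id")
  cell_mean <- function(grp, comp) {
    rows <- tab$group %in% grp & tab$component == comp & tab$converged
    ewa_params(mean(tab$phi[rows]), mean(tab$rho[rows]), mean(tab$beta[rows]))
  }
  list(control_intact = cell_mean("control", "intact"),
       pp_intact = cell_mean("psychosis", "intact"),
       pp_impaired = cell_mean(c("control", "psychosis"), "impaired"),
       table = tab)
}
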