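# CSV/JSON interchange. Trial tables use 0-based option indices and
# 1-based trial numbering; every file begins with a schema-version
# comment line.

trial_cols <- c("subject_id", "group", "stage_index", "stage_label",
                "trial_in_stage", "choice", "correct", "credits", "win")

sessions_to_df <- function(sessions) {
  if (inherits(sessions, "prl_session")) sessions <- list(sessions)
  if (inherits(sessions, "prl_cohort")) sessions <- sessions$sessions
  do.call(rbind, lapply(sessions, function(s) as.data.frame(s)[, trial_cols]))
}

write_versioned_csv <- function(df, path, schema) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# prlewa %s v1", schema), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_versioned_csv <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s: missing required column(s): %s", basename(path),
          paste(missing, collapse = ", "))
  df
}

#' Write and read trial tables
#'
#' One row per trial; the reader re-orders rows canonically by
#' (subject, stage, trial), rejects duplicate (subject, stage, trial)
#' keys naming the offending rows, and splits the table back into
#' per-subject sessions. A write/read cycle is lossless for the trial
#' records (simulation-only attributes such as the task config are not
#' serialized).
#'
#' @param sessions A `"prl_session"`, a list of them, or a
#'   `"prl_cohort"`.
#' @param path CSV path.
#' @return `write_trial_table` returns the path; `read_trial_table` a
#'   named list of `"prl_session"` data frames.
#' @export
write_trial_table <- function(sessions, path) {
  write_versioned_csv(sessions_to_df(sessions), path, "trial_table")
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- read_versioned_csv(path, trial_cols)
  if (nrow(df) == 0L) return(list())
  key <- paste(df$subject_id, df$stage_index, df$trial_in_stage, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stopf("duplicate (subject, stage, trial) keys at data row(s) %s",
          paste(head(dup, 10L), collapse = ", "))
  }
  df <- df[order(df$subject_id, df$stage_index, df$trial_in_stage), ]
  rownames(df) <- NULL
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$stage_label <- as.character(df$stage_label)
  df$correct <- as.logical(df$correct)
  df$win <- as.logical(df$win)
  df$credits <- as.numeric(df$credits)
  out <- lapply(split(df, df$subject_id), function(s) {
    rownames(s) <- NULL
    class(s) <- c("prl_session", "data.frame")
    s
  })
  out[unique(df$subject_id)]
}

#' Write and read devaluation tables
#'
#' Response counts go to a per-block CSV (`subject_id`, `block`,
#' `valued_responses`, `devalued_responses`); ratings go to a sidecar
#' CSV (`subject_id`, `token`, `phase` in pre/post, `rating`).
#'
#' @param devals Named list of [deval_session()]s (names = subject ids).
#' @param counts_path,ratings_path CSV paths.
#' @return `write_deval_table` returns `counts_path`;
#'   `read_deval_table` a named list of [deval_session()]s.
#' @export
write_deval_table <- function(devals, counts_path, ratings_path) {
  counts <- do.call(rbind, lapply(names(devals), function(id)
    cbind(subject_id = id, devals[[id]]$blocks)))
  ratings <- do.call(rbind, lapply(names(devals), function(id) {
    d <- devals[[id]]
    rows <- list()
    for (phase in c("pre", "post")) {
      r <- d[[paste0("rating_", phase)]]
      if (!is.null(r))
        rows[[phase]] <- data.frame(subject_id = id, token = names(r),
                                    phase = phase, rating = unname(r))
    }
    do.call(rbind, rows)
  }))
  write_versioned_csv(counts, counts_path, "deval_counts")
  if (!is.null(ratings))
    write_versioned_csv(ratings, ratings_path, "deval_ratings")
  invisible(counts_path)
}

#' @rdname write_deval_table
#' @export
read_deval_table <- function(counts_path, ratings_path = NULL) {
  counts <- read_versioned_csv(counts_path, c("subject_id", "block",
                                              "valued_responses",
                                              "devalued_responses"))
  ratings <- if (!is.null(ratings_path) && file.exists(ratings_path))
    read_versioned_csv(ratings_path, c("subject_id", "token", "phase",
                                       "rating")) else NULL
  ids <- unique(counts$subject_id)
  out <- lapply(ids, function(id) {
    blocks <- counts[counts$subject_id == id,
                     c("block", "valued_responses", "devalued_responses")]
    blocks <- blocks[order(blocks$block), ]
    rownames(blocks) <- NULL
    pre <- post <- NULL
    if (!is.null(ratings)) {
      r <- ratings[ratings$subject_id == id, ]
      if (nrow(r)) {
        pre <- setNames(r$rating[r$phase == "pre"], r$token[r$phase == "pre"])
        post <- setNames(r$rating[r$phase == "post"], r$token[r$phase == "post"])
        if (!length(pre)) pre <- NULL
        if (!length(post)) post <- NULL
      }
    }
    deval_session(blocks, rating_pre = pre, rating_post = post)
  })
  setNames(out, ids)
}

#' Round-trip task configurations through JSON
#'
#' @param config A [prl_task()].
#' @param path JSON path.
#' @return `write_task_config` returns the path; `read_task_config` the
#'   reconstructed `"prl_task"`, identical to the one written.
#' @export
write_task_config <- function(config, path) {
  stopifnot(inherits(config, "prl_task"))
  payload <- list(
    schema = "prlewa task_config v1",
    advance_on_truncation = config$advance_on_truncation,
    stages = lapply(config$stages, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$schema, "prlewa task_config v1"))
    stopf("%s: unrecognized task config schema", basename(path))
  stages <- lapply(payload$stages, function(s)
    stage_spec(s$stage_label, s$target_option, s$p_reward_target,
               s$p_reward_nontarget, win_credits = s$win_credits,
               win_probs = s$win_probs,
               criterion_consecutive = s$criterion_consecutive,
               max_trials = s$max_trials))
  new_prl_task(stages, payload$advance_on_truncation)
}

#' Round-trip model parameters through JSON
#'
#' Flat key-value parameter files: model name, parameter values, payoff
#' coding.
#'
#' @param params [ewa_params()] or [rp_params()].
#' @param path JSON path.
#' @param coding Optional payoff coding recorded with the parameters.
#' @return `write_params` returns the path; `read_params` the parameter
#'   object (with the coding as attribute `"coding"` when recorded).
#' @export
write_params <- function(params, path, coding = NULL) {
  payload <- list(schema = "prlewa params v1", model = model_name(params),
                  parameters = unclass(params))
  if (!is.null(coding)) payload$coding <- coding
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "prlewa params v1"))
    stopf("%s: unrecognized parameter file schema", basename(path))
  p <- payload$parameters
  out <- switch(payload$model,
                ewa = ewa_params(p$phi, p$rho, p$beta),
                rp = rp_params(p$a_rew, p$a_pun, p$beta),
                stopf("unknown model '%s'", payload$model))
  if (!is.null(payload$coding)) attr(out, "coding") <- payload$coding
  out
}

#' Write a cohort to a directory of interchange files
#'
#' Emits the trial table, devaluation counts and ratings CSVs, the
#' ground-truth subject table, and a JSON manifest recording the seed
#' and a fingerprint of the generating spec, enabling exact re-runs.
#'
#' @param cohort A `"prl_cohort"`.
#' @param dir Output directory (created if needed).
#' @return The directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "prl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_table(cohort$sessions, file.path(dir, "trials.csv"))
  write_deval_table(cohort$devals, file.path(dir, "deval_counts.csv"),
                    file.path(dir, "deval_ratings.csv"))
  write_versioned_csv(cohort$subjects, file.path(dir, "subjects.csv"),
                      "subjects")
  groups <- lapply(cohort$spec$groups, function(g)
    list(label = g$label, n = g$n, p_impaired = g$p_impaired,
         params_intact = unclass(g$params_intact),
         params_impaired = unclass(g$params_impaired)))
  manifest <- list(schema = "prlewa cohort_manifest v1",
                   seed = cohort$seed,
                   spec_fingerprint = spec_fingerprint(cohort$spec),
                   groups = groups)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Stable content fingerprint of a spec (hex-coded 32-bit rolling hash
# over its deparsed form); identifies re-runs, not a cryptographic hash.
spec_fingerprint <- function(spec) {
  bytes <- utf8ToInt(paste(deparse(unclass(spec)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
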