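#' Z-score a feature matrix
#'
#' Columns are centred and scaled to unit sample standard deviation
#' (the `n - 1` denominator); this convention is fixed so cluster
#' solutions are reproducible across tools.
#'
#' @param x Numeric matrix or data frame, subjects in rows (>= 2).
#' @return Numeric matrix with column means 0 and sample SDs 1.
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("features must be numeric")
  if (nrow(x) < 2L) stopf("need at least 2 subjects to standardize")
  if (anyNA(x)) stopf("features contain missing values")
  sds <- apply(x, 2L, sd)
  zero <- which(sds == 0)
  if (length(zero))
    stopf("zero-variance feature column(s): %s",
          paste(colnames(x)[zero] %||% zero, collapse = ", "))
  scale(x)[, , drop = FALSE]
}

#' Ward hierarchical clustering on squared Euclidean distance
#'
#' Agglomerative Ward's-method linkage computed on squared Euclidean
#' distances (the classical SPSS convention: `hclust(d^2,
#' method = "ward.D")`), cut at `k` clusters. Given the same input
#' order the solution is deterministic; merge ties are broken by
#' `hclust`'s lowest-index rule.
#'
#' @param x Numeric feature matrix (usually [zscore_features()] output).
#' @param k Number of clusters.
#' @return Integer cluster labels (1..k), in input row order.
#' @export
ward_cluster <- function(x, k = 2L) {
  x <- as.matrix(x)
  k <- assert_count(k, "k")
  if (nrow(x) < k) stopf("need at least k = %d rows, have %d", k, nrow(x))
  hc <- hclust(dist(x)^2, method = "ward.D")
  unname(cutree(hc, k = k))
}

#' Classify a cohort into intact vs impaired goal-directed action
#'
#' Reproduces the subgrouping logic for devaluation performance:
#' z-score the preference ratio (response bias) and the valued-action
#' response rate, Ward-cluster the pooled cohort into two groups, and
#' label the cluster with the higher mean bias "intact". The empirical
#' boundary interval (maximum impaired bias, minimum intact bias) is
#' reported; subjects with undefined bias (no responses) are excluded
#' from clustering and listed in the result.
#'
#' @param metrics Data frame with columns `subject_id`, `bias`,
#'   `valued_rate` (e.g. from [cohort_summary()]); other columns are
#'   carried through.
#' @return Object of class `"gda_classification"`: `labels` (the input
#'   rows plus a `gda_label` factor), `boundary` (`c(low, high)`),
#'   `excluded` (subject ids with undefined bias), `cluster_means`.
#' @export
classify_goal_directed <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("subject_id", "bias", "valued_rate") %in% names(metrics)))
  usable <- !is.na(metrics$bias) & !is.na(metrics$valued_rate)
  excluded <- metrics$subject_id[!usable]
  m <- metrics[usable, , drop = FALSE]
  if (nrow(m) < 2L) stopf("need at least 2 subjects with defined bias")
  z <- zscore_features(m[, c("bias", "valued_rate")])
  cl <- ward_cluster(z, k = 2L)
  means <- tapply(m$bias, cl, mean)
  intact_cluster <- as.integer(names(means)[which.max(means)])
  label <- factor(ifelse(cl == intact_cluster, "intact", "impaired"),
                  levels = c("intact", "impaired"))
  m$gda_label <- label
  boundary <- c(low = max(m$bias[label == "impaired"]),
                high = min(m$bias[label == "intact"]))
  structure(list(labels = m, boundary = boundary,
                 excluded = as.character(excluded),
                 cluster_means = c(intact = unname(max(means)),
                                   impaired = unname(min(means)))),
            class = "gda_classification")
}

#' @export
print.gda_classification <- function(x, digits = 3, ...) {
  tab <- table(x$labels$gda_label)
  cat(sprintf("Goal-directed action subgroups: %d intact / %d impaired\n",
              tab["intact"], tab["impaired"]))
  cat(sprintf("bias boundary interval: [%.*f, %.*f]\n",
              digits, x$boundary["low"], digits, x$boundary["high"]))
  if (length(x$excluded))
    cat("excluded (undefined bias):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write subgroup labels to CSV
#'
#' @param classification A `"gda_classification"`.
#' @param path Output CSV path.
#' @export
write_gda_labels <- function(classification, path) {
  df <- classification$labels
  df$boundary_low <- classification$boundary["low"]
  df$boundary_high <- classification$boundary["high"]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
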