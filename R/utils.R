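#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic functions in the package accept an explicit `seed`
#' argument and route it through this helper: the global RNG state is
#' saved, the seed set, the expression evaluated, and the previous state
#' restored, so seeded calls never perturb the caller's random stream.
#' A `NULL` seed evaluates the expression under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1L)
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive independent sub-seeds from the current stream (or a given seed),
# kept below 2^31 so they are valid R integer seeds.
derive_seeds <- function(n, seed = NULL) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("`%s` must be a single number in [%s, %s]", name,
          format(lower), format(upper))
  as.numeric(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      x != as.integer(x))
    stopf("`%s` must be a single integer >= %d", name, lower)
  as.integer(x)
}

assert_choice_index <- function(choice) {
  if (!is.numeric(choice) || any(is.na(choice)) || !all(choice %in% c(0, 1)))
    stopf("`choice` must be an option index 0 or 1")
  as.integer(choice)
}
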