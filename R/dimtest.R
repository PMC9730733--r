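#' Corrected t statistic for repeated cross-validation
#'
#' Paired t statistic on fold-wise accuracy differences whose variance
#' term carries the Nadeau-Bengio overlap correction for k-fold
#' cross-validation:
#' `t = mean(diffs) / (sqrt(1/(r k) + 1/(k - 1)) * sd(diffs))`,
#' with `sd` the sample standard deviation.  The `1/(k-1)` term accounts
#' for the dependence introduced by overlapping training sets; the
#' corrected statistic is always smaller in magnitude than the naive
#' paired t, i.e. the correction only ever makes the test more
#' conservative.
#'
#' With zero-variance differences the statistic degenerates: it is
#' `+Inf` for a positive mean, `-Inf` for a negative mean and `0` when
#' all differences are zero (never NaN).
#'
#' @param diffs numeric vector of `r * k` paired differences.
#' @param r,k repetitions and folds of the CV design (`k >= 2`).
#' @return the corrected t statistic.
#' @examples
#' corrected_t(rep(c(0.01, -0.01), 50), r = 10, k = 10)
#' @export
corrected_t <- function(diffs, r, k) {
  r <- as.integer(r); k <- as.integer(k)
  if (k < 2L) stop_input("`k` must be >= 2")
  if (length(diffs) != r * k) {
    stop_input("`diffs` must have length r * k = ", r * k)
  }
  m <- mean(diffs)
  s <- sd(diffs)
  if (s == 0) {
    return(if (m > 0) Inf else if (m < 0) -Inf else 0)
  }
  m / (sqrt(1 / (r * k) + 1 / (k - 1)) * s)
}

#' One-sided gain test between neighboring dimensions
#'
#' Tests whether adding one embedding dimension improves mean test
#' accuracy: null `mu_{d+1} <= mu_d` against alternative
#' `mu_{d+1} > mu_d`.  The differences `test_acc(d+1) - test_acc(d)`,
#' paired by (repetition, fold), enter [corrected_t()]; the p-value is
#' the upper-tail probability of a Student t distribution with
#' `r k - 1` degrees of freedom at that statistic.
#'
#' Degenerate zero-variance samples are resolved by the limits of the
#' statistic: all differences equal and positive gives p = 0, all equal
#' and non-positive gives p = 1.
#'
#' @param acc_low,acc_high `accuracy_samples` (see [cv_accuracy()]) with
#'   `acc_high$dim == acc_low$dim + 1`, computed under the same
#'   [cv_plan()] (identical partitions — the pairing precondition).
#' @param plan the shared [cv_plan()].
#' @return an object of class `gain_test`: `from_dim`, `t_statistic`,
#'   `p_value`, `df`.
#' @export
gain_pvalue <- function(acc_low, acc_high, plan) {
  stopifnot(inherits(acc_low, "accuracy_samples"),
            inherits(acc_high, "accuracy_samples"),
            inherits(plan, "cv_plan"))
  if (acc_high$dim != acc_low$dim + 1L) {
    stop_input("gain test requires neighboring dimensions (got ",
               acc_low$dim, " and ", acc_high$dim, ")")
  }
  if (acc_low$k != plan$k || acc_low$r != plan$r ||
      acc_high$k != plan$k || acc_high$r != plan$r ||
      acc_low$seed != plan$seed || acc_high$seed != plan$seed) {
    stop_input("accuracy samples do not share the cross-validation plan")
  }
  if (length(acc_low$test_acc) != length(acc_high$test_acc)) {
    stop_input("mismatched sample lengths")
  }
  diffs <- acc_high$test_acc - acc_low$test_acc
  tt <- corrected_t(diffs, plan$r, plan$k)
  df <- plan$r * plan$k - 1L
  p <- if (sd(diffs) == 0) {
    if (mean(diffs) > 0) 0 else 1
  } else {
    pt(tt, df = df, lower.tail = FALSE)
  }
  structure(list(from_dim = acc_low$dim, t_statistic = tt, p_value = p,
                 df = df),
            class = "gain_test")
}

#' Holm-Bonferroni step-down selection
#'
#' Step-down multiple-testing correction over the `m` neighboring-dimension
#' tests: p-values are ranked ascending and the r-th smallest is compared
#' to `alpha / (m - r + 1)`; at the first comparison that fails, that
#' hypothesis and all larger p-values are declared non-significant.  Holm
#' rejections are always a superset of plain Bonferroni (`alpha / m`)
#' rejections, i.e. the procedure is uniformly more powerful at the same
#' family-wise error rate.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise significance level (default 0.05).
#' @return a logical vector (significant gain per test) in the original
#'   order, with the per-test Holm thresholds attached as attribute
#'   `"threshold"`.
#' @examples
#' holm_select(c(0.001, 0.2, 0.03), alpha = 0.05)
#' @export
holm_select <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m < 1L) stop_input("need at least one p-value")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must lie in (0, 1)")
  ord <- order(p_values)
  thresholds_sorted <- alpha / (m - seq_len(m) + 1)
  pass <- p_values[ord] < thresholds_sorted
  # step-down stopping rule: everything at or after the first failure
  # (in p-order) is non-significant
  sig_sorted <- cumprod(pass) > 0
  significant <- logical(m)
  significant[ord] <- sig_sorted
  thresholds <- numeric(m)
  thresholds[ord] <- thresholds_sorted
  attr(significant, "threshold") <- thresholds
  significant
}

#' Test configuration for dimension selection
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param max_dim_tested number of neighboring-dimension tests `m`: gains
#'   `d -> d+1` are tested for `d = 1..m`, so embeddings are fitted for
#'   dimensions `1..m+1`.
#' @return an object of class `test_config`.
#' @export
test_config <- function(alpha = 0.05, max_dim_tested = 5L) {
  max_dim_tested <- as.integer(max_dim_tested)
  if (max_dim_tested < 1L) stop_input("`max_dim_tested` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must lie in (0, 1)")
  structure(list(alpha = alpha, max_dim_tested = max_dim_tested),
            class = "test_config")
}

#' Estimate the perceptual dimensionality of a triplet dataset
#'
#' The full selection procedure:
#' (a) fit and cross-validate embeddings for dimensions `1..m+1` on shared
#' partitions, collecting `r k` test-accuracy samples per dimension;
#' (b) test each neighboring pair `d -> d+1` for a significant accuracy
#' gain with the corrected one-sided paired t-test;
#' (c) apply the Holm-Bonferroni step-down correction across the `m`
#' tests;
#' (d) scanning upward from d = 1, return the smallest `d` whose gain test
#' is non-significant; if every gain is significant, report "at least
#' m+1" dimensions.
#'
#' A significant gain occurring beyond the first non-significant one does
#' not change the selection (the procedure returns the lowest
#' gain-providing dimensionality) but is recorded as a warning in the
#' result.
#'
#' @param data a [triplet_dataset()].
#' @param config a [test_config()].
#' @param plan a [cv_plan()].
#' @param embed an [embed_config()].
#' @param warm_start logical; warm-start each dimension's fits from the
#'   next-lower dimension's solution (default TRUE inside the scan).
#' @return an object of class `dimension_estimate`: `selected_dim`
#'   (integer), `at_least` (TRUE when every gain was significant, meaning
#'   "at least m+1"), `samples` (list of `accuracy_samples` for dims
#'   1..m+1), `tests` (data frame with from_dim, t, p, df,
#'   holm_threshold, significant), `warnings`, plus the echoed configs.
#' @examples
#' \donttest{
#' world <- simulate_world(n = 12, d = 1, noise = "low", seed = 7)
#' sim <- generate_dataset(simulation_design(12, 1, lambda = 8), world,
#'                         seed = 7)
#' est <- estimate_dimension(sim$data, test_config(max_dim_tested = 2),
#'                           cv_plan(k = 5, r = 2, seed = 1),
#'                           embed_config(n_restarts = 3))
#' est$selected_dim
#' }
#' @export
estimate_dimension <- function(data, config = test_config(),
                               plan = cv_plan(), embed = embed_config(),
                               warm_start = TRUE) {
  if (!inherits(data, "triplet_dataset")) data <- triplet_dataset(data)
  stopifnot(inherits(config, "test_config"))
  m_tests <- config$max_dim_tested
  dims <- seq_len(m_tests + 1L)
  if (n_triplets(data) < plan$k) {
    stop_input("dataset of ", n_triplets(data), " triplets cannot support ",
               plan$k, "-fold cross-validation; the rule of thumb ",
               "recommends at least 2*d*n*log2(n) triplets (",
               rule_of_thumb_budget(data$n_stimuli, m_tests + 1L),
               " at dimension ", m_tests + 1L, ")")
  }
  samples <- cv_scan(data, dims, plan, embed, warm_start = warm_start)
  tests <- lapply(seq_len(m_tests), function(d) {
    gain_pvalue(samples[[d]], samples[[d + 1L]], plan)
  })
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  significant <- holm_select(p, config$alpha)
  thresholds <- attr(significant, "threshold")
  first_ns <- which(!significant)
  at_least <- length(first_ns) == 0L
  selected <- if (at_least) m_tests + 1L else first_ns[1L]
  warnings <- character(0)
  if (!at_least && any(significant[seq_along(significant) > selected])) {
    later <- which(significant & seq_along(significant) > selected)
    warnings <- paste0(
      "significant accuracy gain at ", paste(later, collapse = ", "),
      " -> ", paste(later + 1L, collapse = ", "),
      " beyond the selected dimension ", selected,
      "; selection keeps the lowest non-significant gain")
  }
  test_table <- data.frame(
    from_dim = vapply(tests, `[[`, integer(1), "from_dim"),
    t_statistic = vapply(tests, `[[`, numeric(1), "t_statistic"),
    p_value = p,
    df = vapply(tests, `[[`, integer(1), "df"),
    holm_threshold = thresholds,
    significant = as.logical(significant))
  structure(list(selected_dim = as.integer(selected), at_least = at_least,
                 samples = samples, tests = test_table,
                 warnings = warnings, test_config = config, plan = plan,
                 embed_config = embed),
            class = "dimension_estimate")
}

#' @export
print.dimension_estimate <- function(x, ...) {
  cat("Dimensionality estimate from triplet accuracy gains\n")
  acc <- vapply(x$samples, function(s) mean(s$test_acc), numeric(1))
  tr <- vapply(x$samples, function(s) mean(s$train_acc), numeric(1))
  dims <- vapply(x$samples, `[[`, integer(1), "dim")
  cat("  mean accuracy by dimension:\n")
  print(data.frame(dim = dims, train = round(tr, 4), test = round(acc, 4)),
        row.names = FALSE)
  cat("  gain tests (corrected paired t, Holm step-down):\n")
  print(transform(x$tests, t_statistic = round(t_statistic, 3),
                  p_value = signif(p_value, 3),
                  holm_threshold = signif(holm_threshold, 3)),
        row.names = FALSE)
  if (x$at_least) {
    cat("  selected: at least", x$selected_dim, "dimensions\n")
  } else {
    cat("  selected:", x$selected_dim, "dimension(s)\n")
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
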