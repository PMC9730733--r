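#' Data-quality diagnostics
#'
#' Inspects a finished run for the two failure modes that make a
#' dimension estimate a lower bound rather than the truth:
#'
#' * `HIGH_NOISE` — the maximum mean test accuracy across the tested
#'   dimensions is below `acc_threshold` (default 0.7).  Low-noise
#'   settings typically reach about 0.9; accuracies below 0.7 indicate
#'   substantial judgment noise and an increased risk of underestimation.
#' * `INSUFFICIENT_DATA` — the train/test accuracy gap at the selected
#'   dimension exceeds `gap_threshold` (default 0.1), or the dataset is
#'   smaller than the `2 d n log2(n)` rule of thumb at some tested
#'   dimension.
#'
#' Each warning record carries the numbers that triggered it.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param acc_threshold critical maximum test accuracy (default 0.7).
#' @param gap_threshold critical train minus test gap (default 0.1).
#' @return a list of warning records (`code`, `message`, `value`).
#' @export
diagnose <- function(report, acc_threshold = 0.7, gap_threshold = 0.1) {
  stopifnot(inherits(report, "run_report"))
  per_dim <- report$per_dimension
  warnings <- list()
  max_test <- max(per_dim$test_mean)
  if (max_test < acc_threshold) {
    warnings <- c(warnings, list(list(
      code = "HIGH_NOISE",
      message = sprintf(
        "maximum mean test accuracy %.3f is below %.2f: high judgment noise, dimension estimate is likely a lower bound",
        max_test, acc_threshold),
      value = max_test)))
  }
  sel <- report$selected_dim
  gap <- per_dim$train_mean[per_dim$dim == sel] -
    per_dim$test_mean[per_dim$dim == sel]
  if (length(gap) == 1L && gap > gap_threshold) {
    warnings <- c(warnings, list(list(
      code = "INSUFFICIENT_DATA",
      message = sprintf(
        "train/test accuracy gap %.3f at the selected dimension exceeds %.2f: consider collecting more triplets",
        gap, gap_threshold),
      value = gap)))
  }
  needs <- vapply(per_dim$dim, function(d) {
    rule_of_thumb_budget(report$n_stimuli, d)
  }, integer(1))
  short <- report$n_triplets < needs
  if (any(short)) {
    d_short <- per_dim$dim[short][1L]
    warnings <- c(warnings, list(list(
      code = "INSUFFICIENT_DATA",
      message = sprintf(
        "dataset of %d triplets is below the 2*d*n*log2(n) recommendation (%d at dimension %d)",
        report$n_triplets, needs[short][1L], d_short),
      value = report$n_triplets)))
  }
  warnings
}

#' Run the full dimension-estimation pipeline
#'
#' End-to-end driver: obtain triplets (from a dataset object, a triplet
#' file, or the synthetic-observer simulator), estimate the
#' dimensionality with [estimate_dimension()], fit the final scale on the
#' complete dataset at the selected dimension, and attach data-quality
#' diagnostics.  The returned report echoes the complete configuration,
#' so re-running with the echoed settings reproduces it bit for bit.
#'
#' @param triplets a [triplet_dataset()], or `NULL`.
#' @param file path of a triplet file (used when `triplets` is `NULL`).
#' @param sim a list with elements `n`, `d`, `lambda`, `noise`: simulate
#'   the dataset instead of reading one.
#' @param max_dim number of neighboring-dimension tests (dimensions
#'   `1..max_dim + 1` are fitted).
#' @param alpha family-wise significance level.
#' @param k,r cross-validation folds and repetitions.
#' @param n_restarts random restarts per embedding fit.
#' @param seed master seed for folds, restarts and (if used) simulation.
#' @param acc_threshold,gap_threshold diagnostic thresholds, see
#'   [diagnose()].
#' @param fit_final fit the final full-data scale at the selected
#'   dimension (default TRUE).
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(triplets = NULL, file = NULL, sim = NULL,
                         max_dim = 5L, alpha = 0.05, k = 10L, r = 10L,
                         n_restarts = 10L, seed = 1L,
                         acc_threshold = 0.7, gap_threshold = 0.1,
                         fit_final = TRUE) {
  noise_ceiling_est <- NULL
  source_desc <- NULL
  if (!is.null(sim)) {
    stopifnot(all(c("n", "d", "lambda", "noise") %in% names(sim)))
    world <- simulate_world(sim$n, sim$d, noise = sim$noise, seed = seed)
    gen <- generate_dataset(
      simulation_design(sim$n, sim$d, lambda = sim$lambda), world)
    triplets <- gen$data
    noise_ceiling_est <- gen$noise_ceiling
    source_desc <- sprintf("simulated (n=%d, d=%d, lambda=%g, noise=%s)",
                           sim$n, sim$d, sim$lambda, sim$noise)
  } else if (is.null(triplets)) {
    if (is.null(file)) stop_input("provide `triplets`, `file` or `sim`")
    triplets <- read_triplets(file)
    source_desc <- file
  } else {
    if (!inherits(triplets, "triplet_dataset")) {
      triplets <- triplet_dataset(triplets)
    }
    source_desc <- "in-memory dataset"
  }
  plan <- cv_plan(k = k, r = r, seed = seed)
  embed <- embed_config(n_restarts = n_restarts)
  est <- estimate_dimension(triplets, test_config(alpha, max_dim), plan,
                            embed)
  per_dim <- data.frame(
    dim = vapply(est$samples, `[[`, integer(1), "dim"),
    train_mean = vapply(est$samples, function(s) mean(s$train_acc),
                        numeric(1)),
    train_sd = vapply(est$samples, function(s) sd(s$train_acc), numeric(1)),
    test_mean = vapply(est$samples, function(s) mean(s$test_acc),
                       numeric(1)),
    test_sd = vapply(est$samples, function(s) sd(s$test_acc), numeric(1)))
  final <- NULL
  if (fit_final) {
    final <- final_scale(triplets, est$selected_dim,
                         embed_config(n_restarts = n_restarts,
                                      seed = child_seed(seed, 999L)))
  }
  report <- structure(list(
    config = list(source = source_desc, sim = sim, max_dim = max_dim,
                  alpha = alpha, k = k, r = r, n_restarts = n_restarts,
                  seed = seed, acc_threshold = acc_threshold,
                  gap_threshold = gap_threshold),
    n_stimuli = triplets$n_stimuli,
    n_triplets = n_triplets(triplets),
    per_dimension = per_dim,
    tests = est$tests,
    selected_dim = est$selected_dim,
    at_least = est$at_least,
    selection_warnings = est$warnings,
    noise_ceiling = noise_ceiling_est,
    final_scale = if (is.null(final)) NULL else unclass(final$scale),
    final_stress = if (is.null(final)) NULL else final$stress),
    class = "run_report")
  report$diagnostics <- diagnose(report, acc_threshold, gap_threshold)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Triplet dimensionality report\n")
  cat("  data:", x$config$source, "-", x$n_triplets, "triplets over",
      x$n_stimuli, "stimuli\n")
  if (!is.null(x$noise_ceiling)) {
    cat(sprintf("  noise ceiling: %.4f\n", x$noise_ceiling))
  }
  cat("  accuracy by dimension:\n")
  print(transform(x$per_dimension,
                  train_mean = round(train_mean, 4),
                  train_sd = round(train_sd, 4),
                  test_mean = round(test_mean, 4),
                  test_sd = round(test_sd, 4)), row.names = FALSE)
  cat("  gain tests:\n")
  print(transform(x$tests, t_statistic = round(t_statistic, 3),
                  p_value = signif(p_value, 3),
                  holm_threshold = signif(holm_threshold, 3)),
        row.names = FALSE)
  if (x$at_least) {
    cat("  selected dimension: at least", x$selected_dim, "\n")
  } else {
    cat("  selected dimension:", x$selected_dim, "\n")
  }
  for (w in x$selection_warnings) cat("  note:", w, "\n")
  if (length(x$diagnostics)) {
    for (w in x$diagnostics) cat("  WARNING [", w$code, "] ", w$message,
                                 "\n", sep = "")
  } else {
    cat("  diagnostics: clean\n")
  }
  invisible(x)
}

#' Read and write run reports
#'
#' Reports serialize to JSON (numbers at full precision).  Reading
#' restores the `run_report` class and its data-frame members so that a
#' written report round-trips through the reader.
#'
#' @param report a `run_report`.
#' @param path file path.
#' @return [write_report()] returns `path` invisibly; [read_report()]
#'   returns a `run_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$final_scale)) x$final_scale <- as.matrix(x$final_scale)
  x$selected_dim <- as.integer(x$selected_dim)
  if (!is.null(x$diagnostics) && length(x$diagnostics) == 0L) {
    x$diagnostics <- list()
  }
  structure(x, class = "run_report")
}
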