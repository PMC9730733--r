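#' Soft ordinal embedding stress
#'
#' The squared-hinge stress of a scale on a triplet dataset: each triplet
#' (anchor, near, far) contributes
#' `max(0, dist(near, anchor) - dist(anchor, far) + 1)^2`.
#' The "+1" margin forbids the trivial all-zero configuration; a triplet
#' satisfied by at least a unit margin contributes nothing.  Zero stress
#' therefore implies triplet accuracy 1 on the same data.  Because of the
#' margin the stress is invariant under rigid motions of the scale but,
#' unlike accuracy, not under rescaling.
#'
#' @param scale a [perceptual_scale()].
#' @param data a [triplet_dataset()].
#' @return a non-negative number ([soe_stress()]), or the n x d gradient
#'   matrix ([soe_stress_gradient()]).
#' @examples
#' s <- perceptual_scale(c(0, 0.5, 1))
#' soe_stress(s, triplet_dataset(c(2, 1, 3)))  # (0.5 - 0.5 + 1)^2 = 1
#' @export
soe_stress <- function(scale, data) {
  if (!inherits(data, "triplet_dataset")) data <- triplet_dataset(data)
  check_indices(scale, data)
  soe_stress_cpp(unclass(scale), data$triplets - 1L)
}

#' @rdname soe_stress
#' @details The gradient follows the chain rule through the two Euclidean
#'   distances of each active triplet; at the hinge boundary the
#'   subgradient 0 is used, and an exactly zero distance contributes a zero
#'   gradient direction rather than NaN.
#' @export
soe_stress_gradient <- function(scale, data) {
  if (!inherits(data, "triplet_dataset")) data <- triplet_dataset(data)
  check_indices(scale, data)
  soe_gradient_cpp(unclass(scale), data$triplets - 1L)
}

#' Embedding configuration
#'
#' Settings for [fit_embedding()].  The optimizer is BFGS
#' (`stats::optim`), restarted from `n_restarts` independent random
#' initializations; the restart with minimal final stress wins (first
#' restart on ties, for determinism).  Restart seeds are derived as
#' `seed + restart index`, so individual restarts are reproducible in
#' isolation.
#'
#' @param dim embedding dimension (>= 1); may be `NULL` here and supplied
#'   by the caller that performs the fit (e.g. the dimension scan).
#' @param n_restarts number of random initializations (default 10).
#' @param max_iterations BFGS iteration cap per restart.
#' @param abstol,reltol convergence tolerances handed to `stats::optim`;
#'   `abstol` terminates zero-stress (perfectly fit) instances exactly.
#' @param init_spread standard deviation of the i.i.d. normal initial
#'   coordinates (default 1, matching the simulator's ground-truth prior).
#' @param seed master seed for the restarts, or `NULL` for the current RNG
#'   stream.
#' @return an object of class `embed_config`.
#' @export
embed_config <- function(dim = NULL, n_restarts = 10L, max_iterations = 500L,
                         abstol = 1e-12, reltol = 1e-10, init_spread = 1,
                         seed = NULL) {
  if (!is.null(dim)) {
    dim <- as.integer(dim)
    if (dim < 1L) stop_input("`dim` must be >= 1")
  }
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop_input("`n_restarts` must be >= 1")
  if (init_spread <= 0) stop_input("`init_spread` must be positive")
  structure(list(dim = dim, n_restarts = n_restarts,
                 max_iterations = as.integer(max_iterations),
                 abstol = abstol, reltol = reltol,
                 init_spread = init_spread,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "embed_config")
}

# One BFGS run from given initial coordinates; returns list(scale, stress,
# converged) with stress = Inf marking a failed (non-finite) run.
soe_optimize_once <- function(x0, tmat0, n, d, config) {
  fn <- function(par) soe_stress_cpp(matrix(par, n, d), tmat0)
  gr <- function(par) as.vector(soe_gradient_cpp(matrix(par, n, d), tmat0))
  fit <- tryCatch(
    optim(as.vector(x0), fn, gr, method = "BFGS",
          control = list(maxit = config$max_iterations,
                         abstol = config$abstol, reltol = config$reltol)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    return(list(scale = NULL, stress = Inf, converged = FALSE))
  }
  list(scale = perceptual_scale(matrix(fit$par, n, d)),
       stress = fit$value, converged = fit$convergence == 0L)
}

#' Fit a soft ordinal embedding
#'
#' Minimizes the soft ordinal embedding stress (see [soe_stress()]) over
#' stimulus coordinates with BFGS, restarting from `n_restarts` random
#' normal initializations and returning the scale with minimal stress.
#' Restarts whose optimization produces a non-finite stress are marked
#' failed and excluded; if every restart fails, an error is raised.
#'
#' @param data a [triplet_dataset()] with at least one triplet.
#' @param config an [embed_config()]; `config$dim` must be set unless
#'   `dim` is given.
#' @param dim convenience override for the embedding dimension.
#' @param warm_start optional [perceptual_scale()] with at most
#'   `dim` columns used as one additional initial condition, padded with
#'   zero columns.  The dimension scan warm-starts each fit from the
#'   next-lower dimension's solution, which guarantees that the attained
#'   stress is non-increasing in the dimension; standalone fits default to
#'   purely random restarts.
#' @return an object of class `embed_result`: list with elements `scale`,
#'   `stress`, `restart_stresses`, `converged` (one flag per restart) and
#'   `dim`.
#' @examples
#' td <- triplet_dataset(rbind(c(2, 1, 3), c(1, 2, 3)))
#' fit <- fit_embedding(td, dim = 1, config = embed_config(seed = 1))
#' fit$stress
#' @export
fit_embedding <- function(data, config = embed_config(), dim = NULL,
                          warm_start = NULL) {
  if (!inherits(data, "triplet_dataset")) data <- triplet_dataset(data)
  if (n_triplets(data) < 1L) stop_input("cannot fit an empty dataset")
  stopifnot(inherits(config, "embed_config"))
  if (!is.null(dim)) config$dim <- as.integer(dim)
  d <- config$dim
  if (is.null(d)) stop_input("embedding dimension not set")
  n <- data$n_stimuli
  tmat0 <- data$triplets - 1L
  inits <- vector("list", config$n_restarts)
  for (s in seq_len(config$n_restarts)) {
    restart_seed <- if (is.null(config$seed)) NULL else config$seed + s
    inits[[s]] <- with_seed(restart_seed,
                            matrix(rnorm(n * d, sd = config$init_spread),
                                   n, d))
  }
  if (!is.null(warm_start)) {
    if (ncol(warm_start) > d) {
      stop_input("warm start has more dimensions than the target fit")
    }
    pad <- matrix(0, n, d - ncol(warm_start))
    inits <- c(inits, list(cbind(unclass(warm_start), pad)))
  }
  stresses <- rep(Inf, length(inits))
  converged <- rep(FALSE, length(inits))
  best <- NULL
  for (s in seq_along(inits)) {
    run <- soe_optimize_once(inits[[s]], tmat0, n, d, config)
    stresses[s] <- run$stress
    converged[s] <- run$converged
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  if (is.null(best$scale)) {
    stop_input("all ", length(inits), " embedding restarts failed")
  }
  structure(list(scale = best$scale, stress = best$stress,
                 restart_stresses = stresses, converged = converged,
                 dim = d),
            class = "embed_result")
}

#' @export
print.embed_result <- function(x, ...) {
  cat("Soft ordinal embedding fit\n")
  cat("  dimension:", x$dim, " stimuli:", nrow(x$scale), "\n")
  cat(sprintf("  stress: %.6g (best of %d restarts, %d converged)\n",
              x$stress, length(x$restart_stresses), sum(x$converged)))
  invisible(x)
}
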