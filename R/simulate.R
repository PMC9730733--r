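#' Trial-budget helpers
#'
#' [triplet_budget()] is the simulator's dataset size:
#' `floor(lambda * d * n * ln(n))` triplets.  The scaling factor lambda
#' makes trial numbers comparable across ground-truth scales; the named
#' levels are minimal (lambda = 2), moderate (4) and generous (8).
#' Truncation (floor) matches the published example counts.
#'
#' [rule_of_thumb_budget()] is the minimum-data heuristic
#' `ceil(2 * d * n * log2(n))` used by the diagnostics to warn on
#' undersized datasets.
#'
#' @param n number of stimuli (>= 3).
#' @param d hypothesized dimension (>= 1).
#' @param lambda_factor positive scaling factor.
#' @return an integer trial count.
#' @examples
#' triplet_budget(60, 3, 4)       # 2947
#' rule_of_thumb_budget(8, 1)     # 48
#' @export
triplet_budget <- function(n, d, lambda_factor) {
  if (n < 3) stop_input("`n` must be >= 3")
  if (d < 1) stop_input("`d` must be >= 1")
  if (lambda_factor <= 0) stop_input("`lambda_factor` must be positive")
  as.integer(floor(lambda_factor * d * n * log(n)))
}

#' @rdname triplet_budget
#' @export
rule_of_thumb_budget <- function(n, d) {
  if (n < 3) stop_input("`n` must be >= 3")
  if (d < 1) stop_input("`d` must be >= 1")
  as.integer(ceiling(2 * d * n * log2(n)))
}

#' Triplet cost of the ordinal-capacity alternative
#'
#' Determining the dimension via ordinal capacity requires sorting all
#' pairwise distances, on the order of `n^2 log n` triplets, whereas
#' estimating a d-dimensional scale needs on the order of `d n log n`.
#' This returns their ratio — the extra experimental effort factor of the
#' capacity route (about 20x for n = 40 stimuli in two dimensions).
#'
#' @param n number of stimuli.
#' @param d scale dimension.
#' @return the ratio of the two asymptotic triplet costs.
#' @export
ordinal_capacity_ratio <- function(n, d) {
  (n^2 * log(n)) / (d * n * log(n))
}

#' Sample a normal ground-truth scale
#'
#' Coordinates drawn i.i.d. from the standard multivariate normal
#' (zero mean, identity covariance) — the simulator's stock of
#' ground-truth scales; reproducible under `seed`.
#'
#' @param n number of stimuli (>= 3, so that at least one triplet exists).
#' @param d dimension (>= 1).
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return a [perceptual_scale()].
#' @export
sample_normal_scale <- function(n, d, seed = NULL) {
  if (n < 3) stop_input("`n` must be >= 3 (no triplet exists otherwise)")
  if (d < 1) stop_input("`d` must be >= 1")
  coords <- with_seed(seed, matrix(rnorm(n * d), n, d))
  perceptual_scale(coords)
}

#' Spread of the pairwise distances of a scale
#'
#' The sample standard deviation of all `n (n - 1) / 2` pairwise
#' Euclidean distances.  The simulator rescales its nominal noise levels
#' by this statistic so that signal-to-noise ratios are comparable across
#' scales of different size and dimension; the spread is homogeneous of
#' degree one (scaling the coordinates by c scales the spread by c), so
#' judgment-flip probabilities are invariant to the scale's units.
#'
#' @param scale a [perceptual_scale()] with at least 3 stimuli in
#'   non-degenerate position.
#' @return a positive number.
#' @export
distance_spread <- function(scale) {
  if (nrow(scale) < 2L) stop_input("spread needs at least two stimuli")
  d <- as.vector(dist(unclass(scale)))
  if (length(d) < 2L) {
    stop_input("a single pairwise distance has no spread; need n >= 3")
  }
  s <- sd(d)
  if (!is.finite(s) || s <= 0) {
    stop_input("degenerate scale: pairwise distances have zero spread")
  }
  s
}

#' Synthetic observer
#'
#' A ground-truth world bundles the true scale with the judgment-noise
#' model: on each trial the observer compares the two distances to the
#' anchor after adding Gaussian noise `N(0, sigma_effective^2)` to the
#' near distance.  The nominal noise levels low / med / high correspond
#' to sigma = 0.5 / 1.0 / 2.0, rescaled by the spread of the true
#' pairwise distances ([distance_spread()]); `"none"` gives a noise-free
#' deterministic observer.
#'
#' @param scale the true [perceptual_scale()].
#' @param noise one of `"none"`, `"low"`, `"med"`, `"high"`, or a single
#'   non-negative number used as the nominal sigma before rescaling.
#' @param seed integer seed recorded with the world (used by convenience
#'   wrappers; judgment draws consume the caller's RNG stream).
#' @return an object of class `ground_truth_world`: `scale`,
#'   `sigma_level`, `sigma_base`, `sigma_effective`, `spread`, `seed`.
#' @export
ground_truth_world <- function(scale, noise = "med", seed = NULL) {
  bases <- c(none = 0, low = 0.5, med = 1, high = 2)
  if (is.character(noise)) {
    noise <- match.arg(noise, names(bases))
    base <- bases[[noise]]
    level <- noise
  } else {
    base <- as.numeric(noise)
    if (length(base) != 1L || !is.finite(base) || base < 0) {
      stop_input("`noise` must be a level name or a non-negative number")
    }
    level <- "custom"
  }
  spread <- distance_spread(scale)
  structure(list(scale = scale, sigma_level = level, sigma_base = base,
                 sigma_effective = base * spread, spread = spread,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ground_truth_world")
}

#' @rdname ground_truth_world
#' @param n,d stimulus count and true dimension for a freshly sampled
#'   normal scale.  [simulate_world()] draws the scale from its own
#'   seeded stream, so changing the later trial budget never perturbs the
#'   ground truth.
#' @export
simulate_world <- function(n, d, noise = "med", seed = 1L) {
  scale <- sample_normal_scale(n, d, seed = child_seed(seed, 1L))
  ground_truth_world(scale, noise = noise, seed = as.integer(seed))
}

#' @export
print.ground_truth_world <- function(x, ...) {
  cat("Synthetic observer:", nrow(x$scale), "stimuli,",
      ncol(x$scale), "true dimension(s)\n")
  cat(sprintf("  noise %s (sigma = %.3f after spread rescaling by %.3f)\n",
              x$sigma_level, x$sigma_effective, x$spread))
  invisible(x)
}

#' Simulation design
#'
#' @param n stimulus count.
#' @param d ground-truth dimension (sets the trial budget).
#' @param lambda trial-budget scaling factor (2 = minimal, 4 = moderate,
#'   8 = generous).
#' @param n_ceiling number of extra held-out triplets used to estimate the
#'   noise ceiling (default 10000).
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n, d, lambda = 4, n_ceiling = 10000L) {
  budget <- triplet_budget(n, d, lambda)
  if (budget < 1L) stop_input("trial budget must be >= 1")
  structure(list(n = as.integer(n), d = as.integer(d), lambda = lambda,
                 budget = budget, n_ceiling = as.integer(n_ceiling)),
            class = "simulation_design")
}

#' Simulate triplet judgments
#'
#' Judges the question "is stimulus j or k more similar to anchor i?"
#' from the true distances plus fresh Gaussian noise per judgment:
#' the response is `(i, j, k)` if
#' `dist(psi_j, psi_i) + eps <= dist(psi_i, psi_k)` with
#' `eps ~ N(0, sigma_effective^2)`, and `(i, k, j)` otherwise.  The
#' anchor is always the first index; only the near/far orientation is
#' stochastic.  The probability of the ground-truth ordering is
#' `Phi(Delta / sigma)` with `Delta = dist(psi_i, psi_k) - dist(psi_j,
#' psi_i)`.  Draws consume the current RNG stream; seed at the caller.
#'
#' @param world a [ground_truth_world()].
#' @param i,j,k equal-length vectors of distinct stimulus indices.
#' @return a [triplet_dataset()] of `length(i)` judged triplets.
#' @export
simulate_judgment <- function(world, i, j, k) {
  stopifnot(inherits(world, "ground_truth_world"))
  if (!(length(i) == length(j) && length(j) == length(k))) {
    stop_input("`i`, `j`, `k` must have equal length")
  }
  if (any(i == j | i == k | j == k)) {
    stop_input("stimulus indices within a question must be distinct")
  }
  scale <- world$scale
  n <- nrow(scale)
  if (any(c(i, j, k) < 1L) || any(c(i, j, k) > n)) {
    stop_input("stimulus index out of range 1..", n)
  }
  d_near <- row_dist(scale, j, i)
  d_far <- row_dist(scale, i, k)
  eps <- if (world$sigma_effective > 0) {
    rnorm(length(i), 0, world$sigma_effective)
  } else {
    numeric(length(i))
  }
  keep <- d_near + eps <= d_far
  triplet_dataset(cbind(anchor = i,
                        near = ifelse(keep, j, k),
                        far = ifelse(keep, k, j)),
                  n_stimuli = n)
}

# Uniformly sampled ordered distinct index triples (with replacement
# across questions: repeated questions are legitimate and each is judged
# with fresh noise).
sample_questions <- function(n, m) {
  i <- sample.int(n, m, replace = TRUE)
  j <- sample.int(n - 1L, m, replace = TRUE)
  j <- j + (j >= i)                       # j uniform on {1..n} \ {i}
  k <- sample.int(n - 2L, m, replace = TRUE)
  lo <- pmin(i, j); hi <- pmax(i, j)
  k <- k + (k >= lo)
  k <- k + (k >= hi)                      # k uniform on {1..n} \ {i, j}
  cbind(i = i, j = j, k = k)
}

#' Generate a synthetic triplet dataset with its noise-ceiling sample
#'
#' Draws `design$budget` random triplet questions (three distinct
#' stimulus indices each), judges each with [simulate_judgment()], and
#' additionally judges `design$n_ceiling` held-out questions used only to
#' approximate the noise ceiling.  Question sampling and noise draws use
#' independent seeded streams, so the ground truth and the questions do
#' not shift when the budget changes.
#'
#' @param design a [simulation_design()].
#' @param world a [ground_truth_world()] over the same `n` stimuli.
#' @param seed integer seed; defaults to the world's seed.
#' @return a list of class `triplet_sim`: `data` and `ceiling`
#'   ([triplet_dataset()]s), `design`, `world` and `noise_ceiling` (the
#'   accuracy of the true scale on the ceiling sample).
#' @export
generate_dataset <- function(design, world, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(world, "ground_truth_world"))
  if (design$n != nrow(world$scale)) {
    stop_input("design and world disagree on the number of stimuli")
  }
  if (is.null(seed)) seed <- world$seed
  if (is.null(seed)) stop_input("a seed is required (world has none)")
  judge <- function(m, qseed, nseed) {
    q <- with_seed(qseed, sample_questions(design$n, m))
    with_seed(nseed, simulate_judgment(world, q[, 1L], q[, 2L], q[, 3L]))
  }
  data <- judge(design$budget, child_seed(seed, 11L), child_seed(seed, 12L))
  ceiling_data <- judge(design$n_ceiling,
                        child_seed(seed, 13L), child_seed(seed, 14L))
  structure(list(data = data, ceiling = ceiling_data, design = design,
                 world = world,
                 noise_ceiling = noise_ceiling(world, ceiling_data)),
            class = "triplet_sim")
}

#' @export
print.triplet_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated triplets: %d trials (lambda = %g, d = %d, n = %d)\n",
    x$design$budget, x$design$lambda, x$design$d, x$design$n))
  cat(sprintf("  noise %s, noise ceiling %.4f (from %d held-out trials)\n",
              x$world$sigma_level, x$noise_ceiling, x$design$n_ceiling))
  invisible(x)
}

#' Noise ceiling
#'
#' The best possible generalization accuracy: the triplet accuracy of the
#' TRUE scale on a large held-out sample of noisy judgments — the
#' fraction of judgments still consistent with ground truth.  It is 1 for
#' a noise-free observer and approaches 0.5 (coin flipping) as the noise
#' dominates.
#'
#' @param world a [ground_truth_world()].
#' @param ceiling_data a non-empty [triplet_dataset()] of held-out judged
#'   triplets.
#' @return a number in \[0, 1\].
#' @export
noise_ceiling <- function(world, ceiling_data) {
  stopifnot(inherits(world, "ground_truth_world"))
  if (n_triplets(ceiling_data) == 0L) {
    stop_input("empty noise-ceiling sample")
  }
  triplet_accuracy(world$scale, ceiling_data)
}

#' The simulator's validation grid
#'
#' The full factorial design used to validate the procedure on normal
#' ground-truth scales: small (n = 20, d = 1, 2, 3), medium (n = 60,
#' d = 1, 2, 3, 8) and large (n = 100, d = 3, 8) scales, crossed with
#' three noise levels and three trial budgets — 81 conditions in total.
#'
#' @return a data frame with columns `n`, `d`, `noise`, `lambda` and
#'   `budget`, one row per condition.
#' @export
validation_grid <- function() {
  scales <- rbind(
    data.frame(n = 20L, d = c(1L, 2L, 3L)),
    data.frame(n = 60L, d = c(1L, 2L, 3L, 8L)),
    data.frame(n = 100L, d = c(3L, 8L)))
  grid <- merge(merge(scales, data.frame(noise = c("low", "med", "high"))),
                data.frame(lambda = c(2, 4, 8)))
  grid <- grid[order(grid$n, grid$d, grid$noise, grid$lambda), ]
  rownames(grid) <- NULL
  grid$budget <- mapply(triplet_budget, grid$n, grid$d, grid$lambda)
  grid
}
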