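# Construct a vector with exact sample mean and sd.
fix_moments <- function(x, mean_target, sd_target) {
  mean_target + sd_target * (x - mean(x)) / sd(x)
}

test_that("corrected t matches the hand-evaluated formula", {
  expect_equal(corrected_t(rep(c(0.01, -0.01), 50), r = 10, k = 10), 0)
  set.seed(1)
  diffs <- fix_moments(rnorm(100), 0.01, 0.02)
  # 0.01 / (sqrt(1/100 + 1/9) * 0.02)
  expect_equal(corrected_t(diffs, 10, 10),
               0.01 / (sqrt(0.01 + 1 / 9) * 0.02))
  expect_equal(corrected_t(diffs, 10, 10), 1.43674, tolerance = 1e-5)
  expect_error(corrected_t(diffs, 10, 5), "length")
})

test_that("correction shrinks the naive paired t by the exact factor", {
  set.seed(2)
  for (kr in list(c(10, 10), c(5, 5), c(2, 10))) {
    r <- kr[1]; k <- kr[2]
    diffs <- rnorm(r * k, mean = 0.005, sd = 0.03)
    naive <- mean(diffs) / (sd(diffs) / sqrt(r * k))
    factor <- sqrt((1 / (r * k)) / (1 / (r * k) + 1 / (k - 1)))
    expect_equal(corrected_t(diffs, r, k), naive * factor)
    expect_lt(abs(corrected_t(diffs, r, k)), abs(naive))
    # antisymmetry
    expect_equal(corrected_t(-diffs, r, k), -corrected_t(diffs, r, k))
  }
})

make_samples <- function(dim, test_acc, plan) {
  structure(list(dim = dim, test_acc = test_acc,
                 train_acc = pmin(1, test_acc + 0.02),
                 k = plan$k, r = plan$r, seed = plan$seed),
            class = "accuracy_samples")
}

test_that("gain p-values follow the upper tail of t(rk - 1)", {
  plan <- cv_plan(k = 10, r = 10, seed = 1)
  base <- rep(0.8, 100)
  # no difference at all: degenerate sd, no evidence of gain
  g0 <- gain_pvalue(make_samples(1, base, plan),
                    make_samples(2, base, plan), plan)
  expect_equal(g0$p_value, 1)
  # constant positive gain: certain evidence
  g1 <- gain_pvalue(make_samples(1, base, plan),
                    make_samples(2, base + 0.05, plan), plan)
  expect_equal(g1$p_value, 0)
  # t = 0 with positive sd: p = 0.5
  set.seed(3)
  jitter <- fix_moments(rnorm(100), 0, 0.01)
  g2 <- gain_pvalue(make_samples(1, base, plan),
                    make_samples(2, base + jitter, plan), plan)
  expect_equal(g2$p_value, 0.5)
  # hand case: mean 0.01, sd 0.02 -> t = 1.43674, df = 99
  gains <- fix_moments(rnorm(100), 0.01, 0.02)
  g3 <- gain_pvalue(make_samples(1, base, plan),
                    make_samples(2, base + gains, plan), plan)
  expect_equal(g3$df, 99L)
  expect_equal(g3$p_value, pt(0.01 / (sqrt(0.01 + 1 / 9) * 0.02), df = 99,
                              lower.tail = FALSE))
  expect_equal(g3$p_value, 0.0769, tolerance = 1e-3)
  # p monotone decreasing in the t statistic
  bigger <- fix_moments(rnorm(100), 0.02, 0.02)
  g4 <- gain_pvalue(make_samples(1, base, plan),
                    make_samples(2, base + bigger, plan), plan)
  expect_lt(g4$p_value, g3$p_value)
  # contract checks
  expect_error(gain_pvalue(make_samples(1, base, plan),
                           make_samples(3, base, plan), plan),
               "neighboring")
  other <- cv_plan(k = 5, r = 20, seed = 1)
  expect_error(gain_pvalue(make_samples(1, base, plan),
                           make_samples(2, base, plan), other),
               "plan")
})

test_that("Holm step-down ranks, stops at the first failure", {
  sel <- holm_select(c(0.001, 0.2, 0.03), alpha = 0.05)
  expect_equal(as.logical(sel), c(TRUE, FALSE, FALSE))
  expect_equal(attr(sel, "threshold"), c(0.05 / 3, 0.05 / 1, 0.05 / 2))
  # m = 1 reduces to a plain alpha comparison
  expect_true(as.logical(holm_select(0.04, 0.05)))
  expect_false(as.logical(holm_select(0.06, 0.05)))
  # stopping rule: once the smallest p fails its (strictest) threshold,
  # later p-values are blocked even if below their own thresholds
  sel2 <- holm_select(c(0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(as.logical(sel2), c(FALSE, FALSE, FALSE))
  sel3 <- holm_select(c(0.03, 0.04, 0.001), alpha = 0.05)
  expect_equal(as.logical(sel3), c(FALSE, FALSE, TRUE))
  expect_error(holm_select(c(0.5, 1.2)), "0, 1")
})

test_that("Holm rejections contain the Bonferroni rejections", {
  set.seed(4)
  for (rep in 1:50) {
    m <- sample(1:8, 1)
    p <- runif(m)^sample(1:3, 1)  # skew some vectors toward small p
    holm <- as.logical(holm_select(p, 0.05))
    bonf <- p < 0.05 / m
    expect_true(all(holm[bonf]))
  }
})

test_that("dimension selection applies the scan-up stopping rule", {
  # selection logic exercised end-to-end on noise-free 1-D data: no gain
  # beyond dimension 1, so the first test is non-significant -> returns 1
  trip <- agreeing_triples(c(0, 1, 3, 7))
  td <- triplet_dataset(trip[rep(seq_len(nrow(trip)), 2), ])
  est <- estimate_dimension(td, test_config(max_dim_tested = 2),
                            cv_plan(k = 4, r = 2, seed = 9),
                            embed_config(n_restarts = 3))
  expect_equal(est$selected_dim, 1L)
  expect_false(est$at_least)
  expect_false(any(est$tests$significant))
  expect_equal(est$tests$df, rep(7L, 2))
  expect_equal(nrow(est$tests), 2L)
  # selected dimension never has a significant preceding gain test
  expect_true(est$selected_dim == 1L ||
                all(est$tests$significant[seq_len(est$selected_dim - 1)]))
})

test_that("infeasible designs are rejected with the budget rule", {
  td <- triplet_dataset(rbind(c(1, 2, 3), c(2, 1, 3)))
  expect_error(estimate_dimension(td, test_config(max_dim_tested = 1),
                                  cv_plan(k = 10, r = 2, seed = 1)),
               "rule of thumb")
})
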