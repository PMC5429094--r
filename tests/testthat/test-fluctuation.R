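test_that("Lea-Coulson pmf follows the MSS recursion and its invariants", {
  # hand-evaluated recursion: p1 = m*p0/2, p2 = (m/2)(p0/3 + p1/2)
  p <- ld_pmf(1, 2)
  expect_equal(p, c(0.3678794, 0.1839397, 0.1072982), tolerance = 1e-6)
  expect_equal(ld_pmf(0, 3), c(1, 0, 0, 0))
  expect_equal(ld_pmf(1, 0), exp(-1))
  for (m in c(0, 0.3, 1, 5, 10)) {
    p <- ld_pmf(m, 200)
    expect_equal(p[1], exp(-m))
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(cumsum(p) <= 1 + 1e-12))
  }
  # mass converges to 1; residual tail is of order m/n_max
  for (m in c(1, 10)) {
    tail1 <- 1 - sum(ld_pmf(m, 500))
    tail2 <- 1 - sum(ld_pmf(m, 5000))
    expect_lt(tail2, tail1)
    expect_lt(tail2, 2 * m / 5000)
  }
  expect_error(ld_pmf(-1, 5), "non-negative")
  expect_error(ld_pmf(1, -1), "non-negative")
})

test_that("pmf matches an independent compound-Poisson construction", {
  for (m in c(0.5, 2)) {
    expect_equal(ld_pmf(m, 25), oracle_ld_pmf(m, 25), tolerance = 1e-10)
  }
})

test_that("MSS MLE maximizes the likelihood (grid-search oracle)", {
  expect_equal(mss_mle(c(0, 0, 1, 1)), 0.5, tolerance = 1e-3)
  expect_equal(mss_mle(c(0, 0, 1, 1)), oracle_grid_mle(c(0, 0, 1, 1)),
               tolerance = 1e-3)
  set.seed(11)
  for (i in 1:5) {
    counts <- sample(0:20, size = sample(3:8, 1), replace = TRUE)
    if (all(counts == 0)) counts[1] <- 1
    expect_equal(mss_mle(counts), oracle_grid_mle(counts), tolerance = 2e-3,
                 label = paste("counts", paste(counts, collapse = ",")))
  }
})

test_that("MSS MLE boundary behaviour and simulation consistency", {
  expect_identical(mss_mle(c(0, 0, 0, 0)), 0)
  expect_error(mss_mle(numeric(0)), "empty")
  expect_error(mss_mle(c(-1, 2)), "non-negative")
  expect_warning(mss_mle(c(0, 2, 1e6)), "capped")
  suppressWarnings({
    e <- simulate_fluctuation(m = 1, n_cultures = 1e4, seed = 42)
    m_hat <- mss_mle(e)
  })
  expect_lt(abs(m_hat - 1) / 1, 0.05)
})

test_that("mutation rate is m over mean Nt, with optional scaling", {
  e <- fluctuation_experiment(c(0, 5), viable_counts = rep(2e8, 4))
  est <- mutation_rate(e, m_hat = 2)
  expect_equal(est$rate, 1e-8)
  expect_equal(est$m_hat / est$mean_Nt, est$rate)
  est0 <- mutation_rate(e, m_hat = 0)
  expect_equal(est0$rate, 0)
  expect_equal(est0$ci_low, 0)
  expect_gt(est0$ci_high, 0)
  est_s <- mutation_rate(e, m_hat = 1, scaling_factor = 1e7)
  expect_equal(est_s$rate_scaled, est_s$rate * 1e7)
  expect_true(est_s$ci_low <= est_s$rate && est_s$rate <= est_s$ci_high)
})

test_that("Stewart CI matches its closed form and shrinks with culture number", {
  # hand evaluation of exp(ln 1 +/- 1.96 * 1.225 * 1^-0.315 / sqrt(30))
  ci <- ci_95(1, 30)
  expect_equal(ci, exp(c(-1, 1) * qnorm(0.975) * 1.225 / sqrt(30)),
               tolerance = 1e-10)
  w30 <- diff(log(ci_95(2, 30)))
  w60 <- diff(log(ci_95(2, 60)))
  expect_equal(w30 / w60, sqrt(2), tolerance = 1e-10)
  expect_true(ci_95(1, 30)[1] < 1 && 1 < ci_95(1, 30)[2])
})

test_that("profile-likelihood CI brackets the grid-search maximizer", {
  counts <- c(0, 0, 1, 1)
  m_grid <- oracle_grid_mle(counts)
  ci <- ci_95(mss_mle(counts), length(counts), method = "profile",
              counts = counts)
  expect_lt(ci[1], m_grid)
  expect_gt(ci[2], m_grid)
  # profile interval is wider than zero and ordered
  expect_true(ci[1] < ci[2])
})

test_that("rate comparison: identities, degenerate variance, and power", {
  make_est <- function(rep_m, nt = 2e8) {
    e <- suppressWarnings(
      fluctuation_experiment(rep(c(0, 1), 3), rep(nt, 4),
                             replicate = rep(c("a", "b", "c"), each = 2)))
    est <- mutation_rate(e)
    est$replicate_m <- rep_m
    est$rate <- mean(rep_m) / nt
    est
  }
  same <- compare_rates(make_est(c(1, 2, 3)), make_est(c(1, 2, 3)))
  expect_equal(same$p_value, 1)
  expect_equal(same$fold_change, 1)
  dgn <- compare_rates(make_est(c(2, 2, 2)), make_est(c(5, 5, 5)))
  expect_true(is.infinite(dgn$statistic))
  expect_lt(dgn$p_value, 1e-300)
  expect_error(compare_rates(make_est(c(1, 2)), make_est(2)), "replicates")

  # 10-fold true rate difference, 5 biological replicates per side
  reps <- 100
  hits <- logical(reps)
  folds <- numeric(reps)
  for (r in seq_len(reps)) {
    suppressWarnings({
      ea <- simulate_fluctuation(2, n_cultures = 150, seed = 9000 + r,
                                 n_replicates = 5)
      eb <- simulate_fluctuation(0.2, n_cultures = 150, seed = 19000 + r,
                                 n_replicates = 5)
      cmp <- compare_rates(mutation_rate(ea), mutation_rate(eb))
    })
    hits[r] <- cmp$p_value < 0.05
    folds[r] <- cmp$fold_change
  }
  expect_gte(mean(hits), 0.9)
  expect_true(median(folds) > 5 && median(folds) < 20)
})

test_that("density equality check: separable, degenerate, and type-I rate", {
  sep <- density_equality(list(c(1e8, 1.1e8, 0.9e8), c(1e10, 1.05e10, 0.95e10)))
  expect_false(sep$pass)
  flat <- density_equality(list(c(2e8, 2e8), c(2e8, 2e8), c(2e8, 2e8)))
  expect_true(flat$pass)
  expect_error(density_equality(list(c(1, 2))), ">= 2")

  set.seed(303)
  reps <- 1000
  fails <- vapply(seq_len(reps), function(i) {
    g <- replicate(4, rlnorm(5, log(2e8), 0.1), simplify = FALSE)
    !density_equality(g)$pass
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_true(abs(mean(fails) - 0.05) < 2 * se + 1e-9)
})
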