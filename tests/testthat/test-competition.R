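test_that("fluorescence-loss correction divides by 1 - f_loss and clips", {
  expect_equal(correct_fluorescence_loss(0.4, 0), 0.4)
  expect_equal(correct_fluorescence_loss(0.45, 0.1), 0.5)
  expect_warning(out <- correct_fluorescence_loss(0.95, 0.2), "clip")
  expect_equal(out, 1)
  expect_error(correct_fluorescence_loss(0.5, 1), "f_loss")
  expect_error(correct_fluorescence_loss(1.2, 0), "\\[0, 1\\]")
})

test_that("relative fitness: odds-ratio identities", {
  expect_equal(relative_fitness(0.5, 0.5, 3), 1)
  expect_equal(relative_fitness(0.5, 2 / 3, 1), 2)
  expect_equal(relative_fitness(0.5, 2 / 3, 2), sqrt(2))
  expect_equal(relative_fitness(0.5, 2 / 3, 1, reciprocal = TRUE), 0.5)
  expect_error(relative_fitness(0, 0.5, 1), "pseudocount")
  expect_error(relative_fitness(0.5, 1, 1), "pseudocount")
  # group property: W over n rounds equals the geometric composition of
  # per-round W values along any intermediate path
  A <- c(0.3, 0.42, 0.61, 0.8)
  w_total <- relative_fitness(A[1], A[4], n = 3)
  w_steps <- vapply(1:3, function(i) relative_fitness(A[i], A[i + 1], 1),
                    numeric(1))
  expect_equal(w_total, prod(w_steps)^(1 / 3), tolerance = 1e-12)
  # monotone in A_end at fixed A_start, n
  ends <- seq(0.1, 0.9, by = 0.1)
  ws <- vapply(ends, function(e) relative_fitness(0.4, e, 2), numeric(1))
  expect_true(all(diff(ws) > 0))
})

test_that("rounds to fixation inverts the fitness equation", {
  expect_equal(rounds_to_fixation(2, 0.5, 2 / 3), 1)
  expect_equal(rounds_to_fixation(2, 0.5, 0.5 + 1e-16), 0, tolerance = 1e-8)
  # hand arithmetic: ln(99) / ln(3.61)
  expect_equal(rounds_to_fixation(3.61, 0.5, 0.99),
               log(99) / log(3.61), tolerance = 1e-12)
  expect_equal(rounds_to_fixation(3.61, 0.5, 0.99), 3.58, tolerance = 0.01)
  # machine-precision round trip
  n <- rounds_to_fixation(1.7, 0.2, 0.95)
  expect_equal(relative_fitness(0.2, 0.95, n), 1.7, tolerance = 1e-12)
  expect_error(rounds_to_fixation(1, 0.5, 0.9), "never fixes")
  expect_warning(rounds_to_fixation(2, 0.5, 0.3), "negative")
})

test_that("theoretical competition of two Gompertz models", {
  p <- c(y0 = -2, yM = 2, SGR = 0.2, LT = 5)
  same <- theoretical_competition(p, p, 1e4, 1e4, 24)
  expect_equal(same$A_end, same$A_start)
  expect_equal(same$W, 1)
  early <- c(y0 = -2, yM = 2, SGR = 0.2, LT = 0)
  late <- c(y0 = -2, yM = 2, SGR = 0.2, LT = 10)
  res <- theoretical_competition(early, late, 1e4, 1e4, 24)
  expect_gt(res$A_end, res$A_start)
  expect_gt(res$W, 1)
  # brute-force curve-evaluation oracle for the LT in {0, 5} pair
  lag5 <- c(y0 = -2, yM = 2, SGR = 0.2, LT = 5)
  out <- theoretical_competition(early, lag5, 1e4, 1e4, 24)
  rise <- function(LT, x) 2 * exp(-exp(exp(1) * 0.2 / 2 * (LT - x) + 1))
  na <- 1e4 * 10^rise(0, 24)
  nb <- 1e4 * 10^rise(5, 24)
  expect_equal(out$A_end, na / (na + nb), tolerance = 1e-12)
  expect_error(theoretical_competition(early, late, 1e4, 1e4, -2), "positive")
})

test_that("fixation consistency report and its round trip", {
  expect_equal(fixation_consistency(3, 2, 0.5, 8 / 9)$ratio, 1)
  r2 <- fixation_consistency(1.5, 2, 0.5, 8 / 9)
  expect_equal(r2$ratio, 2)
  expect_match(r2$note, "direct fitness effects")
  n <- rounds_to_fixation(2.5, 0.4, 0.97)
  expect_equal(fixation_consistency(n, 2.5, 0.4, 0.97)$ratio, 1)
})

test_that("fitness estimation from raw cytometry counts", {
  # exact counts with known fractions: A 0.5 -> 2/3 in one round
  est <- estimate_relative_fitness(50000, 50000, 66667, 33333)
  expect_equal(est$W, 2, tolerance = 1e-3)
  # pseudocount rescues boundary counts
  expect_error(estimate_relative_fitness(0, 1e5, 5e4, 5e4))
  est_pc <- estimate_relative_fitness(0, 1e5, 5e4, 5e4, pseudocount = 0.5)
  expect_true(is.finite(est_pc$W) && est_pc$W > 1)
  # fluorescence loss is undone when known
  sim <- simulate_competition(2, 0.5, 1, events = 1e6, f_loss = 0.1,
                              seed = 77)
  est_c <- estimate_relative_fitness(
    sim$fluorescent[1], sim$nonfluorescent[1],
    sim$fluorescent[2], sim$nonfluorescent[2], f_loss = 0.1)
  expect_equal(est_c$W, 2, tolerance = 0.05)
})

test_that("simulated competitions recover W within binomial sampling error", {
  for (true_w in c(1, 2)) {
    ws <- vapply(1:20, function(s) {
      sim <- simulate_competition(true_w, 0.5, 1, events = 1e5,
                                  seed = 600 + s)
      estimate_relative_fitness(sim$fluorescent[1], sim$nonfluorescent[1],
                                sim$fluorescent[2], sim$nonfluorescent[2])$W
    }, numeric(1))
    # delta method: sd(W) from two binomial fractions at 1e5 events
    A_end <- true_w / (1 + true_w)
    se_w <- true_w * sqrt(
      1 / (0.5 * 0.5 * 1e5) + 1 / (A_end * (1 - A_end) * 1e5))
    expect_lt(abs(mean(ws) - true_w), 3 * se_w / sqrt(20) + 1e-3)
    expect_lt(sd(ws), 3 * se_w)
  }
})

test_that("marker-neutrality null: one-sample t-test rejects at about alpha", {
  set.seed(808)
  reps <- 200
  rejected <- vapply(seq_len(reps), function(i) {
    ws <- vapply(1:6, function(j) {
      sim <- simulate_competition(1, 0.5, 1, events = 1e5)
      estimate_relative_fitness(sim$fluorescent[1], sim$nonfluorescent[1],
                                sim$fluorescent[2], sim$nonfluorescent[2])$W
    }, numeric(1))
    t.test(ws, mu = 1)$p.value < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rejected) - 0.05), 3 * se)
})
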