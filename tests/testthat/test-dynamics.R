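test_that("generations per cycle follow log2 of the regrowth factor", {
  expect_equal(generations_per_cycle(5e8, 5e8), 0)
  # 100,000-fold regrowth and 100-fold regrowth
  expect_equal(generations_per_cycle(1, 1e5), 16.61, tolerance = 1e-3)
  expect_equal(generations_per_cycle(5.4e6, 5.4e8), log2(100))
  expect_equal(generations_per_cycle(5.4e6, 5.4e8), 6.644, tolerance = 1e-3)
  expect_error(generations_per_cycle(0, 1e5), "positive")
  # additivity: cumulative generations over concatenated cycles
  set.seed(3)
  ci <- runif(10, 1e6, 1e7); ce <- ci * runif(10, 50, 200)
  expect_equal(cumulative_generations(ci, ce),
               cumulative_generations(ci[1:4], ce[1:4]) +
                 cumulative_generations(ci[5:10], ce[5:10]))
})

test_that("effective population size is g * N0", {
  expect_equal(effective_population_size(6.67, 2.73e8), 6.67 * 2.73e8)
  expect_equal(effective_population_size(1, 123), 123)
  expect_equal(effective_population_size(2, 10), 20)
  expect_error(effective_population_size(-1, 10), "positive")
})

test_that("Spearman machinery matches stats::cor and a hand-ranked fixture", {
  # hand fixture: ranks of x are (1, 2.5, 2.5, 4), ranks of y (1.5, 1.5, 3, 4)
  x <- c(1, 2, 2, 3); y <- c(10, 10, 20, 30)
  expect_equal(mutevol:::spearman_rho(x, y), 5 / 6, tolerance = 1e-12)
  set.seed(17)
  for (i in 1:15) {
    a <- round(rnorm(12), 1)  # rounding forces ties
    b <- round(a * 0.5 + rnorm(12), 1)
    expect_equal(mutevol:::spearman_rho(a, b),
                 cor(a, b, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("delta correlation: monotone deltas, tie handling, rank invariance", {
  tol <- c(5, 5.5, 6, 6.5, 7.5, 8)          # deltas 0.5 0.5 0.5 1 0.5
  up <- c(1, 2, 4, 8, 30, 40)               # bigger jumps with bigger steps
  res <- delta_correlation(tol, up, seed = 1)
  expect_gt(res$rho, 0)
  # perfectly co/anti-monotone delta pairs: deltas of the second series are
  # (1, 2, 4, 8) and (-1, -2, -4, -8) against tolerance deltas (.25 .. 1)
  co <- delta_correlation(c(5, 5.25, 5.75, 6.5, 7.5), c(1, 2, 4, 8, 16),
                          seed = 1)
  expect_equal(co$rho, 1)
  anti <- delta_correlation(c(5, 5.25, 5.75, 6.5, 7.5), c(16, 15, 13, 9, 1),
                            seed = 1)
  expect_equal(anti$rho, -1)
  # frozen hand-ranked tied fixture: dx ranks (4.5 1.5 4.5 4.5 1.5 4.5),
  # dy ranks (3 2 4 5 1 6)
  tolf <- c(5, 5.5, 5.5, 6, 6.5, 6.5, 7)
  ratef <- c(1, 4, 3, 9, 20, 15, 40)
  fix <- delta_correlation(tolf, ratef, seed = 2)
  expect_equal(fix$rho, 0.8280787, tolerance = 1e-6)
  expect_equal(fix$method, "permutation")
  # identical seed => identical permutation p-value
  expect_equal(fix$p_value, delta_correlation(tolf, ratef, seed = 2)$p_value)
  # rank invariance: increasing affine maps of either series rescale the
  # deltas positively and leave the rank correlation untouched
  fix2 <- delta_correlation(3 * tolf + 2, 100 * ratef + 7, seed = 2)
  expect_equal(fix2$rho, fix$rho)
  # the rank statistic itself is invariant under monotone transforms
  expect_equal(mutevol:::spearman_rho(exp(diff(tolf)), diff(ratef)^3),
               mutevol:::spearman_rho(diff(tolf), diff(ratef)))
  # log_rate changes the delta definition (it is a documented option, not a
  # rank-preserving transform) but still yields a valid correlation
  fixlog <- delta_correlation(tolf, ratef, log_rate = TRUE, seed = 2)
  expect_true(abs(fixlog$rho) <= 1)
  # degenerate: all deltas tied on one axis
  dg <- delta_correlation(c(5, 5.5, 6, 6.5), c(1, 2, 3, 4) * 0 + 2, seed = 1)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
})

test_that("group association dichotomizes mutator status correctly", {
  # 8 hypermutator lines at high tolerance, 12 at low: binary encoding on
  # both axes gives a perfect rank correlation
  rel_rate <- c(rep(8, 8), rep(0.6, 12))
  tolerance <- c(rep(11, 8), rep(6, 12))
  res <- group_association(rel_rate, tolerance, seed = 4)
  expect_equal(res$rho, 1)
  expect_lt(res$p_value, 0.05)
  expect_equal(sum(res$group), 8)
  # identical tolerance distributions: no association signal over seeds
  set.seed(42)
  rhos <- vapply(1:50, function(i) {
    tol_null <- sample(rep(c(6, 8, 10), length.out = 20))
    group_association(rel_rate, tol_null, seed = i)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
  # single group present is flagged
  one <- group_association(rep(2, 6), 1:6, seed = 1)
  expect_true(one$degenerate)
  expect_error(group_association(c(2, 0.5), c(5, 6)), ">= 4")
})

test_that("mutational spectrum tally classifies and conserves counts", {
  expect_equal(
    mutation_spectrum("A", "G")$counts$count,
    c(1, 0, 0, 0, 0))
  expect_equal(
    mutation_spectrum("A", "T")$counts$count,
    c(0, 1, 0, 0, 0))
  # 6 transitions, 2 transversions, 2 single-base deletions
  ref <- c("A", "G", "C", "T", "A", "G", "A", "C", "CA", "TG")
  alt <- c("G", "A", "T", "C", "G", "A", "T", "G", "C", "T")
  sp <- mutation_spectrum(ref, alt)
  expect_equal(sp$counts$count, c(6, 2, 2, 0, 0))
  expect_equal(sp$counts$fraction, c(0.6, 0.2, 0.2, 0, 0))
  # in-frame deletion, ambiguous base, MNV
  sp2 <- mutation_spectrum(c("ATGA", "N", "AT"), c("A", "A", "GC"))
  expect_equal(sp2$counts$count[sp2$counts$class == "inframe_indel"], 1)
  expect_equal(sp2$counts$count[sp2$counts$class == "unclassified"], 2)
  # conservation under random inputs
  set.seed(12)
  bases <- c("A", "C", "G", "T", "N", "AT", "ATG", "")
  r <- sample(bases, 200, replace = TRUE)
  a <- sample(bases, 200, replace = TRUE)
  expect_equal(sum(mutation_spectrum(r, a)$counts$count), 200)
})
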