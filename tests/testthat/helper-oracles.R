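# Independent oracles used across the suite. They never call the package's
# own recursion/optimizer paths.

# Luria-Delbruck pmf built as a compound Poisson: the number of mutational
# events is Poisson(m) and each event founds a clone whose final size k has
# probability 1/(k(k+1)) in a fully grown culture. The pmf is assembled by
# explicit convolution of the clone-size distribution -- an entirely
# different route from the MSS recursion.
oracle_ld_pmf <- function(m, n_max) {
  q <- c(0, 1 / ((1:n_max) * (2:(n_max + 1))))  # q[k+1] = P(clone size = k)
  cur <- c(1, rep(0, n_max))                    # 0-fold convolution
  p <- stats::dpois(0, m) * cur
  jmax <- max(30, stats::qpois(1 - 1e-13, m))
  for (j in seq_len(jmax)) {
    new <- numeric(n_max + 1)
    for (k in 1:n_max) {
      new[k + 1] <- sum(cur[1:(k + 1)] * rev(q[1:(k + 1)]))
    }
    cur <- new
    p <- p + stats::dpois(j, m) * cur
  }
  p
}

# Exhaustive two-stage grid search of the Lea-Coulson likelihood using the
# oracle pmf: coarse pass, then refinement at the target resolution.
oracle_grid_mle <- function(counts, upper = max(5, max(counts)),
                            coarse = 1e-2, fine = 1e-4) {
  n_max <- max(counts, 1)
  loglik <- function(m) {
    p <- oracle_ld_pmf(m, n_max)
    sum(log(pmax(p[counts + 1], 1e-300)))
  }
  grid1 <- seq(coarse, upper, by = coarse)
  ll1 <- vapply(grid1, loglik, numeric(1))
  best <- grid1[which.max(ll1)]
  grid2 <- seq(max(fine, best - 2 * coarse), best + 2 * coarse, by = fine)
  ll2 <- vapply(grid2, loglik, numeric(1))
  grid2[which.max(ll2)]
}
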