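# Luria-Delbruck fluctuation analysis: Lea-Coulson mutant-count
# distribution, Ma-Sandri-Sarkar maximum likelihood, confidence intervals,
# and comparison statistics for mutation-rate estimates.

#' Bundle a fluctuation assay's raw observations
#'
#' A fluctuation experiment consists of the mutant counts scored on selective
#' plates for a set of parallel cultures, plus viable-count calibration
#' cultures plated non-selectively to estimate the final population size
#' `Nt` per culture. Cultures are grouped into biological replicates by
#' `replicate`; per-replicate estimates feed [compare_rates()].
#'
#' @param mutant_counts Non-negative integer vector, one count per parallel
#'   culture (at least 2 cultures).
#' @param viable_counts Positive numeric vector of colony-forming units per
#'   culture from the plated calibration cultures (ideally >= 4).
#' @param replicate Optional character/factor vector of biological-replicate
#'   labels, one per culture. Defaults to a single replicate.
#' @param culture_volume_ml Culture volume in ml (metadata only).
#' @return An object of class `fluctuation_experiment`.
#' @seealso [mss_mle()], [mutation_rate()], [simulate_fluctuation()]
#' @export
fluctuation_experiment <- function(mutant_counts, viable_counts,
                                   replicate = NULL, culture_volume_ml = 0.2) {
  mutant_counts <- as.numeric(mutant_counts)
  viable_counts <- as.numeric(viable_counts)
  if (length(mutant_counts) < 2)
    stop("a fluctuation experiment needs at least 2 parallel cultures")
  if (anyNA(mutant_counts) || any(mutant_counts < 0))
    stop("mutant counts must be non-negative and non-missing")
  if (any(mutant_counts != round(mutant_counts)))
    stop("mutant counts must be whole numbers")
  if (length(viable_counts) < 1 || anyNA(viable_counts) ||
      any(viable_counts <= 0))
    stop("viable counts must be positive and non-missing")
  if (length(viable_counts) < 4)
    warning("fewer than 4 viable-count calibration cultures; ",
            "the mean Nt estimate will be imprecise")
  if (is.null(replicate)) replicate <- rep("R1", length(mutant_counts))
  replicate <- as.character(replicate)
  if (length(replicate) != length(mutant_counts))
    stop("'replicate' must have one label per culture")
  structure(
    list(mutant_counts = mutant_counts,
         viable_counts = viable_counts,
         replicate = replicate,
         culture_volume_ml = culture_volume_ml),
    class = "fluctuation_experiment")
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat("Fluctuation experiment:", length(x$mutant_counts), "parallel cultures,",
      length(unique(x$replicate)), "biological replicate(s)\n")
  cat("  mutant counts: median", median(x$mutant_counts),
      " max", max(x$mutant_counts), "\n")
  cat("  mean Nt:", format(mean(x$viable_counts), digits = 4),
      "CFU per culture\n")
  invisible(x)
}

#' Luria-Delbruck mutant-count probabilities
#'
#' Probability mass `p_0 .. p_n_max` of observing a given number of mutants
#' in a fully grown culture under the Lea-Coulson model, computed by the
#' Ma-Sandri-Sarkar recursion
#' `p_0 = exp(-m)`, `p_n = (m/n) * sum_{i=0}^{n-1} p_i / (n - i + 1)`,
#' where `m` is the expected number of mutational events per culture.
#'
#' @param m Expected number of mutations per culture (>= 0).
#' @param n_max Largest mutant count to evaluate (>= 0).
#' @return Numeric vector of length `n_max + 1`; entry `k + 1` is `P(N = k)`.
#' @examples
#' ld_pmf(1, 5)
#' @export
ld_pmf <- function(m, n_max) {
  if (length(m) != 1L || is.na(m) || m < 0)
    stop("'m' must be a single non-negative number")
  if (length(n_max) != 1L || is.na(n_max) || n_max < 0)
    stop("'n_max' must be a single non-negative integer")
  n_max <- as.integer(n_max)
  ld_pmf_cpp(m, n_max)
}

# Log-likelihood of a tabulated count vector at a given m.
# tab[k + 1] is the number of cultures with k mutants.
ld_loglik <- function(tab, m) {
  ld_loglik_cpp(as.numeric(tab), m)
}

#' Ma-Sandri-Sarkar maximum-likelihood estimate of m
#'
#' Maximizes the Lea-Coulson likelihood of the observed mutant counts over
#' the expected number of mutational events per culture, `m`. The search is
#' a derivative-free 1-D optimization on `log(m)` over the bracket
#' `[1e-6, max(count)]`; the distribution is truncated at the maximum
#' observed count. Counts above `count_cap` are capped with a warning
#' (the Luria-Delbruck tail is heavy and jackpot plates are often recorded
#' as "too many to count").
#'
#' @param x A [fluctuation_experiment()] or a numeric vector of mutant
#'   counts.
#' @param count_cap Ceiling applied to observed counts before estimation.
#' @param tol Convergence tolerance on `log(m)`.
#' @return The MLE `m_hat` (a single number; 0 when all counts are zero).
#' @examples
#' mss_mle(c(0, 1, 0, 4, 0, 0, 2, 0))
#' @export
mss_mle <- function(x, count_cap = 1e4, tol = 1e-6) {
  counts <- if (inherits(x, "fluctuation_experiment")) x$mutant_counts
            else as.numeric(x)
  if (length(counts) < 1L) stop("empty mutant-count vector")
  if (anyNA(counts) || any(counts < 0))
    stop("mutant counts must be non-negative and non-missing")
  if (any(counts > count_cap)) {
    warning(sprintf("%d count(s) above the ceiling of %g were capped",
                    sum(counts > count_cap), count_cap))
    counts <- pmin(counts, count_cap)
  }
  if (all(counts == 0)) return(0)
  n_max <- as.integer(max(counts))
  tab <- tabulate(counts + 1L, nbins = n_max + 1L)
  lo <- log(1e-6)
  hi <- log(max(n_max, 1))
  opt <- optimize(function(lm) ld_loglik(tab, exp(lm)),
                  interval = c(lo, hi), maximum = TRUE, tol = tol)
  m_hat <- exp(opt$maximum)
  if (opt$maximum > hi - 1e-4 && hi > lo + 1e-3)
    warning(sprintf(
      "MLE at the upper search bound (bracket [%g, %g] on m); estimate may not have converged",
      exp(lo), exp(hi)))
  m_hat
}

#' 95% confidence interval for m
#'
#' Default method is Stewart's log-normal approximation: the standard
#' deviation of `log(m_hat)` is taken as `1.225 * m_hat^-0.315 / sqrt(C)`
#' for `C` parallel cultures, matching the behaviour of the commonly used
#' fluctuation-analysis calculators. A profile-likelihood interval
#' (chi-square cutoff on the Lea-Coulson log-likelihood) is available via
#' `method = "profile"` and requires the raw counts.
#'
#' When `m_hat` is 0 (no mutants observed anywhere) the lower bound is 0 and
#' the upper bound is the exact binomial bound from the zero-class
#' probability, `-log(0.025) / C`.
#'
#' @param m_hat MLE of the expected mutations per culture.
#' @param n_cultures Number of parallel cultures `C` (>= 2).
#' @param method `"stewart"` (default) or `"profile"`.
#' @param counts Raw mutant counts; required for `method = "profile"`.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(m_low, m_high)`.
#' @export
ci_95 <- function(m_hat, n_cultures, method = c("stewart", "profile"),
                  counts = NULL, conf = 0.95) {
  method <- match.arg(method)
  if (n_cultures < 2) stop("need at least 2 cultures for a confidence interval")
  alpha <- 1 - conf
  if (m_hat == 0)
    return(c(0, -log(alpha / 2) / n_cultures))
  if (m_hat < 0) stop("'m_hat' must be non-negative")
  if (method == "stewart") {
    z <- qnorm(1 - alpha / 2)
    sigma <- 1.225 * m_hat^(-0.315) / sqrt(n_cultures)
    return(exp(log(m_hat) + c(-1, 1) * z * sigma))
  }
  # profile likelihood
  if (is.null(counts)) stop("profile CI needs the raw mutant counts")
  counts <- pmin(as.numeric(counts), 1e4)
  n_max <- as.integer(max(counts, 1))
  tab <- tabulate(counts + 1L, nbins = n_max + 1L)
  ll_hat <- ld_loglik(tab, m_hat)
  cut <- qchisq(conf, df = 1) / 2
  f <- function(lm) ld_loglik(tab, exp(lm)) - (ll_hat - cut)
  lo_bracket <- log(m_hat) - 10
  hi_bracket <- log(max(n_max, 1) * 10)
  m_low <- if (f(lo_bracket) > 0) exp(lo_bracket) else
    exp(uniroot(f, c(lo_bracket, log(m_hat)), tol = 1e-8)$root)
  m_high <- if (f(hi_bracket) > 0) exp(hi_bracket) else
    exp(uniroot(f, c(log(m_hat), hi_bracket), tol = 1e-8)$root)
  c(m_low, m_high)
}

#' Convert m to a mutation rate with confidence interval
#'
#' The number of mutational events per culture divided by the mean final
#' viable count gives the mutation rate per cell per generation at the
#' reporter locus. A user-supplied `scaling_factor` (e.g. a per-bp,
#' per-10^7-generation normalization) rescales the rate; it is deliberately
#' an input because the extrapolation from a reporter locus to the genome
#' depends on the assay.
#'
#' @param experiment A [fluctuation_experiment()].
#' @param m_hat Optional precomputed MLE; estimated by [mss_mle()] when
#'   `NULL`.
#' @param scaling_factor Optional multiplier applied to the rate.
#' @param ci_method Passed to [ci_95()].
#' @param count_cap Passed to [mss_mle()].
#' @return An object of class `mutation_rate_estimate` with elements
#'   `m_hat`, `rate`, `rate_scaled`, `ci_low`, `ci_high` (bounds on the
#'   rate), `n_cultures`, `mean_Nt`, and `replicate_m` (per-biological-
#'   replicate MLEs when two or more replicates are present).
#' @export
mutation_rate <- function(experiment, m_hat = NULL, scaling_factor = NULL,
                          ci_method = c("stewart", "profile"),
                          count_cap = 1e4) {
  if (!inherits(experiment, "fluctuation_experiment"))
    stop("'experiment' must be a fluctuation_experiment")
  ci_method <- match.arg(ci_method)
  if (is.null(m_hat)) m_hat <- mss_mle(experiment, count_cap = count_cap)
  if (m_hat < 0) stop("'m_hat' must be non-negative")
  mean_Nt <- mean(experiment$viable_counts)
  if (mean_Nt <= 0) stop("mean viable count must be positive")
  rate <- m_hat / mean_Nt
  C <- length(experiment$mutant_counts)
  ci_m <- ci_95(m_hat, C, method = ci_method,
                counts = experiment$mutant_counts)
  reps <- split(experiment$mutant_counts, experiment$replicate)
  replicate_m <- if (length(reps) >= 2)
    vapply(reps, mss_mle, numeric(1), count_cap = count_cap) else NULL
  structure(
    list(m_hat = m_hat,
         rate = rate,
         rate_scaled = if (!is.null(scaling_factor)) rate * scaling_factor
                       else NA_real_,
         ci_low = ci_m[1] / mean_Nt,
         ci_high = ci_m[2] / mean_Nt,
         n_cultures = C,
         mean_Nt = mean_Nt,
         replicate_m = replicate_m,
         ci_method = ci_method),
    class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat("Mutation-rate estimate (MSS maximum likelihood)\n")
  cat(sprintf("  m_hat  : %.4g mutations per culture (%d cultures)\n",
              x$m_hat, x$n_cultures))
  cat(sprintf("  rate   : %.4g per cell per generation  [95%% CI %.4g - %.4g, %s]\n",
              x$rate, x$ci_low, x$ci_high, x$ci_method))
  if (!is.na(x$rate_scaled))
    cat(sprintf("  scaled : %.4g\n", x$rate_scaled))
  invisible(x)
}

#' Compare two mutation-rate estimates
#'
#' Two-sided Student's t-test on the per-biological-replicate numbers of
#' mutational events (the replicate-level `m_hat` values), mirroring the
#' convention of comparing calculator-reported mutational-event counts when
#' population densities are equal. Also reports the fold change of the
#' rates. When a list of viable-count groups is supplied, the equal-density
#' precondition is checked with [density_equality()] and a failure is
#' flagged.
#'
#' @param est_a,est_b `mutation_rate_estimate` objects carrying
#'   `replicate_m` (>= 2 biological replicates per side).
#' @param density_groups Optional list of viable-count vectors (one per
#'   strain/time point) for the equal-density check.
#' @param alpha Significance level for the density check.
#' @return A list of class `rate_comparison`: `statistic`, `p_value`,
#'   `fold_change` (rate_a / rate_b), the replicate values, and
#'   `density_ok` (NA when unchecked).
#' @export
compare_rates <- function(est_a, est_b, density_groups = NULL, alpha = 0.05) {
  ra <- est_a$replicate_m
  rb <- est_b$replicate_m
  if (is.null(ra) || is.null(rb) || length(ra) < 2 || length(rb) < 2)
    stop("both estimates need >= 2 biological replicates for a t-test")
  fold <- est_a$rate / est_b$rate
  va <- var(ra); vb <- var(rb)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(ra), mean(rb)))) {
      statistic <- 0; p_value <- 1
    } else {
      statistic <- Inf * sign(mean(ra) - mean(rb))
      p_value <- .Machine$double.xmin  # below any printable floor
    }
  } else {
    tt <- t.test(ra, rb, var.equal = TRUE)
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  density_ok <- NA
  if (!is.null(density_groups)) {
    dens <- density_equality(density_groups, alpha = alpha)
    density_ok <- dens$pass
    if (!dens$pass)
      warning("population densities differ significantly; ",
              "the rate comparison assumes equal cell densities")
  }
  structure(
    list(statistic = statistic, p_value = p_value, fold_change = fold,
         replicate_m_a = ra, replicate_m_b = rb, density_ok = density_ok),
    class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Mutation-rate comparison (t-test on replicate mutational events)\n")
  cat(sprintf("  t = %.4g, p = %.4g, fold change = %.4g\n",
              x$statistic, x$p_value, x$fold_change))
  if (!is.na(x$density_ok) && !x$density_ok)
    cat("  WARNING: equal-density precondition failed\n")
  invisible(x)
}

#' Check the equal-cell-density assumption
#'
#' One-way ANOVA with post-hoc Tukey correction on viable-count groups, used
#' to verify that population densities at plating do not differ between the
#' strains or time points being compared. Degenerate input with no variance
#' at all passes trivially.
#'
#' @param groups List (>= 2) of numeric viable-count vectors, each with
#'   >= 2 observations.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_value` (ANOVA F-test), `pass` (p > alpha), and
#'   `tukey` (the `TukeyHSD` table, or NULL for degenerate input).
#' @export
density_equality <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of >= 2 viable-count vectors")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs >= 2 observations")
  values <- unlist(groups, use.names = FALSE)
  if (any(values <= 0)) stop("viable counts must be positive")
  grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (var(values) < .Machine$double.eps * mean(values)^2)
    return(list(p_value = 1, pass = TRUE, tukey = NULL))
  fit <- aov(values ~ grp)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(p_value = p, pass = p > alpha, tukey = TukeyHSD(fit))
}
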