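# Death-rate estimation from declining viable-count series: decline-segment
# selection, one-phase exponential decay fitting, and group comparisons.

#' Select the declining segment of a viability time series
#'
#' Viable counts first rise during growth, then fall in stationary phase.
#' The decay model applies to the fall only; this returns the maximal
#' suffix of the series starting at the global CFU maximum (earliest index
#' on ties). Fewer than `min_points` points after the peak, or a peak at
#' the last observation, is a failure, flagged rather than thrown.
#'
#' @param time_h Strictly increasing times in hours.
#' @param cfu Positive viable counts (CFU/ml), same length.
#' @param min_points Minimum usable decline length (default 4).
#' @return List with `ok`, `time_h`, `cfu`, `start_index`, and `reason`
#'   when `ok` is `FALSE`.
#' @export
select_decline_segment <- function(time_h, cfu, min_points = 4) {
  time_h <- as.numeric(time_h); cfu <- as.numeric(cfu)
  if (length(time_h) != length(cfu)) stop("'time_h' and 'cfu' lengths differ")
  if (any(diff(time_h) <= 0)) stop("'time_h' must be strictly increasing")
  if (anyNA(cfu) || any(cfu <= 0)) stop("'cfu' must be positive")
  peak <- which.max(cfu)  # earliest tie
  idx <- peak:length(cfu)
  if (peak == length(cfu))
    return(list(ok = FALSE, start_index = peak,
                reason = "series is monotone increasing (no decline)"))
  if (length(idx) < min_points)
    return(list(ok = FALSE, start_index = peak,
                reason = sprintf("only %d points after the peak (need >= %d)",
                                 length(idx), min_points)))
  list(ok = TRUE, time_h = time_h[idx], cfu = cfu[idx], start_index = peak,
       reason = NULL)
}

#' Fit a one-phase exponential decay to declining viable counts
#'
#' Least-squares fit of `y = (ymax - ymin) * exp(-k * x) + ymin` on the
#' linear CFU scale, with time re-origined to the start of the decline
#' segment. `k` (h^-1) is the death-rate constant. `ymin` may be fitted
#' freely (default, bounded at 0) or fixed via `fix_ymin`.
#'
#' @param time_h Times of the declining segment (hours), or a segment list
#'   from [select_decline_segment()] passed as the first argument.
#' @param cfu Viable counts, same length (ignored when a segment list is
#'   given).
#' @param fix_ymin Optional fixed floor; `NULL` (default) fits it.
#' @param min_points Minimum number of points (default 4).
#' @return Object of class `decay_fit`: `coefficients` (`ymax, ymin, k`),
#'   `ci` (95% Wald intervals), `sse`, `converged`, `reason`,
#'   `segment_start_index`, `t0` (re-origin offset).
#' @seealso [select_decline_segment()], [simulate_decay()]
#' @export
fit_decay <- function(time_h, cfu = NULL, fix_ymin = NULL, min_points = 4) {
  start_index <- 1L
  if (is.list(time_h) && !is.null(time_h$ok)) {
    seg <- time_h
    if (!seg$ok) stop("decline-segment selection failed: ", seg$reason)
    start_index <- seg$start_index
    cfu <- seg$cfu
    time_h <- seg$time_h
  }
  time_h <- as.numeric(time_h); cfu <- as.numeric(cfu)
  if (length(time_h) != length(cfu)) stop("'time_h' and 'cfu' lengths differ")
  if (length(time_h) < min_points)
    stop(sprintf("need >= %d points in the declining segment", min_points))
  if (any(diff(time_h) <= 0)) stop("'time_h' must be strictly increasing")
  if (anyNA(cfu) || any(cfu <= 0)) stop("'cfu' must be positive")
  t0 <- time_h[1]
  x <- time_h - t0
  n <- length(x)

  ymax0 <- cfu[1]
  ymin0 <- max(min(cfu) * 0.5, 0)
  span <- max(cfu[1] - cfu[n], cfu[1] * 1e-3)
  k0 <- min(max(log(max(cfu[1] / max(cfu[n], 1e-12), 1.01)) / max(x), 1e-4), 10)

  failed <- function(reason) {
    structure(list(coefficients = c(ymax = NA_real_, ymin = NA_real_,
                                    k = NA_real_),
                   ci = NULL, sse = NA_real_, converged = FALSE,
                   reason = reason, segment_start_index = start_index,
                   t0 = t0),
              class = "decay_fit")
  }

  dat <- data.frame(x = x, y = cfu)
  fit <- tryCatch({
    if (is.null(fix_ymin)) {
      minpack.lm::nlsLM(y ~ (ymax - ymin) * exp(-k * x) + ymin, data = dat,
                        start = list(ymax = ymax0, ymin = ymin0, k = k0),
                        lower = c(ymax = 0, ymin = 0, k = 1e-8),
                        upper = c(ymax = Inf, ymin = Inf, k = 100),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      if (fix_ymin < 0) stop("'fix_ymin' must be >= 0")
      minpack.lm::nlsLM(y ~ (ymax - fix_ymin) * exp(-k * x) + fix_ymin,
                        data = dat,
                        start = list(ymax = ymax0, k = k0),
                        lower = c(ymax = 0, k = 1e-8),
                        upper = c(ymax = Inf, k = 100),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))

  cf <- coef(fit)
  if (!is.null(fix_ymin)) cf <- c(cf["ymax"], ymin = fix_ymin, cf["k"])
  cf <- cf[c("ymax", "ymin", "k")]
  pred <- (cf["ymax"] - cf["ymin"]) * exp(-cf["k"] * x) + cf["ymin"]
  sse <- sum((cfu - pred)^2)
  ci <- tryCatch({
    se <- sqrt(diag(vcov(fit)))
    tq <- qt(0.975, df = n - length(coef(fit)))
    est <- coef(fit)
    cbind(low = est - tq * se, high = est + tq * se)
  }, error = function(e) NULL)
  if (cf[["ymax"]] <= cf[["ymin"]])
    return(failed("fitted ymax <= ymin: no decay signal"))
  structure(list(coefficients = cf, ci = ci, sse = sse, converged = TRUE,
                 reason = NULL, segment_start_index = start_index, t0 = t0),
            class = "decay_fit")
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Exponential-decay fit: FAILED (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat("One-phase exponential decay fit\n")
  cat(sprintf("  ymax = %.4g  ymin = %.4g  k = %.4g /h\n",
              cf["ymax"], cf["ymin"], cf["k"]))
  invisible(x)
}

#' Compare death-rate constants across strains or time points
#'
#' Pairwise two-tailed Student's t-tests on replicate death-rate constants
#' `k`, plus an optional one-way ANOVA with post-hoc Tukey correction when
#' more than two groups are present. Groups with a single replicate are
#' described but not tested.
#'
#' @param k Numeric vector of fitted death-rate constants (one per
#'   replicate), or a named list of such vectors (then `group` is ignored).
#' @param group Grouping factor parallel to `k`.
#' @param anova Run the ANOVA/Tukey path when > 2 groups (default TRUE).
#' @return List with `summary` (per-group n, mean, sd), `pairwise` (data
#'   frame of t-test results, NULL if untestable), `anova_p`, `tukey`.
#' @export
compare_death_rates <- function(k, group = NULL, anova = TRUE) {
  if (is.list(k)) {
    group <- rep(names(k), lengths(k))
    k <- unlist(k, use.names = FALSE)
  }
  if (is.null(group)) stop("'group' is required when 'k' is a vector")
  if (length(k) != length(group)) stop("'k' and 'group' lengths differ")
  if (anyNA(k) || any(k <= 0)) stop("death-rate constants must be positive")
  group <- factor(as.character(group), levels = unique(as.character(group)))
  groups <- split(k, group)
  summ <- data.frame(group = names(groups),
                     n = lengths(groups),
                     mean_k = vapply(groups, mean, numeric(1)),
                     sd_k = vapply(groups, function(g)
                       if (length(g) > 1) sd(g) else NA_real_, numeric(1)),
                     row.names = NULL)
  testable <- names(groups)[lengths(groups) >= 2]
  pairwise <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(testable, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
      if (var(a) == 0 && var(b) == 0) {
        p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1
             else .Machine$double.xmin
        stat <- if (p == 1) 0 else Inf * sign(mean(a) - mean(b))
      } else {
        tt <- t.test(a, b, var.equal = TRUE)
        p <- tt$p.value; stat <- unname(tt$statistic)
      }
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 statistic = stat, p_value = p)
    }))
  }
  anova_p <- NA_real_; tukey <- NULL
  if (anova && length(testable) > 2) {
    keep <- group %in% testable
    fit <- aov(k[keep] ~ droplevels(group[keep]))
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tukey <- TukeyHSD(fit)
  }
  list(summary = summ, pairwise = pairwise, anova_p = anova_p, tukey = tukey)
}

#' Compare dead-cell fractions between two groups
#'
#' Two-sided Student's t-test on replicate dead-cell fractions (e.g.
#' propidium-iodide-positive event proportions from live-dead staining).
#'
#' @param fractions_a,fractions_b Numeric vectors of fractions in \[0, 1\]
#'   with at least 2 replicates each.
#' @return List with `mean_a`, `mean_b`, `difference`, `statistic`,
#'   `p_value`.
#' @export
dead_fraction_compare <- function(fractions_a, fractions_b) {
  for (f in list(fractions_a, fractions_b)) {
    if (length(f) < 2) stop("need >= 2 replicate fractions per group")
    if (anyNA(f) || any(f < 0) || any(f > 1))
      stop("dead-cell fractions must lie in [0, 1]")
  }
  va <- var(fractions_a); vb <- var(fractions_b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(fractions_a), mean(fractions_b)))
    stat <- if (equal) 0 else Inf * sign(mean(fractions_a) - mean(fractions_b))
    p <- if (equal) 1 else .Machine$double.xmin
  } else {
    tt <- t.test(fractions_a, fractions_b, var.equal = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(mean_a = mean(fractions_a), mean_b = mean(fractions_b),
       difference = mean(fractions_a) - mean(fractions_b),
       statistic = stat, p_value = p)
}
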