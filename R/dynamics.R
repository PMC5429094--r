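# Lineage accounting and trajectory-level analyses: generations per
# transfer cycle, effective population size, rank correlations between
# mutation-rate and tolerance changes, and mutational-spectrum tallies.

#' Generations per serial-transfer cycle
#'
#' Number of doublings in one growth cycle, `log2(CFU_e / CFU_i)`, from the
#' viable counts at the start (`cfu_i`) and end (`cfu_e`) of the cycle.
#' Vectorized over cycles.
#'
#' @param cfu_i,cfu_e Positive viable counts at cycle start and end.
#' @return Generations per cycle (vector).
#' @examples
#' generations_per_cycle(5.4e6, 5.4e8)  # log2(100) = 6.644
#' @export
generations_per_cycle <- function(cfu_i, cfu_e) {
  if (anyNA(cfu_i) || anyNA(cfu_e) || any(cfu_i <= 0) || any(cfu_e <= 0))
    stop("viable counts must be positive")
  log2(cfu_e / cfu_i)
}

#' Cumulative generations over a series of cycles
#'
#' Sum of [generations_per_cycle()] over all transfer cycles.
#'
#' @inheritParams generations_per_cycle
#' @return Total generations elapsed.
#' @export
cumulative_generations <- function(cfu_i, cfu_e) {
  sum(generations_per_cycle(cfu_i, cfu_e))
}

#' Effective population size of a serial-transfer line
#'
#' Serial-transfer estimate `Ne = g * N0`, with `g` the generations per
#' growth cycle and `N0` the number of founder cells transferred at each
#' passage.
#'
#' @param g Generations per cycle (> 0).
#' @param N0 Transferred founder count (> 0).
#' @return Effective population size.
#' @examples
#' effective_population_size(6.67, 2.73e8)  # 1.82e9
#' @export
effective_population_size <- function(g, N0) {
  if (any(is.na(g)) || any(is.na(N0)) || any(g <= 0) || any(N0 <= 0))
    stop("'g' and 'N0' must be positive")
  g * N0
}

# Average ranks with ties, written out explicitly so the rank arithmetic is
# package-owned and testable against stats::cor.test.
avg_rank <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Spearman rho: Pearson correlation of average ranks.
spearman_rho <- function(x, y) {
  rx <- avg_rank(x); ry <- avg_rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

spearman_p <- function(x, y, rho, n_perm, seed) {
  n <- length(x)
  if (n < 20) {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i)
      spearman_rho(x, y[sample.int(n)]), numeric(1))
    (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * pt(-abs(tt), df = n - 2)
  }
}

#' Correlation between consecutive changes in rate and tolerance
#'
#' Forms deltas between consecutive trajectory points for both the
#' mutation-rate estimate and the ethanol tolerance, then computes the
#' Spearman rank correlation with average ranks for ties. Tolerance changes
#' live on a discrete 0.25/0.5 percentage-point grid, hence the
#' rank-based method. For fewer than 20 delta pairs the p-value comes from
#' a seeded permutation test; otherwise from the large-sample t
#' approximation.
#'
#' @param tolerance_pct Tolerance (% v/v) at each ordered time point.
#' @param rate Mutation-rate estimate at each time point (same length).
#' @param log_rate Take deltas of `log(rate)` instead of `rate`.
#' @param n_perm Permutations for the small-sample p-value.
#' @param seed Seed for the permutation test.
#' @return List with `rho`, `p_value`, `n_pairs`, `method`, and
#'   `degenerate` (TRUE when all deltas are tied on either axis, in which
#'   case `rho` is `NA`).
#' @export
delta_correlation <- function(tolerance_pct, rate, log_rate = FALSE,
                              n_perm = 1e4, seed = NULL) {
  if (length(tolerance_pct) != length(rate))
    stop("'tolerance_pct' and 'rate' lengths differ")
  if (length(rate) < 4)
    stop("need >= 4 time points (>= 3 consecutive delta pairs)")
  if (log_rate) {
    if (any(rate <= 0)) stop("log-scale deltas need positive rates")
    rate <- log(rate)
  }
  dx <- diff(tolerance_pct)
  dy <- diff(rate)
  if (length(unique(dx)) == 1L || length(unique(dy)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n_pairs = length(dx),
                method = "none", degenerate = TRUE))
  rho <- spearman_rho(dx, dy)
  method <- if (length(dx) < 20) "permutation" else "t-approximation"
  p <- spearman_p(dx, dy, rho, n_perm, seed)
  list(rho = rho, p_value = p, n_pairs = length(dx), method = method,
       degenerate = FALSE)
}

#' Association between mutator status and endpoint tolerance
#'
#' Evolved lines are dichotomized by whether their mutation rate exceeds
#' the wild type's (rate relative to wild type > 1), and the binary group
#' code is Spearman-correlated against the lines' endpoint ethanol
#' tolerance.
#'
#' @param relative_rate Mutation rate relative to wild type, one per line
#'   (>= 4 lines).
#' @param tolerance_pct Endpoint tolerance per line.
#' @param n_perm,seed Passed to the permutation p-value (used when < 20
#'   lines).
#' @return List with `rho`, `p_value`, `n_lines`, `group` (the binary
#'   encoding), and `degenerate` (TRUE when all lines fall in one group).
#' @export
group_association <- function(relative_rate, tolerance_pct, n_perm = 1e4,
                              seed = NULL) {
  if (length(relative_rate) != length(tolerance_pct))
    stop("'relative_rate' and 'tolerance_pct' lengths differ")
  if (length(relative_rate) < 4) stop("need >= 4 lines")
  grp <- as.numeric(relative_rate > 1)
  if (length(unique(grp)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_,
                n_lines = length(grp), group = grp, degenerate = TRUE))
  rho <- spearman_rho(grp, tolerance_pct)
  p <- spearman_p(grp, tolerance_pct, rho, n_perm, seed)
  list(rho = rho, p_value = p, n_lines = length(grp), group = grp,
       degenerate = FALSE)
}

#' Tally a mutational spectrum
#'
#' Classifies ref/alt allele pairs: single-base substitutions are
#' transitions (A<->G, C<->T) or transversions (any purine<->pyrimidine
#' change); length-changing indels are frameshifts when the length
#' difference is not a multiple of 3, otherwise in-frame indels.
#' Multi-base same-length changes and alleles with ambiguous characters are
#' counted as unclassified. The class counts always sum to the number of
#' input variants.
#'
#' @param ref,alt Character vectors of reference and alternate alleles
#'   (DNA strings; `""` or `"-"` denote a missing allele side of an indel).
#' @return List with `counts` (data frame of class, count, fraction) and
#'   `n` (number of variants).
#' @export
mutation_spectrum <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("'ref' and 'alt' lengths differ")
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  ref[ref == "-"] <- ""; alt[alt == "-"] <- ""
  classes <- c("transition", "transversion", "frameshift_indel",
               "inframe_indel", "unclassified")
  valid <- function(s) !is.na(s) & grepl("^[ACGT]*$", s)
  classify <- function(r, a) {
    if (!valid(r) || !valid(a)) return("unclassified")
    if (nchar(r) == nchar(a)) {
      if (nchar(r) != 1L || r == a) return("unclassified")
      pur <- c("A", "G")
      if ((r %in% pur) == (a %in% pur)) "transition" else "transversion"
    } else {
      if ((abs(nchar(r) - nchar(a)) %% 3L) != 0L) "frameshift_indel"
      else "inframe_indel"
    }
  }
  calls <- mapply(classify, ref, alt, USE.NAMES = FALSE)
  n <- length(calls)
  counts <- vapply(classes, function(cl) sum(calls == cl), numeric(1))
  list(counts = data.frame(class = classes,
                           count = unname(counts),
                           fraction = if (n > 0) unname(counts) / n
                                      else rep(NA_real_, length(classes))),
       n = n)
}
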