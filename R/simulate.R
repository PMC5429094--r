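# Seeded synthetic-data generators. Each generator emulates one assay of
# the pipeline and attaches its ground truth as the "truth" attribute, so
# recovery can be tested end to end without any external data.

#' Simulate a fluctuation experiment
#'
#' Draws Luria-Delbruck mutant counts for `n_cultures` parallel cultures
#' with expected mutations per culture `m`, in one of two modes:
#'
#' * `"pmf"`: inverse-CDF sampling from [ld_pmf()], with residual tail
#'   mass beyond `cap` assigned to `cap` (the tail is heavy; capped draws
#'   are flagged with a warning).
#' * `"forward"`: explicit generation-wise growth: in each generation every
#'   cell divides and new mutations arise binomially among the daughter
#'   cells; each mutant clone then expands stochastically (Yule growth, no
#'   mutant death or differential fitness), so a clone founded in
#'   generation `j` of `g` reaches a geometric final size with mean
#'   `2^(g-j)` -- the stochastic mutant growth assumed by the Lea-Coulson
#'   model.
#'
#' Viable-count calibration cultures are drawn lognormally around `Nt`.
#'
#' @param m Expected mutational events per culture (>= 0).
#' @param n_cultures Number of parallel cultures (>= 2).
#' @param Nt Final viable count per culture.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param mode `"pmf"` (default) or `"forward"`.
#' @param cap Count ceiling for tail capping.
#' @param n_replicates Number of biological-replicate labels to spread the
#'   cultures over.
#' @param n_calibration Calibration cultures per replicate.
#' @param nt_cv Coefficient of variation of the calibration counts.
#' @param generations Generations of growth in forward mode.
#' @return A [fluctuation_experiment()] with attribute `truth`.
#' @export
simulate_fluctuation <- function(m, n_cultures, Nt = 2e8, seed = NULL,
                                 mode = c("pmf", "forward"), cap = 1e4,
                                 n_replicates = 2, n_calibration = 4,
                                 nt_cv = 0.05, generations = 20) {
  mode <- match.arg(mode)
  if (m < 0) stop("'m' must be non-negative")
  if (n_cultures < 2) stop("need at least 2 cultures")
  if (!is.null(seed)) set.seed(seed)
  if (mode == "pmf") {
    if (m == 0) {
      counts <- rep(0, n_cultures)
    } else {
      cdf <- cumsum(ld_pmf(m, cap))
      u <- runif(n_cultures)
      counts <- pmin(findInterval(u, cdf), cap)
      if (any(u > cdf[length(cdf)]))
        warning(sprintf("%d draw(s) fell in the capped tail beyond %g",
                        sum(u > cdf[length(cdf)]), cap))
    }
  } else {
    g <- as.integer(generations)
    N0 <- max(1, round(Nt / 2^g))
    total_new <- N0 * (2^g - 1)
    mu <- m / total_new
    counts <- vapply(seq_len(n_cultures), function(i) {
      cnt <- 0
      for (j in seq_len(g)) {
        new_cells <- N0 * 2^(j - 1)
        muts <- rbinom(1L, size = new_cells, prob = mu)
        if (muts > 0) {
          # mutation times fall within the generation with density matching
          # the exponential population growth; each clone then grows as a
          # Yule process, i.e. geometric final size with mean 2^age
          age <- g - (j - 1) - log2(1 + runif(muts))
          cnt <- cnt + sum(stats::rgeom(muts, prob = 2^-age) + 1)
        }
      }
      min(cnt, cap)
    }, numeric(1))
  }
  sdlog <- sqrt(log(1 + nt_cv^2))
  viable <- rlnorm(n_replicates * n_calibration,
                   meanlog = log(Nt) - sdlog^2 / 2, sdlog = sdlog)
  replicate <- rep(paste0("R", seq_len(n_replicates)),
                   length.out = n_cultures)
  out <- fluctuation_experiment(counts, viable, replicate = sort(replicate))
  attr(out, "truth") <- list(m = m, Nt = Nt, mode = mode, seed = seed)
  out
}

#' Simulate a plate-reader growth curve
#'
#' Evaluates the Gompertz model on a regular sampling grid (15-minute
#' default, matching automated plate readers) and multiplies the
#' linear-scale OD by mean-one lognormal noise with coefficient of
#' variation `noise_cv`.
#'
#' @param y0,yM,SGR,LT Gompertz truth (see [gompertz()]).
#' @param noise_cv Multiplicative OD noise CV (0 for a noiseless curve).
#' @param interval_h Sampling interval in hours.
#' @param duration_h Total monitored time in hours.
#' @param seed Integer seed.
#' @return Data frame with `time_h`, `od`, and attribute `truth`.
#' @export
simulate_growth <- function(y0 = -2, yM = 2, SGR = 0.2, LT = 5,
                            noise_cv = 0.02, interval_h = 0.25,
                            duration_h = 50, seed = NULL) {
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  time_h <- seq(0, duration_h, by = interval_h)
  od <- 10^gompertz(time_h, y0, yM, SGR, LT)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    od <- od * rlnorm(length(od), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out <- data.frame(time_h = time_h, od = od)
  attr(out, "truth") <- list(y0 = y0, yM = yM, SGR = SGR, LT = LT,
                             noise_cv = noise_cv, seed = seed)
  out
}

#' Simulate a flow-cytometry competition assay
#'
#' Propagates the focal-strain fraction through `n_rounds` selection rounds
#' by the odds update `odds(A') = W * odds(A)`, then draws fluorescent and
#' non-fluorescent event counts at every time point from a binomial
#' cytometry model: each of `events` sampled cells is focal with
#' probability `A`, and a focal cell is scored fluorescent with probability
#' `1 - f_loss`.
#'
#' @param true_W True relative fitness of the focal (fluorescent) strain.
#' @param A_start Initial focal fraction.
#' @param n_rounds Number of selection rounds.
#' @param events Cytometry events counted per time point.
#' @param f_loss Fluorescence false-negative fraction.
#' @param seed Integer seed.
#' @return Data frame with `round`, `fluorescent`, `nonfluorescent`,
#'   `f_loss`; attribute `truth` records the parameters and the true
#'   fraction path.
#' @export
simulate_competition <- function(true_W = 2, A_start = 0.5, n_rounds = 1,
                                 events = 1e5, f_loss = 0, seed = NULL) {
  if (true_W <= 0) stop("'true_W' must be positive")
  if (A_start <= 0 || A_start >= 1) stop("'A_start' must be in (0, 1)")
  if (events < 1) stop("'events' must be >= 1")
  if (f_loss < 0 || f_loss >= 1) stop("'f_loss' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  A <- numeric(n_rounds + 1)
  A[1] <- A_start
  for (r in seq_len(n_rounds)) {
    o <- true_W * A[r] / (1 - A[r])
    A[r + 1] <- o / (1 + o)
  }
  fluor <- rbinom(n_rounds + 1, size = events, prob = A * (1 - f_loss))
  out <- data.frame(round = 0:n_rounds,
                    fluorescent = fluor,
                    nonfluorescent = events - fluor,
                    f_loss = f_loss)
  attr(out, "truth") <- list(W = true_W, A_path = A, events = events,
                             f_loss = f_loss, seed = seed)
  out
}

#' Simulate a viability-decay time series
#'
#' Evaluates the one-phase exponential decay
#' `y = (ymax - ymin) * exp(-k * x) + ymin` on a regular grid and applies
#' mean-one lognormal count noise. Optionally prepends a rising growth
#' phase so decline-segment selection can be exercised: the series then
#' peaks exactly at index `rise_points + 1`.
#'
#' @param ymax,ymin,k Decay truth (`k` in h^-1).
#' @param n_points Points in the declining phase.
#' @param duration_h Length of the declining phase (hours).
#' @param noise_cv Count-noise coefficient of variation.
#' @param rise_points Points of rising phase to prepend (0 for none).
#' @param rise_duration_h Length of the prepended rise.
#' @param seed Integer seed.
#' @return Data frame with `time_h`, `cfu`; attribute `truth` (includes
#'   `peak_index`).
#' @export
simulate_decay <- function(ymax = 1e9, ymin = 1e6, k = 0.1, n_points = 30,
                           duration_h = 90, noise_cv = 0.1, rise_points = 0,
                           rise_duration_h = 10, seed = NULL) {
  if (ymax <= ymin || ymin < 0) stop("need ymax > ymin >= 0")
  if (k <= 0) stop("'k' must be positive")
  if (!is.null(seed)) set.seed(seed)
  x <- seq(0, duration_h, length.out = n_points)
  y <- (ymax - ymin) * exp(-k * x) + ymin
  time_h <- x
  if (rise_points > 0) {
    rt <- seq(0, rise_duration_h, length.out = rise_points + 1)[1:rise_points]
    # geometric rise from two decades below the peak, kept strictly below it
    ry <- ymax * 10^(-2 * (1 - rt / rise_duration_h)) * 0.99
    time_h <- c(rt, x + rise_duration_h)
    y <- c(ry, y)
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    y <- y * rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out <- data.frame(time_h = time_h, cfu = y)
  attr(out, "truth") <- list(ymax = ymax, ymin = ymin, k = k,
                             noise_cv = noise_cv,
                             peak_index = rise_points + 1L, seed = seed)
  out
}

#' Simulate a tolerance/mutation-rate trajectory
#'
#' Emulates the characteristic pattern of mutation-rate dynamics during
#' stepwise adaptation to increasing ethanol stress: in cycles where the
#' tolerated ethanol percentage steps up (by 0.5 points, or 0.25 points at
#' and above 7.5%), the underlying mutation rate jumps multiplicatively by
#' `jump_fold` (a mutator allele hitchhiking with the adaptive mutation);
#' in plateau cycles the rate decays geometrically by `plateau_decline`
#' (selection against the mutation-rate burden once adapted). Observed
#' rates carry lognormal estimation noise whose log-scale standard
#' deviation matches the Stewart confidence-interval width for a
#' fluctuation assay with `n_cultures` parallel cultures.
#'
#' @param n_cycles Number of transfer cycles after the baseline point.
#' @param tolerance_start Starting tolerance (% v/v).
#' @param base_rate Starting mutation rate (arbitrary per-cell units).
#' @param p_step Per-cycle probability of a tolerance step.
#' @param jump_fold Multiplicative rate jump accompanying a step (1 for no
#'   coupling).
#' @param plateau_decline Multiplicative rate decay per plateau cycle.
#' @param n_cultures Assay size used to scale estimation noise.
#' @param g_per_cycle Generations per cycle for the cumulative-generations
#'   column.
#' @param noise Logical; set `FALSE` for a noiseless trajectory.
#' @param seed Integer seed.
#' @return Data frame with `cycle`, `tolerance_pct`, `rate` (noisy
#'   estimate), `true_rate`, `generations`; attribute `truth`.
#' @export
simulate_trajectory <- function(n_cycles = 20, tolerance_start = 5,
                                base_rate = 1e-8, p_step = 0.4,
                                jump_fold = 4, plateau_decline = 0.75,
                                n_cultures = 30, g_per_cycle = 6.67,
                                noise = TRUE, seed = NULL) {
  if (n_cycles < 2) stop("need >= 2 cycles")
  if (jump_fold <= 0 || plateau_decline <= 0 || base_rate <= 0)
    stop("rates and fold changes must be positive")
  if (p_step < 0 || p_step > 1) stop("'p_step' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  tol <- numeric(n_cycles + 1)
  true_rate <- numeric(n_cycles + 1)
  tol[1] <- tolerance_start
  true_rate[1] <- base_rate
  for (i in seq_len(n_cycles)) {
    if (runif(1) < p_step) {
      step <- if (tol[i] >= 7.5) 0.25 else 0.5
      tol[i + 1] <- tol[i] + step
      true_rate[i + 1] <- true_rate[i] * jump_fold
    } else {
      tol[i + 1] <- tol[i]
      true_rate[i + 1] <- true_rate[i] * plateau_decline
    }
  }
  sdlog <- 1.225 / sqrt(n_cultures)  # Stewart width at m ~ 1
  rate <- if (noise)
    true_rate * rlnorm(n_cycles + 1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  else true_rate
  out <- data.frame(cycle = 0:n_cycles,
                    tolerance_pct = tol,
                    rate = rate,
                    true_rate = true_rate,
                    generations = (0:n_cycles) * g_per_cycle)
  attr(out, "truth") <- list(jump_fold = jump_fold,
                             plateau_decline = plateau_decline,
                             p_step = p_step, sdlog = sdlog, seed = seed)
  out
}
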