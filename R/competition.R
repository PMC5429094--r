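# Competition-assay relative fitness: odds-ratio fitness per selection
# round, fluorescence-loss correction, rounds-to-fixation, and in-silico
# competition of two fitted growth models.

odds <- function(a) a / (1 - a)

check_fraction <- function(a, name, open = TRUE) {
  if (length(a) != 1L || is.na(a)) stop(sprintf("'%s' must be a single number", name))
  if (open && (a <= 0 || a >= 1))
    stop(sprintf("'%s' must lie strictly inside (0, 1); for boundary %s",
                 name,
                 "fractions from zero counts use a pseudocount (see estimate_relative_fitness)"))
  if (!open && (a < 0 || a > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name))
  invisible(a)
}

#' Correct an observed fluorescent fraction for fluorescence loss
#'
#' A fraction `f_loss` of truly marked (fluorescent) cells is scored as
#' non-fluorescent, so `observed = true * (1 - f_loss)`. The correction
#' divides by `1 - f_loss`; results above 1 are clipped with a warning.
#'
#' @param observed Observed fluorescent fraction in \[0, 1\].
#' @param f_loss Fluorescence false-negative fraction in \[0, 1).
#' @return Corrected fraction.
#' @export
correct_fluorescence_loss <- function(observed, f_loss) {
  check_fraction(observed, "observed", open = FALSE)
  if (length(f_loss) != 1L || is.na(f_loss) || f_loss < 0 || f_loss >= 1)
    stop("'f_loss' must lie in [0, 1)")
  corrected <- observed / (1 - f_loss)
  if (corrected > 1) {
    warning("corrected fraction exceeds 1; clipped to 1")
    corrected <- 1
  }
  corrected
}

#' Relative fitness from start and end fractions
#'
#' The per-selection-round odds-ratio fitness of a focal strain A:
#' `W = [ A_end (1 - A_start) / ((1 - A_end) A_start) ]^(1/n)`.
#' `W = 1` means neutrality; `W > 1` means strain A gained ground. The
#' reciprocal convention (fitness of the competitor) is available via
#' `reciprocal = TRUE`.
#'
#' @param A_start,A_end Focal-strain fractions strictly inside (0, 1).
#' @param n Number of selection rounds (> 0); one 48-h growth cycle is one
#'   round by convention.
#' @param reciprocal Report `1 / W` instead.
#' @return Relative fitness `W` (> 0).
#' @examples
#' relative_fitness(0.5, 2/3, n = 1)  # 2
#' @export
relative_fitness <- function(A_start, A_end, n = 1, reciprocal = FALSE) {
  check_fraction(A_start, "A_start")
  check_fraction(A_end, "A_end")
  if (length(n) != 1L || is.na(n) || n <= 0) stop("'n' must be positive")
  W <- (odds(A_end) / odds(A_start))^(1 / n)
  if (reciprocal) 1 / W else W
}

#' Selection rounds needed to reach a target fraction
#'
#' Inverts the odds-ratio fitness model:
#' `n = log(odds(A_target) / odds(A_start)) / log(W)`, so that
#' `relative_fitness(A_start, A_target, n)` returns `W` exactly. A negative
#' `n` (target on the wrong side of the start given `W`) is returned with a
#' warning.
#'
#' @param W Relative fitness (> 0, != 1).
#' @param A_start,A_target Fractions strictly inside (0, 1).
#' @return Number of selection rounds `n`.
#' @examples
#' rounds_to_fixation(2, 0.5, 2/3)  # 1
#' @export
rounds_to_fixation <- function(W, A_start, A_target) {
  if (length(W) != 1L || is.na(W) || W <= 0) stop("'W' must be positive")
  if (W == 1) stop("W = 1: a neutral strain never fixes")
  check_fraction(A_start, "A_start")
  check_fraction(A_target, "A_target")
  n <- log(odds(A_target) / odds(A_start)) / log(W)
  if (n < 0)
    warning("negative n: the target fraction lies on the wrong side of the ",
            "start given W")
  n
}

as_gompertz_params <- function(fit) {
  if (inherits(fit, "gompertz_fit")) {
    if (!fit$converged) stop("growth fit did not converge")
    return(fit$coefficients)
  }
  fit <- unlist(fit)
  if (!all(c("y0", "yM", "SGR", "LT") %in% names(fit)))
    stop("growth parameters must be named y0, yM, SGR, LT")
  fit[c("y0", "yM", "SGR", "LT")]
}

#' Compete two fitted growth models in silico
#'
#' Each strain grows independently for one cycle according to its own
#' Gompertz model, starting from its inoculum: its end abundance is the
#' inoculum times the model's rise above baseline on the linear scale,
#' `inoculum * 10^(y(cycle_duration) - y0)`. The end fraction and the
#' per-cycle relative fitness (n = 1) are returned. This is the
#' "theoretical competition" used to predict fixation dynamics from growth
#' curves alone, without interaction terms.
#'
#' @param fit_a,fit_b `gompertz_fit` objects or named parameter vectors
#'   (`y0, yM, SGR, LT`).
#' @param inoculum_a,inoculum_b Starting abundances (> 0, e.g. CFU).
#' @param cycle_duration Cycle length in hours (> 0).
#' @return List with `A_start`, `A_end` (fraction of strain A), and `W`
#'   (per-cycle relative fitness of A).
#' @export
theoretical_competition <- function(fit_a, fit_b, inoculum_a, inoculum_b,
                                    cycle_duration) {
  if (length(cycle_duration) != 1L || is.na(cycle_duration) ||
      cycle_duration <= 0)
    stop("'cycle_duration' must be positive")
  if (inoculum_a <= 0 || inoculum_b <= 0) stop("inocula must be positive")
  pa <- as_gompertz_params(fit_a)
  pb <- as_gompertz_params(fit_b)
  fold <- function(p) {
    10^(gompertz(cycle_duration, p["y0"], p["yM"], p["SGR"], p["LT"]) -
        p[["y0"]])
  }
  a_end <- inoculum_a * fold(pa)
  b_end <- inoculum_b * fold(pb)
  A_start <- inoculum_a / (inoculum_a + inoculum_b)
  A_end <- unname(a_end / (a_end + b_end))
  W <- if (isTRUE(all.equal(A_end, A_start))) 1
       else relative_fitness(A_start, A_end, n = 1)
  list(A_start = A_start, A_end = A_end, W = W)
}

#' Compare theoretical and observed rounds to fixation
#'
#' Computes the theoretical number of selection rounds for a strain with
#' fitness `W` to move from `A_start` to `A_target`, and the ratio of
#' theoretical to observed rounds. A ratio well above 1 (fixation faster
#' than the fitness predicts) is annotated as consistent with direct
#' effects of mutations accumulated during the sweep; the annotation is a
#' label only, not a test.
#'
#' @param observed_n Observed number of selection rounds (> 0).
#' @param W,A_start,A_target Passed to [rounds_to_fixation()].
#' @param ratio_flag Ratio above which the annotation is attached.
#' @return List with `theoretical_n`, `observed_n`, `ratio`, and `note`.
#' @export
fixation_consistency <- function(observed_n, W, A_start, A_target,
                                 ratio_flag = 1.5) {
  if (length(observed_n) != 1L || is.na(observed_n) || observed_n <= 0)
    stop("'observed_n' must be positive")
  theo <- rounds_to_fixation(W, A_start, A_target)
  ratio <- theo / observed_n
  note <- if (is.finite(ratio) && ratio > ratio_flag)
    paste("theoretical n exceeds observed n: consistent with direct",
          "fitness effects of mutations accumulated during the sweep")
  else NA_character_
  list(theoretical_n = theo, observed_n = observed_n, ratio = ratio,
       note = note)
}

#' Relative fitness from raw cytometry counts
#'
#' Turns fluorescent/non-fluorescent event counts at the start and end of a
#' competition into a fitness estimate: fractions are formed (optionally
#' with a Haldane-style pseudocount so boundary counts stay usable),
#' corrected for fluorescence loss, and passed to [relative_fitness()].
#'
#' @param fluor_start,nonfluor_start,fluor_end,nonfluor_end Event counts
#'   (>= 0).
#' @param n Selection rounds (default one growth cycle).
#' @param f_loss Fluorescence false-negative fraction.
#' @param pseudocount Added to every count before forming fractions
#'   (default 0; use 0.5 for boundary counts).
#' @return List of class `competition_result`: `A_start`, `A_end`
#'   (corrected fractions), `n`, `W`, `f_loss`, and the raw counts.
#' @export
estimate_relative_fitness <- function(fluor_start, nonfluor_start,
                                      fluor_end, nonfluor_end,
                                      n = 1, f_loss = 0, pseudocount = 0) {
  counts <- c(fluor_start, nonfluor_start, fluor_end, nonfluor_end)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  frac <- function(f, nf) (f + pseudocount) / (f + nf + 2 * pseudocount)
  A_start <- correct_fluorescence_loss(frac(fluor_start, nonfluor_start), f_loss)
  A_end <- correct_fluorescence_loss(frac(fluor_end, nonfluor_end), f_loss)
  W <- relative_fitness(A_start, A_end, n = n)
  structure(list(A_start = A_start, A_end = A_end, n = n, W = W,
                 f_loss = f_loss,
                 counts = data.frame(
                   time_point = c("start", "end"),
                   fluorescent = c(fluor_start, fluor_end),
                   nonfluorescent = c(nonfluor_start, nonfluor_end))),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat("Competition result\n")
  cat(sprintf("  A: %.4f -> %.4f over %g round(s)   W = %.4g\n",
              x$A_start, x$A_end, x$n, x$W))
  invisible(x)
}
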