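# Gompertz growth kinetics on log10 optical density: model evaluation,
# nonlinear least-squares fitting, doubling time, and batch summaries.

#' Evaluate the Gompertz growth model
#'
#' Modified Gompertz model on the log10 density scale:
#' `y(x) = y0 + yM * exp(-exp(e * SGR / yM * (LT - x) + 1))`,
#' with `e = exp(1)`. In this parameterization `y0` is the baseline log10
#' density, `yM` the total log10 rise (carrying-capacity amplitude), `SGR`
#' the specific growth rate (maximum slope of the log10 curve, h^-1), and
#' `LT` the lag time (h): the tangent at the inflection point has slope
#' `SGR` and crosses the baseline `y = y0` at `x = LT`.
#'
#' @param x Time in hours (vector).
#' @param y0 Baseline log10 density.
#' @param yM Carrying-capacity amplitude in log10 units (> 0).
#' @param SGR Specific growth rate (log10 units per hour, > 0).
#' @param LT Lag time in hours (>= 0).
#' @return Log10 density at `x`.
#' @examples
#' gompertz(0:10, y0 = -2, yM = 2, SGR = 0.2, LT = 5)
#' @export
gompertz <- function(x, y0, yM, SGR, LT) {
  y0 + yM * exp(-exp(exp(1) * SGR / yM * (LT - x) + 1))
}

#' Fit the Gompertz model to a growth curve
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of
#' [gompertz()] to `log10` of the optical-density readings. Readings are
#' floored at `floor` before the log to keep blank wells finite. Starting
#' values come from the data: `y0` from the minimum, `yM` from the range,
#' `SGR` from the steepest finite-difference slope, and `LT` from the
#' intercept of the steepest tangent with the baseline.
#'
#' Curves with no growth signal (log10 range below `min_signal`) or a
#' monotone-decreasing trend are reported as failed fits, not errors.
#'
#' @param time_h Time in hours, strictly increasing, >= 8 points.
#' @param od Optical-density readings (same length).
#' @param floor Detection floor applied to `od` before `log10`.
#' @param min_signal Minimum log10 range regarded as a growth signal.
#' @return An object of class `gompertz_fit`: `coefficients` (named vector
#'   `y0, yM, SGR, LT`), `ci` (95% Wald intervals from the linearized
#'   covariance), `sse`, `converged`, `reason`, and the fitted data.
#' @seealso [doubling_time()], [growth_summary()], [simulate_growth()]
#' @export
fit_gompertz <- function(time_h, od, floor = 1e-3, min_signal = 0.05) {
  time_h <- as.numeric(time_h); od <- as.numeric(od)
  if (length(time_h) != length(od)) stop("'time_h' and 'od' lengths differ")
  if (length(time_h) < 8) stop("need at least 8 time points to fit")
  if (any(diff(time_h) <= 0)) stop("'time_h' must be strictly increasing")
  if (anyNA(od)) stop("'od' contains missing values")
  y <- log10(pmax(od, floor))

  failed <- function(reason) {
    structure(list(coefficients = c(y0 = NA_real_, yM = NA_real_,
                                    SGR = NA_real_, LT = NA_real_),
                   ci = NULL, sse = NA_real_, converged = FALSE,
                   reason = reason, time_h = time_h, log10_od = y),
              class = "gompertz_fit")
  }
  if (diff(range(y)) < min_signal) return(failed("no growth signal"))
  # crude trend check: overall decline with no rise above start
  if (y[length(y)] < y[1] && max(y) - y[1] < min_signal)
    return(failed("monotone-decreasing series"))

  y0_0 <- min(y)
  yM_0 <- max(diff(range(y)), min_signal)
  slopes <- diff(y) / diff(time_h)
  i_max <- which.max(slopes)
  SGR_0 <- min(max(slopes[i_max], 1e-3), 10)
  t_mid <- (time_h[i_max] + time_h[i_max + 1]) / 2
  y_mid <- (y[i_max] + y[i_max + 1]) / 2
  LT_0 <- min(max(t_mid - (y_mid - y0_0) / SGR_0, 0), max(time_h))

  dat <- data.frame(t = time_h, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ gompertz(t, y0, yM, SGR, LT), data = dat,
      start = list(y0 = y0_0, yM = yM_0, SGR = SGR_0, LT = LT_0),
      lower = c(y0 = min(y) - 5, yM = 1e-6, SGR = 1e-6, LT = 0),
      upper = c(y0 = max(y) + 5, yM = 10, SGR = 10, LT = max(time_h)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))

  cf <- coef(fit)
  resid <- y - gompertz(time_h, cf["y0"], cf["yM"], cf["SGR"], cf["LT"])
  sse <- sum(resid^2)
  ci <- tryCatch({
    se <- sqrt(diag(vcov(fit)))
    tq <- qt(0.975, df = length(y) - 4)
    cbind(low = cf - tq * se, high = cf + tq * se)
  }, error = function(e) NULL)
  structure(list(coefficients = cf, ci = ci, sse = sse, converged = TRUE,
                 reason = NULL, time_h = time_h, log10_od = y),
            class = "gompertz_fit")
}

#' @export
coef.gompertz_fit <- function(object, ...) object$coefficients

#' @export
predict.gompertz_fit <- function(object, x = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  if (is.null(x)) x <- object$time_h
  cf <- object$coefficients
  gompertz(x, cf["y0"], cf["yM"], cf["SGR"], cf["LT"])
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gompertz fit: FAILED (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat("Gompertz fit (log10 OD scale)\n")
  cat(sprintf("  y0 = %.4g  yM = %.4g  SGR = %.4g /h  LT = %.4g h\n",
              cf["y0"], cf["yM"], cf["SGR"], cf["LT"]))
  cat(sprintf("  doubling time = %.4g h   SSE = %.3g\n",
              log10(2) / cf["SGR"], x$sse))
  invisible(x)
}

#' Doubling time from a Gompertz fit
#'
#' `log10(2) / SGR`: the time to double optical density at the maximum
#' specific growth rate of the log10 curve.
#'
#' @param fit A `gompertz_fit`, or a single positive `SGR` value.
#' @return Doubling time in hours.
#' @examples
#' doubling_time(0.1)  # 3.0103 h
#' @export
doubling_time <- function(fit) {
  sgr <- if (inherits(fit, "gompertz_fit")) {
    if (!fit$converged) stop("cannot compute doubling time from a failed fit")
    fit$coefficients[["SGR"]]
  } else as.numeric(fit)
  if (length(sgr) != 1L || is.na(sgr) || sgr <= 0)
    stop("'SGR' must be a single positive number")
  log10(2) / sgr
}

#' Fit many growth curves and tabulate their parameters
#'
#' Splits a long-format table by its grouping columns, fits each curve with
#' [fit_gompertz()], and returns one row per curve with the fitted
#' parameters, doubling time, and failure reasons where fitting failed.
#'
#' @param data Data frame with columns `time_h` and `od` plus any grouping
#'   columns (e.g. `strain`, `condition`, `replicate`).
#' @param floor Passed to [fit_gompertz()].
#' @return Data frame: one row per group with columns `y0, yM, SGR, LT,
#'   doubling_time_h, sse, converged, reason`. Empty input gives an empty
#'   table.
#' @export
growth_summary <- function(data, floor = 1e-3) {
  stopifnot(is.data.frame(data))
  need <- c("time_h", "od")
  if (!all(need %in% names(data)))
    stop("'data' must contain columns time_h and od")
  group_cols <- setdiff(names(data), need)
  empty <- data.frame()
  if (nrow(data) == 0) return(empty)
  key <- if (length(group_cols)) interaction(data[group_cols], drop = TRUE)
         else factor(rep("all", nrow(data)))
  pieces <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    d <- data[idx, , drop = FALSE]
    d <- d[order(d$time_h), , drop = FALSE]
    fit <- tryCatch(fit_gompertz(d$time_h, d$od, floor = floor),
                    error = function(e) {
                      structure(list(coefficients = c(y0 = NA, yM = NA,
                                                      SGR = NA, LT = NA),
                                     sse = NA_real_, converged = FALSE,
                                     reason = conditionMessage(e)),
                                class = "gompertz_fit")
                    })
    cf <- fit$coefficients
    out <- if (length(group_cols)) d[1, group_cols, drop = FALSE]
           else data.frame(row.names = 1)
    out$y0 <- unname(cf["y0"]); out$yM <- unname(cf["yM"])
    out$SGR <- unname(cf["SGR"]); out$LT <- unname(cf["LT"])
    out$doubling_time_h <- if (fit$converged && cf[["SGR"]] > 0)
      log10(2) / cf[["SGR"]] else NA_real_
    out$sse <- fit$sse
    out$converged <- fit$converged
    out$reason <- if (is.null(fit$reason)) NA_character_ else fit$reason
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}
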