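#' Four-parameter logistic response
#'
#' Forward 4PL model used for sandwich-ELISA standard curves:
#' \deqn{f(x) = d + (a - d) / (1 + (x / c)^b)}
#' where `a` is the response at zero concentration, `d` the response at
#' infinite concentration, `c` the inflection (EC50) and `b` the slope.
#' With `a < d` and `b > 0` the curve increases monotonically in `x`.
#'
#' @param x concentration (nonnegative).
#' @param a,d lower and upper response asymptotes.
#' @param c inflection concentration (> 0).
#' @param b slope factor (> 0 for an increasing curve).
#' @return modelled signal at `x`.
#' @export
fourpl <- function(x, a, d, c, b) {
  d + (a - d) / (1 + (x / c)^b)
}

#' Fit an ELISA standard curve
#'
#' Least-squares fit of a four-parameter logistic to calibrator points
#' (known concentration, observed signal). Interpolation is only defined
#' within the calibrator signal range.
#'
#' @param calibrators data.frame with columns `concentration` and `signal`,
#'   or a two-column matrix in that order.
#' @return an object of class `standard_curve`: list with `parameters`
#'   (named a, d, c, b), `fit_residual` (residual sum of squares) and
#'   `calibrator_points`.
#' @export
fit_standard_curve <- function(calibrators) {
  cal <- as.data.frame(calibrators)
  if (ncol(cal) < 2) stop("calibrators need (concentration, signal) columns")
  names(cal)[1:2] <- c("concentration", "signal")
  cal <- cal[order(cal$concentration), , drop = FALSE]
  if (length(unique(cal$concentration)) < 5) {
    stop("insufficient_calibrators: need >= 5 distinct concentrations")
  }
  if (any(cal$signal < 0)) stop("calibrator signals must be nonnegative")
  # monotone trend check: signal must correlate strictly with concentration
  rho <- suppressWarnings(stats::cor(cal$concentration, cal$signal,
                                     method = "spearman"))
  if (is.na(rho) || abs(rho) < 0.99) stop("degenerate_curve: calibrator trend not monotone")
  increasing <- rho > 0

  lo <- min(cal$signal); hi <- max(cal$signal)
  span <- hi - lo
  start <- list(
    a = if (increasing) lo - 0.05 * span else hi + 0.05 * span,
    d = if (increasing) hi + 0.05 * span else lo - 0.05 * span,
    c = stats::median(cal$concentration),
    b = if (increasing) 1 else -1
  )
  fit <- minpack.lm::nlsLM(
    signal ~ fourpl(concentration, a, d, c, b),
    data = cal, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- stats::coef(fit)
  if (p[["d"]] <= p[["a"]] && p[["b"]] > 0 || p[["c"]] <= 0) {
    # reparameterize: (a,d,c,b) and (d,a,c,-b) describe the same curve
    p <- c(a = unname(p[["d"]]), d = unname(p[["a"]]),
           c = unname(p[["c"]]), b = -unname(p[["b"]]))
  }
  structure(list(
    parameters = c(a = unname(p[["a"]]), d = unname(p[["d"]]),
                   c = unname(p[["c"]]), b = unname(p[["b"]])),
    fit_residual = sum(stats::resid(fit)^2),
    calibrator_points = cal
  ), class = "standard_curve")
}

#' Interpolate a concentration from a standard curve
#'
#' Inverts the fitted 4PL at an observed signal. Defined only for signals
#' strictly between the curve's asymptotes (and clipped to the calibrator
#' signal range by the caller if desired).
#'
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @param signal observed signal(s).
#' @return interpolated concentration(s), nonnegative.
#' @export
interpolate_concentration <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  p <- curve$parameters
  a <- p[["a"]]; d <- p[["d"]]; c <- p[["c"]]; b <- p[["b"]]
  lo <- min(a, d); hi <- max(a, d)
  if (any(signal <= lo) || any(signal >= hi)) {
    stop("out_of_range: signal at or beyond curve asymptotes")
  }
  # y = d + (a-d)/(1+(x/c)^b)  =>  x = c * ((a-d)/(y-d) - 1)^(1/b)
  c * ((a - d) / (signal - d) - 1)^(1 / b)
}
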