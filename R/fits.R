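# functional_fits: Hill concentration-response and single-exponential
# kinetics fits (Levenberg-Marquardt least squares via minpack.lm).

.fitResult <- function(model, params, se, fixed, rss, n, converged) {
  se <- se[names(params)]
  se[is.na(se)] <- 0
  names(se) <- names(params)
  new("FitResult", model = model, parameters = params, se = se,
      fixed = fixed, rss = rss, nPoints = as.integer(n),
      converged = converged)
}

.nlsSE <- function(fit) {
  s <- summary(fit)$coefficients
  stats::setNames(s[, "Std. Error"], rownames(s))
}

#' Fit the Hill equation to concentration-response data
#'
#' Model: \eqn{y = bottom + (top - bottom) / (1 + (EC_{50}/x)^{n_H})}.
#' By default the bottom is fixed at 0 and the top (saturating plateau)
#' and Hill coefficient are free. Initial values are deterministic:
#' EC50 at the log-midpoint of the concentration range, Hill
#' coefficient 1, top at the maximal response. Standard errors come from
#' the covariance of the fit. Non-convergence raises an error (no
#' partial parameters are returned).
#'
#' @param data data.frame with columns \code{concentration} (nM, > 0)
#'   and \code{response} (fraction), optionally \code{sem}.
#' @param fixBottom,fixTop fix bottom (default \code{TRUE}, at 0) and/or
#'   top (at 1).
#' @param weighted weight points by 1/sem^2 (requires \code{sem}).
#' @return A \code{FitResult} with parameters \code{ec50} (nM),
#'   \code{hillN}, \code{top}, \code{bottom}.
#' @export
fitHill <- function(data, fixBottom = TRUE, fixTop = FALSE,
                    weighted = FALSE) {
  x <- data$concentration
  y <- data$response
  if (any(x <= 0)) stop("concentrations must be positive")
  nFree <- 2 + (!fixBottom) + (!fixTop)
  if (length(x) < nFree)
    stop("need at least ", nFree, " points for ", nFree, " free parameters")
  w <- if (weighted) {
    if (is.null(data$sem)) stop("weighted fit requires a 'sem' column")
    1 / pmax(data$sem, 1e-12)^2
  } else rep(1, length(x))
  start <- list(ec50 = 10^mean(log10(range(x))), hillN = 1)
  lower <- c(ec50 = 1e-12, hillN = 1e-3)
  upper <- c(ec50 = Inf, hillN = Inf)
  form <- "y ~ bottom + (top - bottom) / (1 + (ec50 / x)^hillN)"
  env <- list(x = x, y = y)
  fixed <- character(0)
  if (fixTop) {
    env$top <- 1
    fixed <- c(fixed, "top")
  } else {
    start$top <- max(y)
    lower <- c(lower, top = -Inf)
    upper <- c(upper, top = Inf)
  }
  if (fixBottom) {
    env$bottom <- 0
    fixed <- c(fixed, "bottom")
  } else {
    start$bottom <- min(y)
    lower <- c(lower, bottom = -Inf)
    upper <- c(upper, bottom = Inf)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form), data = env, start = start,
                      lower = lower[names(start)], upper = upper[names(start)],
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  params <- c(ec50 = unname(est["ec50"]), hillN = unname(est["hillN"]),
              top = if (fixTop) 1 else unname(est["top"]),
              bottom = if (fixBottom) 0 else unname(est["bottom"]))
  .fitResult("hill", params, .nlsSE(fit), fixed,
             sum(stats::residuals(fit)^2 * w), length(x), TRUE)
}

#' Fit a single-exponential time course
#'
#' Association: \eqn{y = A (1 - e^{-t/\tau}) + c}; decay:
#' \eqn{y = A e^{-t/\tau} + c}. tau is constrained positive;
#' initialisation is deterministic (tau at one third of the time range).
#' Degenerate data (constant y, amplitude collapsing to 0, or tau at its
#' bound) are flagged by \code{converged = FALSE} rather than reported
#' as a fit.
#'
#' @param t times (min or ms -- tau is returned in the same unit).
#' @param y responses.
#' @param mode \code{"association"} or \code{"decay"}.
#' @return A \code{FitResult} with parameters \code{tau},
#'   \code{amplitude}, \code{offset}.
#' @export
fitExponential <- function(t, y, mode = c("association", "decay")) {
  mode <- match.arg(mode)
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) < 3) stop("need at least 3 points")
  model <- sprintf("exponential_%s", mode)
  if (stats::sd(y) < 1e-14) {
    return(.fitResult(model,
                      c(tau = NA_real_, amplitude = 0, offset = mean(y)),
                      c(tau = 0, amplitude = 0, offset = 0), character(0),
                      sum((y - mean(y))^2), length(t), FALSE))
  }
  tauMin <- 1e-9
  start <- list(tau = diff(range(t)) / 3,
                amplitude = if (mode == "association") max(y) - min(y)
                            else y[which.min(t)] - y[which.max(t)],
                offset = if (mode == "association") min(y) else min(y))
  form <- if (mode == "association")
    "y ~ amplitude * (1 - exp(-t / tau)) + offset"
  else
    "y ~ amplitude * exp(-t / tau) + offset"
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form),
                      data = list(t = t, y = y), start = start,
                      lower = c(tau = tauMin, amplitude = -Inf,
                                offset = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(.fitResult(model, c(tau = NA_real_, amplitude = NA_real_,
                               offset = NA_real_),
                      c(tau = 0, amplitude = 0, offset = 0), character(0),
                      NA_real_, length(t), FALSE))
  }
  est <- stats::coef(fit)
  ok <- est["tau"] > tauMin * 10 && abs(est["amplitude"]) > 1e-10
  .fitResult(model,
             c(tau = unname(est["tau"]),
               amplitude = unname(est["amplitude"]),
               offset = unname(est["offset"])),
             .nlsSE(fit), character(0), sum(stats::residuals(fit)^2),
             length(t), ok)
}
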