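#' Least-squares fit through the origin
#'
#' Fits y = eta * x with zero intercept by ordinary least squares
#' (eta = sum(xy) / sum(x^2)); the standard error comes from the residual
#' variance of the one-parameter model.  Used for the linear law relating
#' the aggregate sensitivity of an influencer to its local PageRank
#' probability.
#'
#' @param x,y numeric vectors of equal length (n >= 2; x not all zero).
#' @return an object of class `origin_fit` with `coefficients` (named
#'   `eta`), `se`, `n`, `residuals`, `fitted`, and the underlying `lm` fit.
#' @export
fit_origin <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 points")
  if (all(x == 0)) stop("x must not be all zero")
  fit <- stats::lm(y ~ 0 + x)
  eta <- unname(stats::coef(fit)[1])
  rss <- sum(stats::residuals(fit)^2)
  structure(list(coefficients = c(eta = eta),
                 se = c(eta = sqrt(rss / (length(x) - 1) / sum(x^2))),
                 n = length(x),
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 x = x, y = y, lm = fit),
            class = "origin_fit")
}

#' Power-law fit by log-log ordinary least squares
#'
#' Fits y = eta_t * x^kappa by regressing ln y on ln x; `kappa` is the
#' slope, `eta_t` the exponentiated intercept, with standard errors from the
#' usual linear-regression formulas on the log scale (eta_t's by the delta
#' method).
#'
#' @param x,y strictly positive numeric vectors (n >= 3).
#' @return an object of class `powerlaw_fit` with `coefficients` (named
#'   `eta_t`, `kappa`), `se`, `n`, `residuals` (log scale), and the
#'   underlying `lm` fit.
#' @export
fit_powerlaw <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive x and y")
  fit <- stats::lm(log(y) ~ log(x))
  cf <- stats::coef(fit)
  eta_t <- exp(unname(cf[1]))
  # regression standard errors on the log scale (eta_t by the delta method)
  X <- cbind(1, log(x))
  sigma2 <- sum(stats::residuals(fit)^2) / (length(x) - 2)
  sec <- sqrt(diag(sigma2 * solve(crossprod(X))))
  structure(list(coefficients = c(eta_t = eta_t, kappa = unname(cf[2])),
                 se = c(eta_t = eta_t * sec[1], kappa = sec[2]),
                 n = length(x),
                 residuals = stats::residuals(fit),
                 x = x, y = y, lm = fit),
            class = "powerlaw_fit")
}

#' @export
coef.origin_fit <- function(object, ...) object$coefficients
#' @export
coef.powerlaw_fit <- function(object, ...) object$coefficients
#' @export
residuals.origin_fit <- function(object, ...) object$residuals
#' @export
residuals.powerlaw_fit <- function(object, ...) object$residuals

#' @export
predict.origin_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$coefficients[["eta"]] * x
}

#' @export
predict.powerlaw_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$coefficients[["eta_t"]] * x^object$coefficients[["kappa"]]
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("through-origin fit: y = eta x, eta = %.4f +/- %.4f (n = %d)\n",
              x$coefficients[["eta"]], x$se[["eta"]], x$n))
  invisible(x)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: y = eta_t x^kappa, eta_t = %.4f +/- %.4f, kappa = %.4f +/- %.4f (n = %d)\n",
              x$coefficients[["eta_t"]], x$se[["eta_t"]],
              x$coefficients[["kappa"]], x$se[["kappa"]], x$n))
  invisible(x)
}

#' @export
summary.origin_fit <- function(object, ...) {
  list(coefficients = object$coefficients, se = object$se, n = object$n,
       rss = sum(object$residuals^2))
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  list(coefficients = object$coefficients, se = object$se, n = object$n,
       rss_log = sum(object$residuals^2))
}

#' @export
plot.origin_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "Pr(b)", ylab = "Ds(u/d)(b)", ...)
  graphics::abline(0, x$coefficients[["eta"]])
  invisible(x)
}

#' Paper-style report tables from a sensitivity analysis
#'
#' Produces the three standard summaries: the ranked list of the strongest
#' (a, b) sensitivity pairs restricted to a in the up/down subgroups and b
#' in the seed/external subgroups (top-`top_n` cut of the full ranked
#' list), the per-influencer table of Ds(u/d)(b) with local PageRank, and
#' the seed-sensitivity ranking of the responders.
#'
#' @param agg a [sensitivity_aggregates] result.
#' @param top_n how many top pairs to keep (default 40).
#' @return list of data frames `top_pairs`, `influence`, `seed_ranking`.
#' @export
report_tables <- function(agg, top_n = 40L) {
  stopifnot(inherits(agg, "sensitivity_aggregates"))
  list(top_pairs = utils::head(agg$pairs, top_n),
       influence = agg$Ds_ud,
       seed_ranking = agg$Ds_t[order(agg$Ds_t$Ks_t), , drop = FALSE])
}
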