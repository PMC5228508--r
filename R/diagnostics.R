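#' Gelman-Rubin potential scale reduction factor
#'
#' The between/within-chain variance form of R-hat: with \eqn{m} chains of
#' length \eqn{n}, within-chain variance \eqn{W} and between-chain variance
#' \eqn{B} (of chain means, times \eqn{n}),
#' \deqn{\hat R = \sqrt{\left(\frac{n-1}{n} W + \frac{B}{n}\right) / W}.}
#' Values near 1 indicate the chains are sampling the same distribution;
#' the analysis requires at most 1.05 within a model and at most 1.2
#' between the main fit and its prior-sensitivity refit.
#'
#' @param chains list of equal-length numeric vectors, one per chain.
#' @return R-hat (>= ~1). If every chain has zero variance, 1 by convention.
#' @export
cjs_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2L)
  len <- lengths(chains)
  stopifnot(length(unique(len)) == 1L)
  n <- len[1]
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) return(1)
  B_over_n <- stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Between-model R-hat for prior-sensitivity comparison
#'
#' Pools all retained samples of each fit into a single chain and computes
#' R-hat between the two pooled chains, parameter by parameter. Used to
#' confirm that posteriors are not unduly altered by a change of priors
#' (threshold 1.2).
#'
#' @param fitA,fitB \code{\link{cjs_fit}} objects (or matrices of pooled
#'   draws with identical column names).
#' @param pars parameters to compare (default: all shared columns).
#' @return named numeric vector of between-model R-hat values.
#' @export
between_model_rhat <- function(fitA, fitB, pars = NULL) {
  dA <- if (inherits(fitA, "cjs_fit")) cjs_draws(fitA) else as.matrix(fitA)
  dB <- if (inherits(fitB, "cjs_fit")) cjs_draws(fitB) else as.matrix(fitB)
  if (is.null(pars)) pars <- intersect(colnames(dA), colnames(dB))
  missing <- setdiff(pars, intersect(colnames(dA), colnames(dB)))
  if (length(missing))
    stop("parameter(s) absent from one model: ",
         paste(missing, collapse = ", "))
  n <- min(nrow(dA), nrow(dB))
  vapply(pars, function(p)
    cjs_rhat(list(dA[seq_len(n), p], dB[seq_len(n), p])), numeric(1))
}

#' Summarize posterior draws
#'
#' Produces the summary conventions used in the reported tables: the point
#' estimate is the posterior mean; the 95% credible interval is the 2.5 and
#' 97.5% quantiles; the percent relative error is half the interval width
#' over the absolute point estimate, times 100, rounded to two significant
#' figures; the significance is the two-sided posterior tail probability
#' \code{2 min(Pr(theta > 0), Pr(theta < 0))}, floored at \code{1/n_draws}.
#' For a selection indicator the point estimate is the selection
#' probability.
#'
#' @param draws numeric matrix of posterior draws (columns = parameters) or
#'   a single numeric vector.
#' @return data frame with columns \code{parameter}, \code{estimate},
#'   \code{lower}, \code{upper}, \code{sd}, \code{error} (\code{Inf} when
#'   the estimate is 0) and \code{significance}.
#' @export
posterior_summary <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "theta"))
  stopifnot(nrow(draws) >= 1)
  ndraw <- nrow(draws)
  out <- lapply(colnames(draws), function(p) {
    v <- draws[, p]
    est <- mean(v)
    q <- unname(stats::quantile(v, c(0.025, 0.975), type = 7))
    err <- if (est == 0) Inf else signif((q[2] - q[1]) / 2 / abs(est) * 100, 2)
    sig <- max(2 * min(mean(v > 0), mean(v < 0)), 1 / ndraw)
    data.frame(parameter = p, estimate = est, lower = q[1], upper = q[2],
               sd = stats::sd(v), error = err, significance = sig)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @describeIn posterior_summary summary table for a fitted CJS model
#'   (coefficients, then indicators), plus R-hat per parameter.
#' @param object a \code{\link{cjs_fit}}.
#' @param ... unused.
#' @export
summary.cjs_fit <- function(object, ...) {
  d <- cjs_draws(object, c(cjs_coef_names(), cjs_indicator_names()))
  s <- posterior_summary(d)
  s$rhat <- unname(object$rhat[s$parameter])
  class(s) <- c("summary.cjs_fit", "data.frame")
  s
}

#' @export
print.summary.cjs_fit <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Posterior summary of a derived quantity
#'
#' Applies a transform draw by draw and summarizes the result, so the
#' reported value is the posterior mean of the function, not the function of
#' posterior means. The default covariate setting is the representative
#' individual of the analysis: a 650 mm non-spawner in the autumn of 2011.
#'
#' @param fit a \code{\link{cjs_fit}} (or a matrix of coefficient draws).
#' @param transform function of a named coefficient vector returning a
#'   single number (or a vectorized function of the draw matrix).
#' @return one-row data frame from \code{\link{posterior_summary}}.
#' @examples
#' \dontrun{
#' # annual interval recapture probability
#' predict_quantity(fit, function(b)
#'   annual_interval(plogis(b["beta_rho0"]), "recapture"))
#' }
#' @export
predict_quantity <- function(fit, transform) {
  d <- if (inherits(fit, "cjs_fit")) cjs_draws(fit, cjs_coef_names())
       else as.matrix(fit)
  vals <- apply(d, 1, transform)
  stopifnot(is.numeric(vals), is.null(dim(vals)))
  posterior_summary(matrix(vals, ncol = 1,
                           dimnames = list(NULL, "quantity")))
}

#' Predicted probabilities and derived rates from a fitted model
#'
#' Per-draw evaluation of the model's seasonal probabilities at a covariate
#' setting, optionally converted to the annual interval scale or to
#' instantaneous rates.
#'
#' @param object a \code{\link{cjs_fit}}.
#' @param type which probability: seasonal survival (\code{"survival"}),
#'   angler recapture (\code{"recapture"}), movement detection
#'   (\code{"movement"}) or spawning (\code{"spawning"}).
#' @param L,Y,S,x covariate setting (length covariate, standardized year,
#'   spawn season, spawning state); defaults are the representative
#'   individual (650 mm non-spawner, L = 0.5, outside the spawning season).
#' @param scale \code{"seasonal"} (default), \code{"annual"} (interval
#'   probability over four seasons) or \code{"instantaneous"} (annual F for
#'   recapture, annual M for survival).
#' @param ... unused.
#' @return one-row data frame from \code{\link{posterior_summary}}.
#' @export
predict.cjs_fit <- function(object, type = c("survival", "recapture",
                                             "movement", "spawning"),
                            L = 0.5, Y = 0, S = 0, x = 0,
                            scale = c("seasonal", "annual",
                                      "instantaneous"), ...) {
  type <- match.arg(type)
  scale <- match.arg(scale)
  which_p <- c(survival = "phi", recapture = "rho", movement = "delta",
               spawning = "kappa")[type]
  predict_quantity(object, function(b) {
    p <- linear_predictors(b, L = L, Y = Y, S = S, x = x)[[which_p]]
    if (scale == "seasonal") return(unname(p))
    kind <- if (type == "survival") "survival" else "recapture"
    a <- annual_interval(p, kind)
    if (scale == "annual") return(unname(a))
    if (type == "survival") instantaneous_M(a) else instantaneous_F(a)
  })
}
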