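#' Zero-truncated binomial tag-loss log likelihood
#'
#' Double-tagged fish are observed at recapture with either both anchor tags
#' or exactly one; fish that lost both tags cannot be identified, so the
#' binomial for two independent tag fates is truncated at zero retained
#' tags. With per-tag loss probability \eqn{p}, the conditional
#' probabilities are \eqn{(1-p)^2 / (1-p^2)} (both retained) and
#' \eqn{2p(1-p) / (1-p^2)} (one retained), which sum to 1.
#'
#' @param p per-tag loss probability in (0, 1); values outside give
#'   \code{-Inf}.
#' @param n_double recaptures retaining both tags.
#' @param n_single recaptures retaining exactly one tag.
#' @return log likelihood (vectorized over \code{p}).
#' @export
tagloss_loglik <- function(p, n_double, n_single) {
  stopifnot(n_double >= 0, n_single >= 0, n_double + n_single >= 1)
  ll <- rep(-Inf, length(p))
  ok <- p > 0 & p < 1
  # conditional on >= 1 tag retained: both (1-p)/(1+p), one 2p/(1+p)
  ll[ok] <- n_double * (log1p(-p[ok]) - log1p(p[ok])) +
    n_single * (log(2 * p[ok]) - log1p(p[ok]))
  # limiting case: all-double data and p -> 0 has likelihood 1
  if (n_single == 0) ll[p == 0] <- 0
  ll
}

#' Posterior of the tag-loss probability by quadrature
#'
#' Deterministic summary of the posterior of \eqn{p} (and of the
#' double-loss probability \eqn{p^2}) under a Uniform(0, 1) prior, computed
#' by adaptive numerical integration. Serves as the independent cross-check
#' for \code{\link{fit_tagloss}}.
#'
#' @inheritParams tagloss_loglik
#' @return data frame with rows \code{p} and \code{p_squared} and columns
#'   \code{estimate} (posterior mean), \code{lower}, \code{upper} (95%
#'   credible interval).
#' @export
tagloss_posterior <- function(n_double, n_single) {
  dens <- function(p) exp(tagloss_loglik(p, n_double, n_single))
  Z <- stats::integrate(dens, 0, 1)$value
  mom <- function(g) stats::integrate(function(p) g(p) * dens(p),
                                      0, 1)$value / Z
  cdf_inv <- function(prob) {
    stats::uniroot(function(q) stats::integrate(dens, 0, q)$value / Z - prob,
                   c(1e-10, 1 - 1e-10), tol = 1e-10)$root
  }
  q <- c(cdf_inv(0.025), cdf_inv(0.975))
  data.frame(parameter = c("p", "p_squared"),
             estimate = c(mom(identity), mom(function(p) p^2)),
             lower = c(q[1], q[1]^2), upper = c(q[2], q[2]^2))
}

#' Fit the Bayesian zero-truncated binomial tag-loss model
#'
#' Samples the posterior of the per-tag loss probability under a
#' Uniform(0, 1) prior by random-walk Metropolis on \code{logit(p)}, and
#' reports both \eqn{p} and the probability \eqn{p^2} of a double-tagged
#' fish losing both tags (tag fates independent).
#'
#' @inheritParams tagloss_loglik
#' @param n_iter iterations per chain (first half discarded).
#' @param n_chains number of chains.
#' @param seed integer seed.
#' @return object of class \code{"tagloss_fit"}: list with \code{draws}
#'   (per-chain list of vectors of p), \code{counts}, \code{rhat} and
#'   \code{seed}.
#' @examples
#' fit <- fit_tagloss(18, 7, seed = 1)
#' coef(fit)   # posterior mean of p, ~0.18
#' @export
fit_tagloss <- function(n_double, n_single, n_iter = 20000L, n_chains = 3L,
                        seed = 1L) {
  stopifnot(n_double >= 0, n_single >= 0)
  if (n_double + n_single == 0) {
    warning("no recaptures: returning draws from the Uniform(0,1) prior")
    set.seed(seed)
    draws <- lapply(seq_len(n_chains),
                    function(ch) stats::runif(n_iter %/% 2L))
    fit <- structure(list(draws = draws,
                          counts = c(n_double = 0, n_single = 0),
                          rhat = cjs_rhat(draws), seed = seed),
                     class = "tagloss_fit")
    return(fit)
  }
  lpost <- function(lp) {  # logit scale, with Jacobian of the transform
    p <- stats::plogis(lp)
    tagloss_loglik(p, n_double, n_single) + log(p) + log(1 - p)
  }
  draws <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed) + ch)
    lp <- stats::qlogis(stats::runif(1, 0.05, 0.95))
    cur <- lpost(lp)
    keep <- numeric(n_iter %/% 2L)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      prop <- lp + stats::rnorm(1, 0, 0.6)
      new <- lpost(prop)
      if (log(stats::runif(1)) < new - cur) { lp <- prop; cur <- new }
      if (it > n_iter %/% 2L) {
        kept <- kept + 1L
        keep[kept] <- stats::plogis(lp)
      }
    }
    draws[[ch]] <- keep
  }
  structure(list(draws = draws,
                 counts = c(n_double = n_double, n_single = n_single),
                 rhat = cjs_rhat(draws), seed = seed),
            class = "tagloss_fit")
}

#' @export
coef.tagloss_fit <- function(object, ...) {
  p <- unlist(object$draws)
  c(p = mean(p), p_squared = mean(p^2))
}

#' @export
summary.tagloss_fit <- function(object, ...) {
  p <- unlist(object$draws)
  posterior_summary(cbind(p = p, p_squared = p^2))
}

#' @export
print.tagloss_fit <- function(x, ...) {
  cat("Zero-truncated binomial tag-loss model\n")
  cat(sprintf("  recaptures: %d with both tags, %d with one tag\n",
              x$counts["n_double"], x$counts["n_single"]))
  s <- summary(x)
  cat(sprintf("  per-tag loss p: %.3f (95%% CRI [%.3f, %.3f])\n",
              s$estimate[1], s$lower[1], s$upper[1]))
  cat(sprintf("  double loss p^2: %.4f (95%% CRI [%.4f, %.4f])\n",
              s$estimate[2], s$lower[2], s$upper[2]))
  invisible(x)
}
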