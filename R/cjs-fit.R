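#' Prior configuration for the spike-and-slab CJS model
#'
#' Intercepts receive a vague Normal(0, \code{slab_sd}) prior. Each optional
#' coefficient receives the two-component mixture governed by its indicator:
#' Normal(0, \code{slab_sd}) when selected, Normal(0, \code{spike_sd}) (so
#' constrained that its value is effectively zero) when not, with the
#' indicator a priori Bernoulli(\code{indicator_prob}). The prior-sensitivity
#' refit doubles the slab to 6 and leaves the spike unchanged.
#'
#' @param slab_sd standard deviation of the vague component (default 3).
#' @param spike_sd standard deviation of the spike component (default 0.03).
#' @param indicator_prob prior inclusion probability (default 0.5).
#' @return list of class \code{"cjs_priors"}.
#' @export
cjs_priors <- function(slab_sd = 3, spike_sd = 0.03, indicator_prob = 0.5) {
  stopifnot(slab_sd > 0, spike_sd > 0, spike_sd < slab_sd,
            indicator_prob > 0, indicator_prob < 1)
  structure(list(slab_sd = slab_sd, spike_sd = spike_sd,
                 indicator_prob = indicator_prob), class = "cjs_priors")
}

#' MCMC configuration
#'
#' Defaults follow the estimation protocol of the analysis: five chains,
#' 1e5 iterations per chain with the first half discarded as burn-in, then
#' thinning to a grand total of \code{n_save} retained samples, and a
#' convergence requirement of R-hat at most \code{rhat_threshold} for every
#' parameter.
#'
#' @param n_chains number of chains.
#' @param n_iter iterations per chain (burn-in included).
#' @param n_save total retained samples across chains.
#' @param rhat_threshold within-model convergence limit.
#' @return list of class \code{"cjs_control"}.
#' @export
cjs_control <- function(n_chains = 5L, n_iter = 1e5L, n_save = 10000L,
                        rhat_threshold = 1.05) {
  stopifnot(n_chains >= 1, n_iter >= 20, n_save >= n_chains)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_save = as.integer(n_save),
                 rhat_threshold = rhat_threshold), class = "cjs_control")
}

#' Fit the state-space CJS model with indicator variable selection
#'
#' Samples the joint posterior of the eleven coefficients, seven selection
#' indicators and per-fish latent states by Markov chain Monte Carlo. The
#' sampler alternates (i) exact Gibbs draws of each fish's death time
#' (equivalently its whole alive trajectory), (ii) Bernoulli Gibbs draws of
#' unobserved spawning states, (iii) adaptive random-walk Metropolis updates
#' of the coefficients (adaptation restricted to burn-in), with an
#' additional independence proposal from the conditional prior that lets
#' coefficients jump between spike and slab scales, and (iv) Gibbs draws of
#' the indicators from their conjugate Bernoulli full conditionals.
#'
#' Chains are initialized at independent draws from the slab prior scaled by
#' 0.1, with all fish alive throughout their record. The random seed fully
#' determines the output; chain \code{c} uses substream \code{seed + c}.
#'
#' @param data an \code{encounter_data} data frame or \code{\link{cjs_data}}
#'   object (one species).
#' @param priors a \code{\link{cjs_priors}} object.
#' @param control a \code{\link{cjs_control}} object.
#' @param seed integer master seed.
#' @return An object of class \code{"cjs_fit"}: list with \code{draws} (a
#'   list of per-chain matrices, columns the coefficients, indicators and
#'   \code{loglik}), \code{rhat} (named vector), \code{converged},
#'   \code{data}, \code{priors}, \code{control}, \code{seed} and
#'   \code{accept} (mean Metropolis acceptance per coefficient).
#' @seealso \code{\link{summary.cjs_fit}}, \code{\link{predict.cjs_fit}},
#'   \code{\link{cjs_rhat}}
#' @export
cjs_fit <- function(data, priors = cjs_priors(), control = cjs_control(),
                    seed = 1L) {
  data <- as_cjs_data(data)
  stopifnot(inherits(priors, "cjs_priors"), inherits(control, "cjs_control"))
  if (all(is.na(data$y)) && all(is.na(data$m)))
    stop("degenerate data: no observations")
  n_burn <- control$n_iter %/% 2L
  n_keep <- max(1L, control$n_save %/% control$n_chains)
  thin <- max(1L, (control$n_iter - n_burn) %/% n_keep)
  prep <- cjs_cpp_arrays(data)
  draws <- vector("list", control$n_chains)
  accept <- 0
  for (ch in seq_len(control$n_chains)) {
    set.seed(as.integer(seed) + ch)
    beta0 <- stats::rnorm(11, 0, priors$slab_sd) * 0.1
    gamma0 <- stats::rbinom(7, 1, priors$indicator_prob)
    res <- cjs_run_chain(prep$first, prep$last, prep$y, prep$m, prep$Tmat,
                         prep$S, prep$xobs, prep$L, prep$Y,
                         priors$slab_sd, priors$spike_sd,
                         priors$indicator_prob,
                         control$n_iter, n_burn, thin, n_keep,
                         beta0, gamma0)
    colnames(res$draws) <- c(cjs_coef_names(), cjs_indicator_names(),
                             "loglik")
    draws[[ch]] <- res$draws
    accept <- accept + res$accept / control$n_chains
  }
  pars <- c(cjs_coef_names(), cjs_indicator_names())
  rhat <- vapply(pars, function(p) {
    cjs_rhat(lapply(draws, function(d) d[, p]))
  }, numeric(1))
  fit <- structure(list(draws = draws, rhat = rhat,
                        converged = all(rhat <= control$rhat_threshold),
                        data = data, priors = priors, control = control,
                        seed = seed, accept = stats::setNames(
                          accept, cjs_coef_names())),
                   class = "cjs_fit")
  if (!fit$converged)
    warning("chains may not have converged: max R-hat = ",
            signif(max(rhat), 4))
  fit
}

cjs_cpp_arrays <- function(data) {
  na2 <- function(m, fill) { m[is.na(m)] <- fill; m }
  list(first = data$first, last = data$last,
       y = na2(data$y, 0L), m = na2(data$m, -1L),
       Tmat = na2(data$Tmat, 0L), S = na2(data$S, 0L),
       xobs = na2(data$xobs, -1L),
       L = na2(data$L, 0), Y = na2(data$Y, 0))
}

#' Pooled posterior draws
#'
#' @param fit a \code{\link{cjs_fit}}.
#' @param pars optional character vector of parameter names.
#' @return matrix of retained draws, chains concatenated.
#' @export
cjs_draws <- function(fit, pars = NULL) {
  d <- do.call(rbind, fit$draws)
  if (!is.null(pars)) d <- d[, pars, drop = FALSE]
  d
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("State-space CJS model with indicator variable selection\n")
  cat(sprintf("  %d fish x %d periods; %d chains x %d iterations, %d draws retained\n",
              x$data$n, x$data$K, x$control$n_chains, x$control$n_iter,
              nrow(cjs_draws(x))))
  cat(sprintf("  max R-hat %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  b <- colMeans(cjs_draws(x, cjs_coef_names()))
  g <- colMeans(cjs_draws(x, cjs_indicator_names()))
  cat("Posterior mean coefficients:\n")
  print(round(b, 3))
  cat("Selection probabilities:\n")
  print(round(g, 3))
  invisible(x)
}

#' @export
coef.cjs_fit <- function(object, ...) {
  colMeans(cjs_draws(object, cjs_coef_names()))
}

#' Trace and density plots
#'
#' @param x a \code{\link{cjs_fit}}.
#' @param pars parameters to plot (default the four intercepts).
#' @param ... unused.
#' @export
plot.cjs_fit <- function(x, pars = c("beta_phi0", "beta_rho0",
                                     "beta_delta0", "beta_kappa0"), ...) {
  op <- graphics::par(mfrow = c(length(pars), 2),
                      mar = c(3, 4, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (p in pars) {
    rng <- range(unlist(lapply(x$draws, function(d) d[, p])))
    graphics::plot(x$draws[[1]][, p], type = "l", ylim = rng, ylab = p,
                   xlab = "", main = "")
    for (ch in seq_along(x$draws)[-1])
      graphics::lines(x$draws[[ch]][, p], col = ch)
    graphics::plot(stats::density(cjs_draws(x, p)), main = p, xlab = "")
  }
  invisible(x)
}

#' Posterior-predictive encounter histories
#'
#' Draws replicate encounter data sets from the fitted model, one per
#' requested simulation, each conditioned on a coefficient draw from the
#' posterior and on the observed design (first captures, monitoring and
#' spawn-season structure, covariates).
#'
#' @param object a \code{\link{cjs_fit}}.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of \code{encounter_data} data frames.
#' @export
simulate.cjs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- cjs_draws(object, cjs_coef_names())
  idx <- sample.int(nrow(d), nsim, replace = TRUE)
  lapply(seq_len(nsim), function(s)
    simulate_from_design(object$data, d[idx[s], ]))
}
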