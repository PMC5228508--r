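#' Linear predictors of the state-space CJS model
#'
#' Evaluates the four probabilities of the full model on the logit scale:
#' \deqn{logit(\phi) = \beta_{\phi 0} + \beta_{\phi x} x + \beta_{\phi Y} Y}
#' \deqn{logit(\rho) = \beta_{\rho 0} + \beta_{\rho Y} Y}
#' \deqn{logit(\delta) = \beta_{\delta 0} + \beta_{\delta S} S + \beta_{\delta Y} Y}
#' \deqn{logit(\kappa) = \beta_{\kappa 0} + \beta_{\kappa L} L + \beta_{\kappa Y} Y}
#' Coefficients whose indicator is currently 0 still enter through their
#' (spike-shrunk) value; no masking is applied here.
#'
#' @param beta named numeric vector of the eleven coefficients (see
#'   \code{\link{cjs_coef_names}}).
#' @param L length covariate, \code{(FL - 600)/100}.
#' @param Y standardized year.
#' @param S spawn-season indicator (0/1).
#' @param x spawning state (0/1).
#' @return list with elements \code{phi} (seasonal survival), \code{rho}
#'   (seasonal recapture), \code{delta} (movement detection) and \code{kappa}
#'   (spawning), each recycled to the common covariate length.
#' @examples
#' b <- setNames(rep(0, 11), cjs_coef_names())
#' linear_predictors(b, L = 0, Y = 0, S = 0, x = 0)  # all 0.5
#' @export
linear_predictors <- function(beta, L = 0, Y = 0, S = 0, x = 0) {
  beta <- check_beta(beta)
  list(
    phi = stats::plogis(beta["beta_phi0"] + beta["beta_phix"] * x +
                          beta["beta_phiY"] * Y),
    rho = stats::plogis(beta["beta_rho0"] + beta["beta_rhoY"] * Y),
    delta = stats::plogis(beta["beta_delta0"] + beta["beta_deltaS"] * S +
                            beta["beta_deltaY"] * Y),
    kappa = stats::plogis(beta["beta_kappa0"] + beta["beta_kappaL"] * L +
                            beta["beta_kappaY"] * Y))
}

check_beta <- function(beta) {
  nm <- cjs_coef_names()
  if (is.null(names(beta))) {
    stopifnot(length(beta) == length(nm))
    names(beta) <- nm
  }
  stopifnot(all(nm %in% names(beta)), all(is.finite(beta[nm])))
  beta[nm]
}

#' Joint log-density of data, latent states and parameters
#'
#' The unnormalized log posterior of the state-space CJS model at a complete
#' latent configuration: Bernoulli state transitions, the three observation
#' layers (angler recapture, movement detection while monitored, spawning
#' state in spawn-season periods) and, optionally, the spike-and-slab prior.
#' Latent configurations inconsistent with the data (an observation of 1
#' while dead, a revival, spawning out of season) have density \code{-Inf}.
#'
#' @param data a \code{\link{cjs_data}} object.
#' @param beta coefficient vector (see \code{\link{cjs_coef_names}}).
#' @param gamma named 0/1 vector of indicators (see
#'   \code{\link{cjs_indicator_names}}).
#' @param z integer n x K matrix of alive states (1 alive, 0 dead; \code{NA}
#'   outside each fish's record). \code{z[i, first[i]]} must be 1.
#' @param x integer n x K matrix of spawning states; must be 0 wherever the
#'   fish is dead or it is not the spawning season. Where the spawning state
#'   was observed the supplied value must match the observation.
#'
#' @details The model conditions on the release: \code{z} is 1 in the
#'   release period by definition and the observation layers (and the
#'   spawning process) apply from the following period on, so release-period
#'   observations carry no likelihood information and \code{x} is 0 in the
#'   release period.
#' @param priors a \code{\link{cjs_priors}} object.
#' @param include_prior include the prior terms (set \code{FALSE} to obtain
#'   the complete-data log likelihood).
#' @return A single number (possibly \code{-Inf}).
#' @export
log_joint <- function(data, beta, gamma, z, x, priors = cjs_priors(),
                      include_prior = TRUE) {
  data <- as_cjs_data(data)
  beta <- check_beta(beta)
  gamma <- check_gamma(gamma)
  ll <- 0
  for (i in seq_len(data$n)) {
    f <- data$first[i]; l <- data$last[i]
    zi <- z[i, f:l]; xi <- x[i, f:l]
    Si <- data$S[i, f:l]
    if (zi[1] != 1L) return(-Inf)
    if (xi[1] != 0L) return(-Inf)  # spawning process starts after release
    if (any(xi == 1L & (zi == 0L | Si == 0L))) return(-Inf)
    xo <- data$xobs[i, f:l]
    xo[1] <- NA_integer_
    if (any(!is.na(xo) & xo != xi)) return(-Inf)
    p <- linear_predictors(beta, L = data$L[i, f:l], Y = data$Y[i, f:l],
                           S = Si, x = xi)
    if (l > f) {
      ll <- ll + sum(stats::dbinom(zi[-1], 1,
                                   zi[-length(zi)] * p$phi[-length(zi)],
                                   log = TRUE))
      # observation layers apply after the release period
      post <- 2:length(zi)
      ll <- ll + sum(stats::dbinom(data$y[i, f:l][post], 1,
                                   (zi * p$rho)[post], log = TRUE))
      mon <- post[data$Tmat[i, f:l][post] == 1L &
                    !is.na(data$m[i, f:l][post])]
      if (length(mon))
        ll <- ll + sum(stats::dbinom(data$m[i, f:l][mon], 1,
                                     (zi * p$delta)[mon], log = TRUE))
      sp <- post[Si[post] == 1L]
      if (length(sp))
        ll <- ll + sum(stats::dbinom(xi[sp], 1, (zi * p$kappa)[sp],
                                     log = TRUE))
    }
    if (!is.finite(ll)) return(-Inf)
  }
  if (include_prior) ll <- ll + cjs_log_prior(beta, gamma, priors)
  ll
}

check_gamma <- function(gamma) {
  nm <- cjs_indicator_names()
  if (is.null(names(gamma))) {
    stopifnot(length(gamma) == length(nm))
    names(gamma) <- nm
  }
  stopifnot(all(gamma[nm] %in% c(0, 1)))
  gamma[nm]
}

#' @rdname log_joint
#' @export
cjs_log_prior <- function(beta, gamma, priors = cjs_priors()) {
  beta <- check_beta(beta)
  gamma <- check_gamma(gamma)
  intercepts <- c("beta_phi0", "beta_rho0", "beta_delta0", "beta_kappa0")
  lp <- sum(stats::dnorm(beta[intercepts], 0, priors$slab_sd, log = TRUE))
  sds <- ifelse(gamma == 1, priors$slab_sd, priors$spike_sd)
  lp <- lp + sum(stats::dnorm(beta[cjs_indicator_map()], 0, sds, log = TRUE))
  lp + sum(stats::dbinom(gamma, 1, priors$indicator_prob, log = TRUE))
}

#' Marginal log likelihood by the forward algorithm
#'
#' Analytically sums the latent alive states (and any unobserved spawning
#' states) out of the model by a per-fish forward recursion over
#' \code{z in \{0, 1\}}. In spawn-season periods with an unobserved spawning
#' state, the survival term is the mixture over \code{x} weighted by the
#' spawning probability. Used as the small-instance oracle for the sampler
#' and for prior-free likelihood checks; it equals the log of the sum of
#' \code{exp(log_joint(..., include_prior = FALSE))} over all latent
#' configurations.
#'
#' @inheritParams log_joint
#' @return The log marginal likelihood of the observed data.
#' @export
marginal_loglik <- function(data, beta) {
  data <- as_cjs_data(data)
  beta <- check_beta(beta)
  total <- 0
  for (i in seq_len(data$n)) {
    f <- data$first[i]; l <- data$last[i]
    p <- linear_predictors(beta, L = data$L[i, f:l], Y = data$Y[i, f:l],
                           S = data$S[i, f:l], x = 0)
    # spawn-period survival at x = 1 (only the phi_x term changes)
    p1 <- linear_predictors(beta, L = data$L[i, f:l], Y = data$Y[i, f:l],
                            S = data$S[i, f:l], x = 1)
    nt <- l - f + 1L
    yv <- data$y[i, f:l]; mv <- data$m[i, f:l]; Tv <- data$Tmat[i, f:l]
    Sv <- data$S[i, f:l]; xo <- data$xobs[i, f:l]
    # alpha over z at current period; start alive with certainty
    alpha <- c(dead = 0, alive = 1)
    logscale <- 0
    for (tloc in seq_len(nt)) {
      first_period <- tloc == 1L  # release period: no observation layers
      # emission excluding the x-layer (x handled with the transition)
      e_alive <- if (first_period) 1 else stats::dbinom(yv[tloc], 1,
                                                        p$rho[tloc])
      e_dead <- if (yv[tloc] == 0L || first_period) 1 else 0
      if (!first_period && Tv[tloc] == 1L && !is.na(mv[tloc])) {
        e_alive <- e_alive * stats::dbinom(mv[tloc], 1, p$delta[tloc])
        e_dead <- e_dead * (if (mv[tloc] == 0L) 1 else 0)
      }
      # x-layer and transition, jointly
      phi_mix <- function(zn) {
        # returns P(x-layer, z_next = zn | alive at t)
        if (Sv[tloc] == 1L && !first_period) {
          kap <- p$kappa[tloc]
          if (!is.na(xo[tloc])) {
            px <- stats::dbinom(xo[tloc], 1, kap)
            phi <- if (xo[tloc] == 1L) p1$phi[tloc] else p$phi[tloc]
            px * stats::dbinom(zn, 1, phi)
          } else {
            (1 - kap) * stats::dbinom(zn, 1, p$phi[tloc]) +
              kap * stats::dbinom(zn, 1, p1$phi[tloc])
          }
        } else {
          stats::dbinom(zn, 1, p$phi[tloc])
        }
      }
      x_dead <- if (!first_period && Sv[tloc] == 1L && !is.na(xo[tloc]) &&
                      xo[tloc] == 1L)
        0 else 1  # dead fish cannot be observed spawning
      x_alive_final <- if (!first_period && Sv[tloc] == 1L &&
                             !is.na(xo[tloc]))
        stats::dbinom(xo[tloc], 1, p$kappa[tloc]) else 1
      if (tloc < nt) {
        new_alive <- alpha["alive"] * e_alive
        alpha <- c(
          dead = unname(alpha["dead"] * e_dead * x_dead +
                          new_alive * phi_mix(0L)),
          alive = unname(new_alive * phi_mix(1L)))
      } else {
        alpha <- c(dead = unname(alpha["dead"] * e_dead * x_dead),
                   alive = unname(alpha["alive"] * e_alive * x_alive_final))
      }
      s <- sum(alpha)
      if (s == 0) return(-Inf)
      logscale <- logscale + log(s)
      alpha <- alpha / s
    }
    total <- total + logscale
  }
  total
}
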