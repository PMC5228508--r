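#' Seasonal to annual interval probabilities
#'
#' Converts a seasonal (quarterly) probability to the annual interval scale:
#' survival compounds across the four seasons (\eqn{p^4}); recapture is the
#' complement of escaping capture in all four (\eqn{1 - (1-p)^4}).
#'
#' @param p seasonal probability in \[0, 1\].
#' @param kind \code{"survival"} or \code{"recapture"}.
#' @return annual interval probability.
#' @examples
#' annual_interval(plogis(-3.065), "recapture")  # ~0.17
#' @export
annual_interval <- function(p, kind = c("survival", "recapture")) {
  kind <- match.arg(kind)
  stopifnot(all(p >= 0 & p <= 1))
  if (kind == "survival") p^4 else 1 - (1 - p)^4
}

#' Annual survival of a spawner
#'
#' A fish that spawns experiences the spawning survival in its single
#' spawning-season period and the non-spawning survival in the other three:
#' \eqn{\phi_{ns}^3 \phi_{sp}}.
#'
#' @param phi_ns seasonal survival outside the spawning season.
#' @param phi_sp seasonal survival in the spawning season (spawning state 1).
#' @return annual interval survival probability.
#' @export
annual_survival_spawner <- function(phi_ns, phi_sp) {
  stopifnot(all(phi_ns >= 0 & phi_ns <= 1), all(phi_sp >= 0 & phi_sp <= 1))
  phi_ns^3 * phi_sp
}

#' Instantaneous mortality rates
#'
#' Converts annual interval probabilities to instantaneous rates: if all
#' recaptures are harvested, the fishing mortality is
#' \eqn{F = -\log(1 - \rho)}; the natural mortality is
#' \eqn{M = -\log(\phi)}.
#'
#' @param rho_annual annual interval recapture probability in \[0, 1).
#' @param phi_annual annual interval survival probability in (0, 1\].
#' @return rate per year.
#' @export
instantaneous_F <- function(rho_annual) {
  stopifnot(all(rho_annual >= 0))
  if (any(rho_annual >= 1)) stop("rho = 1 gives an infinite rate")
  -log(1 - rho_annual)
}

#' @rdname instantaneous_F
#' @export
instantaneous_M <- function(phi_annual) {
  stopifnot(all(phi_annual <= 1))
  if (any(phi_annual <= 0)) stop("phi = 0 gives an infinite rate")
  -log(phi_annual)
}

#' Effective annual interval fishing mortality
#'
#' Scales the annual interval recapture probability by the fraction of
#' captures actually harvested (1 minus the release rate), assuming released
#' fish survive.
#'
#' @param rho_annual annual interval recapture probability.
#' @param release_rate fraction of captured fish released, in \[0, 1\].
#' @return effective annual interval fishing mortality.
#' @examples
#' effective_interval_F(0.17, 0.40)  # ~0.10
#' @export
effective_interval_F <- function(rho_annual, release_rate) {
  stopifnot(all(rho_annual >= 0 & rho_annual <= 1),
            all(release_rate >= 0 & release_rate <= 1))
  rho_annual * (1 - release_rate)
}

#' Catchability and density from recapture probability and creel estimates
#'
#' Catchability is the probability of capture per unit angler effort,
#' \eqn{q = \rho / E}; given the annual catch \eqn{C}, the implied density
#' is \eqn{D = (C / \rho) / A} fish per hectare over lake area \eqn{A}.
#'
#' @param rho_annual annual interval recapture probability.
#' @param E angler effort (angler-hr per ha per yr), > 0.
#' @param C annual catch (fish).
#' @param area_ha lake area (ha); the study lake is 38,800 ha.
#' @return \code{catchability()}: q (per angler-hr per ha per yr);
#'   \code{fish_density()}: D (fish per ha).
#' @export
catchability <- function(rho_annual, E) {
  stopifnot(all(E > 0), all(rho_annual >= 0 & rho_annual <= 1))
  rho_annual / E
}

#' @rdname catchability
#' @export
fish_density <- function(C, rho_annual, area_ha = 38800) {
  stopifnot(all(C > 0), all(area_ha > 0))
  if (any(rho_annual <= 0)) stop("rho = 0 gives an infinite density")
  (C / rho_annual) / area_ha
}

#' Empirical (indirect) natural mortality estimators
#'
#' Life-history based approximations of the annual instantaneous natural
#' mortality: the maximum-age estimator
#' \eqn{M = 4.899 \, t_{max}^{-0.916}} and the growth-based estimator
#' \eqn{M = 4.188 \, k^{0.73} L_\infty^{-0.33}}.
#'
#' @param t_max maximum age (yr).
#' @param k Von Bertalanffy growth coefficient (per yr).
#' @param L_inf asymptotic length (mm).
#' @return rate per year.
#' @examples
#' empirical_M_tmax(8)             # ~0.73
#' empirical_M_growth(0.19, 1000)  # ~0.13
#' @export
empirical_M_tmax <- function(t_max) {
  stopifnot(all(t_max > 0))
  4.899 * t_max^-0.916
}

#' @rdname empirical_M_tmax
#' @export
empirical_M_growth <- function(k, L_inf) {
  stopifnot(all(k > 0), all(L_inf > 0))
  4.188 * k^0.73 * L_inf^-0.33
}

#' Hyperstability prediction of catchability
#'
#' The density-dependent catchability relationship fitted to Lake Trout
#' recreational fisheries:
#' \eqn{q = \exp(-0.14 E / (1 + 0.35 D)) / E}. As density grows, q
#' approaches 1/E; at low density and high effort, q collapses.
#'
#' @param E angler effort (angler-hr per ha per yr), > 0.
#' @param D density (fish per ha), >= 0.
#' @return predicted catchability.
#' @examples
#' hyperstability_q(4.88, 0.75)  # ~0.12
#' @export
hyperstability_q <- function(E, D) {
  stopifnot(all(E > 0), all(D >= 0))
  exp(-(0.14 * E) / (1 + 0.35 * D)) / E
}
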