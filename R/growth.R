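#' Von Bertalanffy growth parameters
#'
#' Default seasonal growth assumptions for the two study species: an
#' asymptotic fork length of 1,000 mm with a growth coefficient of 0.13 per
#' year for Bull Trout and 0.19 per year for Rainbow Trout.
#'
#' @param species \code{"BullTrout"} or \code{"RainbowTrout"}; ignored if
#'   \code{L_inf} and \code{k} are both supplied.
#' @param L_inf asymptotic length (mm).
#' @param k growth coefficient (per year).
#' @return list of class \code{"growth_params"} with \code{L_inf} and
#'   \code{k}.
#' @export
growth_params <- function(species = c("BullTrout", "RainbowTrout"),
                          L_inf = 1000, k = NULL) {
  species <- match.arg(species)
  if (is.null(k)) k <- if (species == "BullTrout") 0.13 else 0.19
  stopifnot(L_inf > 0, k > 0)
  structure(list(L_inf = L_inf, k = k, species = species),
            class = "growth_params")
}

#' Calculated fork length under seasonal Von Bertalanffy growth
#'
#' Projects a fish's fork length from its measured length at capture to later
#' seasonal periods:
#' \deqn{L_t = L_f + (L_\infty - L_f)(1 - e^{-0.25 k (t - f)})}
#' where the factor 0.25 converts the annual growth coefficient \eqn{k} to
#' the quarterly period scale (four seasons per year).
#'
#' @param L_at_capture measured fork length at capture (mm).
#' @param f period of first capture.
#' @param t period(s) at which to evaluate the length; \code{t >= f}.
#' @param params a \code{\link{growth_params}} object.
#' @return Fork length(s) in mm, non-decreasing in \code{t} and bounded by
#'   \code{params$L_inf}.
#' @examples
#' vb_length(650, 1, 5, growth_params("RainbowTrout"))
#' @export
vb_length <- function(L_at_capture, f, t, params) {
  stopifnot(inherits(params, "growth_params"),
            L_at_capture <= params$L_inf)
  if (any(t < f)) stop("t must be >= the capture period f")
  L_at_capture + (params$L_inf - L_at_capture) *
    (1 - exp(-0.25 * params$k * (t - f)))
}

#' Length covariate transform
#'
#' The fork-length covariate entering the spawning submodel:
#' \code{(FL - 600) / 100}, i.e. centred at 600 mm and scaled to 100 mm
#' units.
#'
#' @param FL calculated fork length (mm).
#' @return Unitless covariate.
#' @export
length_covariate <- function(FL) {
  stopifnot(all(FL > 0))
  (FL - 600) / 100
}

#' Standardized year covariate
#'
#' Centres and scales the calendar year over the modeled periods. By default
#' each distinct calendar year is weighted equally and the sample (n - 1)
#' standard deviation is used; all periods within a year share one value.
#'
#' @param calendar a \code{\link{period_calendar}} (or any data frame with a
#'   \code{year} column ordered by period).
#' @param by standardize over \code{"years"} (distinct calendar years,
#'   default) or \code{"periods"} (every period's year value, so years with
#'   more periods weigh more).
#' @return Numeric vector along the rows of \code{calendar}.
#' @export
standardize_year <- function(calendar, by = c("years", "periods")) {
  by <- match.arg(by)
  yr <- calendar$year
  base <- if (by == "years") sort(unique(yr)) else yr
  if (length(unique(base)) < 2L)
    stop("at least two distinct calendar years are required")
  (yr - mean(base)) / stats::sd(base)
}
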