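#' Model coefficient and indicator names
#'
#' The eleven log-odds coefficients of the full model and the seven
#' selection indicators attached to its optional terms, in the canonical
#' order used throughout the package. Intercepts (\code{beta_phi0},
#' \code{beta_rho0}, \code{beta_delta0}, \code{beta_kappa0}) always carry the
#' vague prior; every other coefficient has a spike-and-slab mixture prior
#' governed by its indicator.
#'
#' @name cjs_parameters
#' @return \code{cjs_coef_names()} and \code{cjs_indicator_names()} return
#'   character vectors.
NULL

#' @rdname cjs_parameters
#' @export
cjs_coef_names <- function() {
  c("beta_phi0", "beta_phix", "beta_phiY",
    "beta_rho0", "beta_rhoY",
    "beta_delta0", "beta_deltaS", "beta_deltaY",
    "beta_kappa0", "beta_kappaL", "beta_kappaY")
}

#' @rdname cjs_parameters
#' @export
cjs_indicator_names <- function() {
  c("gamma_phix", "gamma_phiY", "gamma_rhoY",
    "gamma_deltaS", "gamma_deltaY", "gamma_kappaL", "gamma_kappaY")
}

# position of each indicator's coefficient in the coefficient vector
cjs_indicator_map <- function() c(2L, 3L, 5L, 7L, 8L, 10L, 11L)

#' Assemble encounter histories into model arrays
#'
#' Converts the long-format encounter data produced by
#' \code{\link{build_encounter_data}} (or \code{\link{simulate_encounters}})
#' into the rectangular per-fish by per-period arrays consumed by the
#' sampler and the likelihood functions.
#'
#' @param encounters an \code{encounter_data} data frame for a single
#'   species: columns \code{fish_id}, \code{period}, \code{monitored},
#'   \code{moved}, \code{reported}, \code{spawned}, \code{spawn_season},
#'   \code{length_mm}, \code{year_std}.
#' @return An object of class \code{"cjs_data"}: a list with \code{n},
#'   \code{K}, \code{first}, \code{last}, and \code{n x K} matrices \code{y},
#'   \code{m}, \code{Tmat}, \code{S}, \code{xobs} (integer; \code{NA} where
#'   undefined or unobserved), \code{L} (length covariate, (FL-600)/100) and
#'   \code{Y} (standardized year).
#' @export
cjs_data <- function(encounters) {
  enc <- as.data.frame(encounters)
  req_cols(enc, c("fish_id", "period", "monitored", "moved", "reported",
                  "spawn_season", "length_mm", "year_std"), "encounters")
  if (is.null(enc$spawned)) enc$spawned <- NA_integer_
  if (!is.null(enc$species) && length(unique(enc$species)) > 1L)
    stop("encounter data contains more than one species; fit them separately")
  ids <- unique(enc$fish_id)
  n <- length(ids)
  K <- max(enc$period)
  mk <- function(init) matrix(init, n, K, dimnames = list(ids, NULL))
  y <- mk(NA_integer_); m <- mk(NA_integer_); Tmat <- mk(NA_integer_)
  S <- mk(NA_integer_); xobs <- mk(NA_integer_)
  L <- mk(NA_real_); Y <- mk(NA_real_)
  i <- match(enc$fish_id, ids)
  idx <- cbind(i, enc$period)
  y[idx] <- enc$reported
  m[idx] <- enc$moved
  Tmat[idx] <- enc$monitored
  S[idx] <- enc$spawn_season
  xobs[idx] <- enc$spawned
  L[idx] <- length_covariate(enc$length_mm)
  Y[idx] <- enc$year_std
  first <- tapply(enc$period, i, min)[as.character(seq_len(n))]
  last <- tapply(enc$period, i, max)[as.character(seq_len(n))]
  first <- as.integer(first); last <- as.integer(last)
  # invariants
  if (any(tapply(enc$reported, i, sum) > 1L))
    stop("a fish is reported recaptured in more than one period")
  rec <- tapply(seq_len(nrow(enc)), i, function(r) {
    w <- which(enc$reported[r] == 1L)
    if (length(w) && enc$period[r][w] != max(enc$period[r]))
      stop("periods after a reported recapture must be censored")
  })
  if (any(!is.na(m) & is.na(Tmat)))
    stop("movement recorded outside the fish's record")
  bad <- !is.na(m) & !is.na(Tmat) & Tmat == 0L & !is.na(m)
  if (any(m[bad] %in% c(0L, 1L)))
    stop("movement (moved) must be NA in unmonitored periods")
  structure(list(n = n, K = K, fish_id = ids, first = first, last = last,
                 y = y, m = m, Tmat = Tmat, S = S, xobs = xobs,
                 L = L, Y = Y,
                 species = if (!is.null(enc$species)) enc$species[1] else NA),
            class = "cjs_data")
}

#' @export
print.cjs_data <- function(x, ...) {
  cat("CJS encounter data:", x$n, "fish x", x$K, "periods\n")
  cat("  recaptures:", sum(x$y == 1L, na.rm = TRUE),
      " monitored fish-periods:", sum(x$Tmat == 1L, na.rm = TRUE),
      " spawn-season fish-periods:", sum(x$S == 1L, na.rm = TRUE), "\n")
  invisible(x)
}

as_cjs_data <- function(data) {
  if (inherits(data, "cjs_data")) data else cjs_data(data)
}
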