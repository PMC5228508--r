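# shared fixtures and independent oracles, built in code

# a two-fish, three-period encounter frame with one recapture, one observed
# spawning state, and one unmonitored (anchor-only) fish
tiny_encounters <- function() {
  data.frame(
    fish_id = rep(c("F1", "F2"), c(3, 2)), species = "BullTrout",
    period = c(1, 2, 3, 2, 3), year = 2008,
    season = c("winter", "spring", "summer", "spring", "summer"),
    monitored = c(1, 1, 1, 0, 0), moved = c(NA, 0L, 1L, NA, NA),
    reported = c(0, 0, 1, 0, 0), spawned = c(NA, NA, 1L, NA, NA),
    spawn_season = c(0, 0, 1, 0, 1), length_mm = c(650, 660, 670, 700, 705),
    year_std = c(-1, -1, -1, 1, 1))
}

tiny_beta <- function() {
  stats::setNames(c(1.2, -0.5, 0.2, -2, 0.1, 1.5, -1, 0.05, 0.6, 0.8, -0.2),
                  cjs_coef_names())
}

tiny_gamma <- function() {
  stats::setNames(c(1, 0, 1, 1, 0, 1, 0), cjs_indicator_names())
}

# brute-force marginal likelihood: enumerate every latent configuration
# (alive states after release, unobserved spawning states after release) and
# log-sum-exp the prior-free joint density; independent of the forward
# recursion it checks
enum_marginal <- function(cd, beta, gamma) {
  stopifnot(inherits(cd, "cjs_data"))
  zbits <- do.call(rbind, lapply(seq_len(cd$n), function(i)
    if (cd$last[i] > cd$first[i])
      cbind(i, (cd$first[i] + 1):cd$last[i]) else NULL))
  lat <- which(cd$S == 1L & is.na(cd$xobs), arr.ind = TRUE)
  if (nrow(lat)) lat <- lat[lat[, 2] > cd$first[lat[, 1]], , drop = FALSE]
  nb <- nrow(zbits) + nrow(lat)
  stopifnot(nb <= 14)  # keep enumeration tractable
  pri <- cjs_log_prior(beta, gamma)
  grid <- expand.grid(rep(list(0:1), nb))
  vals <- apply(grid, 1, function(bits) {
    z <- matrix(NA_integer_, cd$n, cd$K)
    z[cbind(seq_len(cd$n), cd$first)] <- 1L
    if (nrow(zbits)) z[zbits] <- as.integer(bits[seq_len(nrow(zbits))])
    x <- matrix(0L, cd$n, cd$K)
    obs1 <- which(!is.na(cd$xobs) & cd$xobs == 1L, arr.ind = TRUE)
    if (nrow(obs1)) {
      obs1 <- obs1[obs1[, 2] > cd$first[obs1[, 1]], , drop = FALSE]
      x[obs1] <- 1L
    }
    if (nrow(lat))
      x[lat] <- as.integer(bits[nrow(zbits) + seq_len(nrow(lat))])
    log_joint(cd, beta, gamma, z, x) - pri
  })
  mx <- max(vals[is.finite(vals)])
  mx + log(sum(exp(vals - mx)))
}

# small raw-bundle design for prep tests
prep_design <- function(species = "BullTrout", n = 12) {
  sim_design(species, years = 2008:2010, n_per_year = ceiling(n / 3),
             acoustic_years = 2008:2010, tag_life_days = 4000,
             n_noise = 50L, n_late = 10L)
}
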