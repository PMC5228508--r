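# sampler correctness checks at small scale; the full-scale recovery,
# selection and coverage checks live in test-acceptance.R

test_that("with no post-release information the posterior is the prior", {
  # every fish first captured in the final period: no transitions, no
  # usable observations, so beta_rho0 must reproduce its Normal(0, 3) prior
  enc <- do.call(rbind, lapply(1:5, function(i)
    data.frame(fish_id = paste0("A", i), species = "BullTrout", period = 4,
               year = 2008, season = "autumn", monitored = 1L,
               moved = NA_integer_, reported = 0L, spawned = NA_integer_,
               spawn_season = 0L, length_mm = 650, year_std = 0)))
  fit <- cjs_fit(enc, control = cjs_control(n_chains = 4, n_iter = 30000,
                                            n_save = 8000), seed = 5)
  d <- cjs_draws(fit, "beta_rho0")
  expect_lt(abs(mean(d)), 0.45)
  expect_gt(sd(d), 2.5)
  expect_lt(sd(d), 3.5)
  # spike behaviour: conditional on a zero indicator the coefficient is
  # confined to the spike scale
  g <- cjs_draws(fit, "gamma_rhoY")
  b <- cjs_draws(fit, "beta_rhoY")
  expect_lt(sd(b[g == 0]), 0.03 * 1.1)
})

test_that("the sampler matches an importance-sampling oracle on tiny data", {
  cd <- cjs_data(tiny_encounters())
  fit <- cjs_fit(cd, control = cjs_control(n_chains = 4, n_iter = 40000,
                                           n_save = 8000), seed = 9)
  # oracle: draw (gamma, beta) from the prior, weight by the marginal
  # likelihood with latent states summed out analytically
  set.seed(99)
  R <- 20000
  pri <- cjs_priors()
  imap <- c(2L, 3L, 5L, 7L, 8L, 10L, 11L)
  g <- matrix(rbinom(R * 7, 1, pri$indicator_prob), R, 7)
  b <- matrix(rnorm(R * 11, 0, pri$slab_sd), R, 11)
  for (k in seq_along(imap))
    b[g[, k] == 0, imap[k]] <- rnorm(sum(g[, k] == 0), 0, pri$spike_sd)
  lw <- apply(b, 1, function(bb)
    marginal_loglik(cd, stats::setNames(bb, cjs_coef_names())))
  w <- exp(lw - max(lw)); w <- w / sum(w)
  ess <- 1 / sum(w^2)
  expect_gt(ess, 500)  # the oracle itself must be reliable
  is_mean <- colSums(b * w)
  mc <- colMeans(cjs_draws(fit, cjs_coef_names()))
  expect_lt(abs(mc["beta_phi0"] - is_mean[1]), 0.25)
  expect_lt(abs(mc["beta_rho0"] - is_mean[4]), 0.25)
  expect_lt(abs(mc["beta_delta0"] - is_mean[6]), 0.25)
  is_g <- colSums(g * w)
  mcg <- colMeans(cjs_draws(fit, cjs_indicator_names()))
  expect_lt(max(abs(mcg - is_g)), 0.1)
})

test_that("fits are reproducible from the seed", {
  d <- sim_design("BullTrout", years = 2008:2009, n_per_year = 8,
                  tag_life_days = 4000)
  enc <- simulate_encounters(d, seed = 3)
  f1 <- cjs_fit(enc, control = cjs_control(n_chains = 2, n_iter = 2000,
                                           n_save = 400), seed = 21)
  f2 <- cjs_fit(enc, control = cjs_control(n_chains = 2, n_iter = 2000,
                                           n_save = 400), seed = 21)
  expect_identical(f1$draws, f2$draws)
})

test_that("degenerate data without observations is refused", {
  enc <- data.frame(fish_id = "A", species = "BullTrout", period = 1,
                    year = 2008, season = "winter", monitored = 0L,
                    moved = NA_integer_, reported = 0L,
                    spawned = NA_integer_, spawn_season = 0L,
                    length_mm = 650, year_std = 0)
  cd <- cjs_data(enc)
  cd$y[] <- NA_integer_
  expect_error(cjs_fit(cd), "degenerate")
})

test_that("fit methods expose coefficients, summaries and predictions", {
  d <- sim_design("BullTrout", years = 2008:2010, n_per_year = 15,
                  tag_life_days = 4000)
  enc <- simulate_encounters(d, seed = 8)
  fit <- cjs_fit(enc, control = cjs_control(n_chains = 2, n_iter = 4000,
                                            n_save = 1000), seed = 13)
  expect_named(coef(fit), cjs_coef_names())
  s <- summary(fit)
  expect_s3_class(s, "summary.cjs_fit")
  expect_equal(nrow(s), 18L)
  expect_true(all(s$lower <= s$upper))
  pr <- predict(fit, "survival", scale = "annual")
  expect_true(pr$estimate > 0 && pr$estimate < 1)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]], "encounter_data")
  expect_output(print(fit), "indicator variable selection")
})
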