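test_that("R-hat separates mixed from divergent chains", {
  set.seed(4)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(cjs_rhat(list(a, b)), 1.01)
  expect_gt(cjs_rhat(list(a, b + 10)), 1.05)
  # zero-variance chains by convention
  expect_equal(cjs_rhat(list(rep(1, 100), rep(1, 100))), 1)
  # matches an independently coded between/within formula on AR(1) chains
  ar <- function(n, rho) {
    x <- numeric(n)
    for (t in 2:n) x[t] <- rho * x[t - 1] + rnorm(1)
    x
  }
  chains <- lapply(1:4, function(i) ar(500, 0.6) + i / 10)
  m <- length(chains); n <- length(chains[[1]])
  W <- mean(sapply(chains, var))
  B <- n * var(sapply(chains, mean))
  ref <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(cjs_rhat(chains), ref)
})

test_that("between-model R-hat flags altered posteriors only", {
  set.seed(6)
  A <- cbind(beta_phi0 = rnorm(4000, 1, 0.3), beta_rho0 = rnorm(4000, -3, 0.2))
  expect_lt(max(between_model_rhat(A, A)), 1.0001)
  B <- A; B[, "beta_phi0"] <- B[, "beta_phi0"] + 2
  r <- between_model_rhat(A, B)
  expect_gt(r["beta_phi0"], 1.2)
  expect_lt(r["beta_rho0"], 1.05)
  expect_error(between_model_rhat(A, B[, 1, drop = FALSE],
                                  pars = colnames(A)), "absent")
})

test_that("prior-sensitivity refit leaves posteriors essentially unchanged", {
  d <- sim_design("BullTrout", years = 2008:2010, n_per_year = 14,
                  tag_life_days = 4000)
  enc <- simulate_encounters(d, seed = 12)
  ctl <- cjs_control(n_chains = 3, n_iter = 8000, n_save = 3000)
  fit3 <- cjs_fit(enc, priors = cjs_priors(slab_sd = 3), control = ctl,
                  seed = 31)
  fit6 <- cjs_fit(enc, priors = cjs_priors(slab_sd = 6), control = ctl,
                  seed = 32)
  r <- between_model_rhat(fit3, fit6,
                          pars = c("beta_phi0", "beta_rho0", "beta_delta0"))
  expect_lt(max(r), 1.2)
})

test_that("posterior summaries follow the reported table conventions", {
  set.seed(7)
  n <- 10000
  draws <- cbind(beta_delta0 = rnorm(n, 2.358, 0.200),
                 beta_rho0 = rnorm(n, -3.065, 0.202),
                 sym = rnorm(n, 0, 1))
  s <- posterior_summary(draws)
  # percent relative error: half the CRI width over |mean|, 2 significant
  # figures -- 17 and 13 for the two reported rows
  expect_equal(s$error[s$parameter == "beta_delta0"], 17)
  expect_equal(s$error[s$parameter == "beta_rho0"], 13)
  # significance is floored at 1/n_draws for one-sided posteriors
  expect_equal(s$significance[s$parameter == "beta_delta0"], 1e-4)
  # symmetric posteriors are insignificant
  expect_gt(s$significance[s$parameter == "sym"], 0.9)
  expect_true(all(s$significance >= 1 / n & s$significance <= 1))
  # order of chain concatenation is irrelevant
  s2 <- posterior_summary(draws[sample.int(n), , drop = FALSE])
  expect_equal(s$estimate, s2$estimate)
  expect_equal(s$error, s2$error)
  # a zero point estimate has undefined relative error
  expect_equal(posterior_summary(cbind(z = c(-1, 1)))$error, Inf)
})

test_that("derived quantities are posterior means of the transform", {
  set.seed(8)
  draws <- matrix(rlnorm(5000, 0, 1), ncol = 1,
                  dimnames = list(NULL, "beta_phi0"))
  draws <- cbind(draws, matrix(0, 5000, 10))
  colnames(draws) <- cjs_coef_names()
  sq <- predict_quantity(draws, function(b) unname(b["beta_phi0"])^2)
  # mean of the square, not square of the mean
  expect_equal(sq$estimate, mean(draws[, 1]^2))
  expect_gt(sq$estimate, mean(draws[, 1])^2)
  # identity transform reduces to the plain summary
  id <- predict_quantity(draws, function(b) unname(b["beta_phi0"]))
  expect_equal(id$estimate, mean(draws[, 1]))
})
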