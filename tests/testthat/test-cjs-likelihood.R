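test_that("linear predictors evaluate the four logit forms", {
  b0 <- stats::setNames(rep(0, 11), cjs_coef_names())
  p <- linear_predictors(b0, L = 2, Y = -1, S = 1, x = 1)
  expect_equal(unname(unlist(p)), rep(0.5, 4))
  # reported Bull Trout spawning-season movement probability ~0.49
  b <- b0
  b["beta_delta0"] <- 2.358
  b["beta_deltaS"] <- -2.399
  expect_equal(round(unname(linear_predictors(b, S = 1)$delta), 2), 0.49)
  # random coefficients against an independent sigmoid evaluation
  set.seed(11)
  for (r in 1:5) {
    b <- stats::setNames(rnorm(11), cjs_coef_names())
    L <- runif(1, -1, 2); Y <- rnorm(1); S <- rbinom(1, 1, 0.5)
    x <- rbinom(1, 1, 0.5)
    p <- linear_predictors(b, L = L, Y = Y, S = S, x = x)
    expect_equal(unname(p$phi),
                 as.numeric(1 / (1 + exp(-(b[1] + b[2] * x + b[3] * Y)))))
    expect_equal(unname(p$kappa),
                 as.numeric(1 / (1 + exp(-(b[9] + b[10] * L + b[11] * Y)))))
  }
})

test_that("joint density is -Inf for impossible latent configurations", {
  cd <- cjs_data(tiny_encounters())
  beta <- tiny_beta(); gam <- tiny_gamma()
  z <- matrix(NA_integer_, 2, 3); x <- matrix(0L, 2, 3)
  z[1, ] <- c(1L, 1L, 1L); z[2, 2:3] <- c(1L, 1L)
  x[1, 3] <- 1L  # matches the observed spawning state
  expect_true(is.finite(log_joint(cd, beta, gam, z, x)))
  # dead before the reported recapture
  z2 <- z; z2[1, 2:3] <- 0L
  expect_identical(log_joint(cd, beta, gam, z2, x), -Inf)
  # revival
  z3 <- z; z3[1, 2] <- 0L
  expect_identical(log_joint(cd, beta, gam, z3, x), -Inf)
  # latent spawning out of season
  x4 <- x; x4[1, 2] <- 1L
  expect_identical(log_joint(cd, beta, gam, z, x4), -Inf)
  # contradicting an observed spawning state
  x5 <- x; x5[1, 3] <- 0L
  expect_identical(log_joint(cd, beta, gam, z, x5), -Inf)
})

test_that("a fish with no post-release data contributes only the prior", {
  enc <- data.frame(fish_id = "A", species = "BullTrout", period = 3,
                    year = 2008, season = "summer", monitored = 1,
                    moved = NA_integer_, reported = 0L,
                    spawned = NA_integer_, spawn_season = 1L,
                    length_mm = 650, year_std = 0)
  cd <- cjs_data(enc)
  beta <- tiny_beta(); gam <- tiny_gamma()
  expect_equal(marginal_loglik(cd, beta), 0)
  z <- matrix(NA_integer_, 1, 3); z[1, 3] <- 1L
  x <- matrix(0L, 1, 3)
  expect_equal(log_joint(cd, beta, gam, z, x),
               cjs_log_prior(beta, gam))
})

test_that("forward recursion equals brute-force enumeration", {
  cd <- cjs_data(tiny_encounters())
  for (s in 1:4) {
    set.seed(100 + s)
    beta <- stats::setNames(rnorm(11, 0, 1.5), cjs_coef_names())
    expect_equal(marginal_loglik(cd, beta),
                 enum_marginal(cd, beta, tiny_gamma()),
                 tolerance = 1e-12)
  }
})

test_that("a fish observed at its final period forces the all-alive path", {
  enc <- tiny_encounters()[1:3, ]  # F1, recaptured at period 3
  cd <- cjs_data(enc)
  beta <- tiny_beta()
  p1 <- linear_predictors(beta, L = length_covariate(650), Y = -1,
                          S = 0, x = 0)
  p2 <- linear_predictors(beta, L = length_covariate(660), Y = -1,
                          S = 0, x = 0)
  p3 <- linear_predictors(beta, L = length_covariate(670), Y = -1,
                          S = 1, x = 1)
  p3_a <- linear_predictors(beta, L = length_covariate(670), Y = -1,
                            S = 1, x = 0)
  # by hand: survive twice, m = 0 then 1, spawn observed, recaptured
  by_hand <- log(p1$phi) + log(1 - p2$delta) + log(1 - p2$rho) +
    log(p2$phi) + log(p3_a$kappa) + log(p3$delta) + log(p3$rho)
  expect_equal(marginal_loglik(cd, beta), unname(by_hand))
})

test_that("observation-history probabilities sum to one", {
  # one monitored fish, two periods, spawn season in the second:
  # outcomes are (y2, m2, x2) triples plus the unobservable latent state
  beta <- tiny_beta()
  total <- 0
  for (y2 in 0:1) for (m2 in 0:1) for (x2 in 0:1) {
    enc <- data.frame(fish_id = "A", species = "BullTrout", period = 1:2,
                      year = 2008, season = c("spring", "summer"),
                      monitored = 1L, moved = c(NA, m2),
                      reported = c(0L, y2), spawned = c(NA, x2),
                      spawn_season = c(0L, 1L), length_mm = 650,
                      year_std = 0)
    total <- total + exp(marginal_loglik(cjs_data(enc), beta))
  }
  # the dead-fish outcome is the all-zero cell, so the 8 cells are exhaustive
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("the joint density is exchangeable over fish order", {
  enc <- tiny_encounters()
  cd <- cjs_data(enc)
  flipped <- enc[c(4, 5, 1, 2, 3), ]
  cd2 <- cjs_data(flipped)
  beta <- tiny_beta()
  expect_equal(marginal_loglik(cd, beta), marginal_loglik(cd2, beta))
})

test_that("rows after a reported recapture are rejected as uncensored", {
  enc <- tiny_encounters()
  extra <- enc[3, ]
  extra$period <- 4L
  extra$reported <- 0L
  enc2 <- rbind(enc, extra)
  enc2$reported[3] <- 1L
  expect_error(cjs_data(enc2), "censored")
})
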