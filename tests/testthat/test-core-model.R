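test_that("mode/concentration and shape parameterizations convert exactly", {
  expect_equal(shapes_from_mode_concentration(0.5, 2),
               c(alpha = 1, beta = 1))
  expect_equal(shapes_from_mode_concentration(0.25, 10),
               c(alpha = 3, beta = 7))
  expect_error(shapes_from_mode_concentration(0.5, 1.9), "kappa")
  expect_error(shapes_from_mode_concentration(1.2, 10), "mu")

  set.seed(42)
  for (i in 1:50) {
    mu <- runif(1, 0.01, 0.99)
    kap <- 2 + rexp(1, 1 / 50)
    sh <- shapes_from_mode_concentration(mu, kap)
    # algebraic identities of the map
    expect_equal(unname((sh["alpha"] - 1) / (sh["alpha"] + sh["beta"] - 2)), mu,
                 tolerance = 1e-12)
    expect_equal(unname(sh["alpha"] + sh["beta"]), kap, tolerance = 1e-12)
    back <- mode_concentration_from_shapes(sh["alpha"], sh["beta"])
    expect_equal(unname(back), c(mu, kap), tolerance = 1e-12)
  }
})

test_that("gamma mode/sd solve satisfies its defining equations", {
  g <- gamma_shape_rate_from_mode_sd(0, 7)
  expect_equal(unname(g), c(1, 1 / 7))

  g <- gamma_shape_rate_from_mode_sd(10, 100)
  expect_equal(unname(g["shape"]), 1.10512, tolerance = 1e-5)
  expect_equal(unname(g["rate"]), 0.0105125, tolerance = 1e-5)
  # defining equations to 1e-9: mode = (shape-1)/rate, sd = sqrt(shape)/rate
  expect_lt(abs((g["shape"] - 1) / g["rate"] - 10), 1e-9)
  expect_lt(abs(sqrt(g["shape"]) / g["rate"] - 100), 1e-9)

  for (case in list(c(3, 0.5), c(0.1, 20), c(500, 500))) {
    g <- gamma_shape_rate_from_mode_sd(case[1], case[2])
    expect_lt(abs((g["shape"] - 1) / g["rate"] - case[1]), 1e-9)
    expect_lt(abs(sqrt(g["shape"]) / g["rate"] - case[2]), 1e-9)
  }
  expect_error(gamma_shape_rate_from_mode_sd(10, 0), "sd")
})

test_that("prior_spec carries consistent derived gamma parameters", {
  pr <- prior_spec()
  expect_gt(pr$gamma_shape, 1)
  expect_lt(abs((pr$gamma_shape - 1) / pr$gamma_rate - 10), 1e-9)
  expect_lt(abs(sqrt(pr$gamma_shape) / pr$gamma_rate - 100), 1e-9)
  expect_error(prior_spec(mu_shape1 = 0), "positive")
})

test_that("theta full conditional is conjugate addition of counts", {
  cp <- cell_params(0.5, 4)  # alpha = beta = 2
  expect_equal(theta_full_conditional(cp, 10, 36), c(alpha = 12, beta = 28))
  expect_equal(theta_full_conditional(cp, 0, 0), c(alpha = 2, beta = 2))
  expect_error(theta_full_conditional(cp, 37, 36), "<= n")

  # posterior mean (alpha+y)/(alpha+beta+n) vs grid quadrature of the
  # unnormalized likelihood x prior over theta
  cp <- cell_params(0.3, 12)
  y <- 14; n <- 36
  fc <- theta_full_conditional(cp, y, n)
  grid <- seq(1 / 2e5, 1 - 1 / 2e5, length.out = 1e5)
  w <- grid^y * (1 - grid)^(n - y) * dbeta(grid, cp$alpha, cp$beta)
  expect_equal(unname(fc["alpha"] / (fc["alpha"] + fc["beta"])),
               sum(grid * w) / sum(w), tolerance = 1e-6)

  # the conditional's density matches the normalized product on a grid
  prod_dens <- w / (sum(w) * (grid[2] - grid[1]))
  expect_lt(max(abs(prod_dens - dbeta(grid, fc["alpha"], fc["beta"]))), 1e-8 * max(prod_dens))
})

test_that("log_posterior matches an independently coded textbook density sum", {
  labs <- cell_labels()
  mu <- c(0.4, 0.5, 0.6, 0.55)
  kap <- c(8, 15, 30, 12)
  cells <- setNames(lapply(1:4, function(i) cell_params(mu[i], kap[i])), labs)

  # prior-only value: Beta(1,1) terms are 0; only the shifted-gamma terms
  empty <- data.frame(participant_id = character(0), enthusiasm = character(0),
                      sequence = character(0), n_items = integer(0),
                      n_correct = integer(0), n_attempted = integer(0))
  st0 <- model_state(cells, setNames(0.5, "p0"))
  g <- gamma_shape_rate_from_mode_sd(10, 100)
  expect_equal(log_posterior(st0, empty),
               sum(dgamma(kap - 2, g["shape"], g["rate"], log = TRUE)),
               tolerance = 1e-12)

  # one participant per cell against the oracle
  rec <- data.frame(participant_id = paste0("p", 1:4),
                    enthusiasm = rep(c("enthusiastic", "neutral"), 2),
                    sequence = rep(c("massed", "spaced"), each = 2),
                    n_items = 36, n_correct = c(18, 10, 25, 30),
                    n_attempted = c(30, 36, 30, 36))
  theta <- setNames(c(0.5, 0.3, 0.7, 0.8), rec$participant_id)
  st <- model_state(cells, theta)
  cell_of <- match(paste(rec$enthusiasm, rec$sequence, sep = "."), labs)
  expect_equal(log_posterior(st, rec),
               oracle_log_joint(mu, kap, theta, rec$n_correct, rec$n_items, cell_of),
               tolerance = 1e-10)

  # single participant, y = 18 of 36, theta = 0.5: binomial term is
  # log C(36,18) + 36 log(1/2); check by differencing against prior-only
  one <- rec[1, , drop = FALSE]
  st1 <- model_state(cells, setNames(0.5, "p1"))
  binom_and_beta <- log_posterior(st1, one) - log_posterior(st1, empty)
  expect_equal(binom_and_beta,
               lchoose(36, 18) + 36 * log(0.5) +
                 dbeta(0.5, cells[[labs[1]]]$alpha, cells[[labs[1]]]$beta, log = TRUE),
               tolerance = 1e-10)

  # likelihood monotonicity: with y = n, pushing theta toward 1 increases it
  full <- transform(one, n_correct = 36, n_attempted = 36)
  vals <- sapply(c(0.5, 0.7, 0.9, 0.99), function(t) {
    log_posterior(model_state(cells, setNames(t, "p1")), full) -
      dbeta(t, cells[[labs[1]]]$alpha, cells[[labs[1]]]$beta, log = TRUE)
  })
  expect_true(all(diff(vals) > 0))

  # additivity: value(A U B) = value(A) + value(B) - prior-only value
  A <- rec[1:2, ]; B <- rec[3:4, ]
  expect_equal(log_posterior(st, rec),
               log_posterior(st, A) + log_posterior(st, B) -
                 log_posterior(st, empty),
               tolerance = 1e-10)

  # out-of-support states yield -Inf, not an error
  bad_cells <- cells
  bad_cells[[1]] <- structure(list(mu = 0.5, kappa = 1.5, alpha = 0.75,
                                   beta = 0.75), class = "cell_params")
  expect_identical(log_posterior(structure(list(cells = bad_cells, theta = theta),
                                           class = "model_state"), rec), -Inf)
})
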