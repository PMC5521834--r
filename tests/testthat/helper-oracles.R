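# Independent oracles used by the tests. Everything here is written from
# textbook definitions, deliberately not sharing code with the package.

# exhaustive-search HDI: examine every window of ceil(mass*N) sorted
# draws, keep the narrowest (lowest start on ties)
oracle_hdi <- function(x, mass = 0.95) {
  s <- sort(x)
  N <- length(s)
  w <- min(ceiling(mass * N), N)
  best <- c(-Inf, Inf)
  for (i in 1:(N - w + 1)) {
    lo <- s[i]; hi <- s[i + w - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# textbook log joint for the hierarchical beta-binomial model with a
# Beta(1,1) prior on each mode and a Gamma(mode 10, sd 100) prior on each
# concentration minus 2; densities written out via lgamma
oracle_log_joint <- function(mu, kap, theta, y, n, cell_of) {
  lgamma_beta <- function(x, a, b) {
    lgamma(a + b) - lgamma(a) - lgamma(b) + (a - 1) * log(x) + (b - 1) * log(1 - x)
  }
  # gamma shape/rate with mode 10, sd 100
  rate <- (10 + sqrt(100 + 4 * 100^2)) / (2 * 100^2)
  shape <- 1 + 10 * rate
  lgamma_gamma <- function(x) {
    shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x
  }
  lp <- 0
  for (c in seq_along(mu)) {
    lp <- lp + lgamma_beta(mu[c], 1, 1) + lgamma_gamma(kap[c] - 2)
  }
  for (p in seq_along(y)) {
    c <- cell_of[p]
    a <- mu[c] * (kap[c] - 2) + 1
    b <- (1 - mu[c]) * (kap[c] - 2) + 1
    lp <- lp + lchoose(n[p], y[p]) + y[p] * log(theta[p]) +
      (n[p] - y[p]) * log(1 - theta[p]) +
      lgamma_beta(theta[p], a, b)
  }
  unname(lp)
}

# 2-D quadrature posterior means of (mu, kappa) for ONE cell holding a
# set of counts, after integrating theta analytically (beta-binomial
# marginal). Grid over mu and log(kappa - 2) with the change-of-variable
# Jacobian.
oracle_cell_posterior_means <- function(y, n, n_grid = 400,
                                        log_km2_range = c(log(1e-3), log(2e4))) {
  mus <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  us <- seq(log_km2_range[1], log_km2_range[2], length.out = n_grid)
  km2 <- exp(us)
  rate <- (10 + sqrt(100 + 4 * 100^2)) / (2 * 100^2)
  shape <- 1 + 10 * rate
  log_prior_u <- dgamma(km2, shape, rate, log = TRUE) + us  # + Jacobian
  ll <- outer(mus, km2, function(m, k2) {
    a <- m * k2 + 1
    b <- (1 - m) * k2 + 1
    out <- 0
    for (p in seq_along(y)) {
      out <- out + lchoose(n[p], y[p]) + lbeta(y[p] + a, n[p] - y[p] + b) -
        lbeta(a, b)
    }
    out
  })
  lp <- sweep(ll, 2, log_prior_u, "+")
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mu = sum(rowSums(w) * mus), kappa = sum(colSums(w) * (km2 + 2)))
}

# balanced synthetic records at given per-cell modes (cell order =
# cell_labels()): convenience wrapper over the package generator
sim_records <- function(n_per_cell, mu, kappa = 10, seed = 1,
                        attempt_mu = 0.999, attempt_kappa = 40) {
  simulate_experiment(
    study_design(n_per_cell = n_per_cell, seed = seed),
    make_cell_truth(mu, kappa),
    make_cell_truth(attempt_mu, attempt_kappa),
    seed = seed)
}

# fake chain_set with constant (or supplied) draws, for contrast
# arithmetic tests; mu and kappa are named lists over cell labels of
# per-draw vectors (recycled)
fake_chains <- function(mu, kappa, n_draws = 1000, n_chains = 2) {
  labs <- recallbb::cell_labels()
  par_names <- c(paste0("mu_", labs), paste0("kappa_", labs))
  one <- sapply(c(mu[labs], kappa[labs]), rep_len, n_draws)
  colnames(one) <- par_names
  structure(list(draws = replicate(n_chains, one, simplify = FALSE),
                 theta = NULL, acceptance = NULL,
                 config = chain_config(n_chains = n_chains, n_samples = n_draws,
                                       thin = 1),
                 prior = prior_spec(), outcome = "n_correct",
                 cells = labs, param_names = par_names),
            class = "chain_set")
}

# gap structure of a trial sequence: positions of each item, differenced
item_gaps <- function(seq) {
  lapply(split(seq_along(seq$items), seq$items), diff)
}
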