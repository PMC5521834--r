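#' MCMC chain protocol configuration
#'
#' Defaults reproduce a four-chain protocol with 1,000 adaptation steps,
#' 4,000 burn-in steps and 60,000 sampling steps per chain thinned by 3,
#' i.e. 20,000 retained draws per chain and 80,000 in total.
#'
#' @param n_chains Number of independent chains.
#' @param n_adapt Adaptation steps (proposal scales are tuned here only,
#'   then frozen so the sampler's invariant distribution is untouched).
#' @param n_burnin Burn-in steps discarded after adaptation.
#' @param n_samples Sampling steps per chain before thinning.
#' @param thin Keep every `thin`-th sampling step; retained draws per
#'   chain = `floor(n_samples / thin)`.
#' @param seed Integer master seed; per-chain streams are derived from it.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 4, n_adapt = 1000, n_burnin = 4000,
                         n_samples = 60000, thin = 3, seed = 1) {
  if (n_chains < 1 || n_adapt < 0 || n_burnin < 0 || n_samples < 1 || thin < 1) {
    stop("chain_config: counts must be non-negative, n_chains, n_samples and thin >= 1")
  }
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin), n_samples = as.integer(n_samples),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf(
    "chain_config: %d chains x (%d adapt + %d burn-in + %d samples, thin %d) -> %d retained/chain\n",
    x$n_chains, x$n_adapt, x$n_burnin, x$n_samples, x$thin,
    x$n_samples %/% x$thin))
  invisible(x)
}

# per-cell Metropolis target given the current theta sufficient statistics
# S1 = sum log theta, S2 = sum log(1 - theta), m = participants in the cell;
# includes the Jacobian of the (logit mu, log(kappa - 2)) transform
cell_target <- function(mu, kap, S1, S2, m, prior) {
  if (mu <= 0 || mu >= 1 || kap <= 2) return(-Inf)
  km2 <- kap - 2
  a <- mu * km2 + 1
  b <- (1 - mu) * km2 + 1
  (a - 1) * S1 + (b - 1) * S2 - m * lbeta(a, b) +
    stats::dbeta(mu, prior$mu_shape1, prior$mu_shape2, log = TRUE) +
    log_kappa_prior(kap, prior) +
    log(mu) + log1p(-mu) + log(km2)
}

#' Fit the hierarchical beta-binomial model by Metropolis-within-Gibbs
#'
#' Runs independent MCMC chains for the 2x2 model: per iteration every
#' participant-level `theta` is drawn exactly from its conjugate full
#' conditional (see [theta_full_conditional()]), and each cell's
#' `(mu, kappa)` pair is updated by a random-walk Metropolis step on
#' `(logit mu, log(kappa - 2))` with the Jacobian-corrected acceptance
#' ratio. Proposal scales are tuned multiplicatively toward an acceptance
#' rate near 0.3 during the adaptation phase only and frozen afterwards.
#'
#' @param records Records table with all four cells represented (see
#'   [simulate_experiment()] / [load_recall_table()]).
#' @param prior A [prior_spec()].
#' @param config A [chain_config()].
#' @param outcome Count column to model: `"n_correct"` or `"n_attempted"`.
#' @param save_theta Keep the participant-level draws (memory scales with
#'   participants x retained draws; off by default).
#' @param init Optional named list over [cell_labels()] of [cell_params()]
#'   used as the starting group-level state in every chain (default:
#'   data-informed starts -- each cell's empirical mean proportion clipped
#'   to (0.01, 0.99), concentration at prior mode + 2).
#' @param update_cells If `FALSE` the group-level parameters stay fixed at
#'   their starting values and only `theta` is Gibbs-sampled (useful for
#'   conjugacy checks).
#' @param prior_only If `TRUE` the likelihood is dropped entirely and the
#'   chains sample the priors on `mu` and `kappa`; `records` may be `NULL`.
#' @return Object of class `chain_set`: `draws` (list of per-chain
#'   matrices, columns `mu_<cell>` and `kappa_<cell>`), optional `theta`
#'   draws, `acceptance` (cells x chains matrix of post-adaptation
#'   Metropolis acceptance rates), `config`, `outcome`, `prior`.
#' @export
run_mcmc <- function(records, prior = prior_spec(), config = chain_config(),
                     outcome = c("n_correct", "n_attempted"),
                     save_theta = FALSE, init = NULL, update_cells = TRUE,
                     prior_only = FALSE) {
  outcome <- match.arg(outcome)
  labs <- cell_labels()

  if (!prior_only) {
    if (is.null(records) || nrow(records) == 0L) {
      stop("run_mcmc: records must be non-empty")
    }
    validate_records(records, require_attempts = outcome == "n_attempted")
    cl <- record_cell(records)
    counts <- table(factor(cl, levels = labs))
    if (any(counts == 0)) {
      stop("run_mcmc: cell(s) with zero participants: ",
           paste(labs[counts == 0], collapse = ", "))
    }
    y <- as.numeric(records[[outcome]])
    n <- as.numeric(records$n_items)
    ids <- as.character(records$participant_id)
    cell_idx <- match(cl, labs)
    P <- length(y)
  } else {
    y <- n <- numeric(0); ids <- character(0); cell_idx <- integer(0); P <- 0L
  }

  # starting group-level state
  if (!is.null(init)) {
    if (!all(labs %in% names(init))) {
      stop("run_mcmc: init must cover all four cells")
    }
    mu0 <- vapply(labs, function(l) init[[l]]$mu, 0)
    kap0 <- vapply(labs, function(l) init[[l]]$kappa, 0)
  } else if (!prior_only) {
    mu0 <- vapply(1:4, function(c) {
      sel <- cell_idx == c
      min(max(mean(y[sel] / n[sel]), 0.01), 0.99)
    }, 0)
    kap0 <- rep(prior$kappa_mode + 2, 4)
  } else {
    mu0 <- rep(0.5, 4)
    kap0 <- rep(prior$kappa_mode + 2, 4)
  }
  if (any(!is.finite(log_kappa_prior(kap0, prior))) || any(mu0 <= 0 | mu0 >= 1)) {
    stop("run_mcmc: non-finite log-posterior at initialization ",
         "(check init values against the prior support)")
  }

  n_keep <- config$n_samples %/% config$thin
  par_names <- c(paste0("mu_", labs), paste0("kappa_", labs))
  chain_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, config$n_chains))

  draws <- vector("list", config$n_chains)
  theta_draws <- if (save_theta && !prior_only) vector("list", config$n_chains) else NULL
  acc_mat <- matrix(NA_real_, 4, config$n_chains,
                    dimnames = list(labs, paste0("chain", seq_len(config$n_chains))))

  for (ch in seq_len(config$n_chains)) {
    res <- with_seed(chain_seeds[ch], run_one_chain(
      mu0, kap0, y, n, cell_idx, P, prior, config, n_keep,
      update_cells = update_cells, prior_only = prior_only,
      save_theta = save_theta && !prior_only))
    colnames(res$draws) <- par_names
    draws[[ch]] <- res$draws
    if (!is.null(theta_draws)) {
      colnames(res$theta) <- ids
      theta_draws[[ch]] <- res$theta
    }
    acc_mat[, ch] <- res$acc
  }

  structure(list(draws = draws, theta = theta_draws, acceptance = acc_mat,
                 config = config, prior = prior, outcome = outcome,
                 cells = labs, param_names = par_names,
                 participant_ids = if (P > 0) ids else character(0)),
            class = "chain_set")
}

# one chain of the Metropolis-within-Gibbs sampler; assumes the RNG state
# has already been seeded by the caller
run_one_chain <- function(mu0, kap0, y, n, cell_idx, P, prior, config, n_keep,
                          update_cells, prior_only, save_theta) {
  mu <- mu0; kap <- kap0
  z1 <- stats::qlogis(mu); z2 <- log(kap - 2)
  scale1 <- rep(0.3, 4); scale2 <- rep(0.5, 4)
  S1 <- S2 <- numeric(4); m_cell <- numeric(4)
  if (!prior_only) m_cell <- tabulate(cell_idx, 4)
  idx_by_cell <- if (!prior_only) split(seq_len(P), cell_idx) else NULL

  n_total <- config$n_adapt + config$n_burnin + config$n_samples
  out <- matrix(NA_real_, n_keep, 8)
  th_out <- if (save_theta) matrix(NA_real_, n_keep, P) else NULL
  acc_sample <- numeric(4)
  acc_window <- numeric(4)
  window <- 0L
  keep_row <- 0L
  eps <- 1e-12

  for (it in seq_len(n_total)) {
    if (!prior_only) {
      a <- mu[cell_idx] * (kap[cell_idx] - 2) + 1
      b <- (1 - mu[cell_idx]) * (kap[cell_idx] - 2) + 1
      th <- stats::rbeta(P, a + y, b + n - y)
      th <- pmin(pmax(th, eps), 1 - eps)
      lt <- log(th); l1t <- log1p(-th)
      for (c in 1:4) {
        S1[c] <- sum(lt[idx_by_cell[[c]]])
        S2[c] <- sum(l1t[idx_by_cell[[c]]])
      }
    }

    if (update_cells) {
      for (c in 1:4) {
        curr <- cell_target(mu[c], kap[c], S1[c], S2[c], m_cell[c], prior)
        z1p <- z1[c] + scale1[c] * stats::rnorm(1)
        z2p <- z2[c] + scale2[c] * stats::rnorm(1)
        mup <- stats::plogis(z1p)
        kapp <- 2 + exp(z2p)
        prop <- cell_target(mup, kapp, S1[c], S2[c], m_cell[c], prior)
        if (is.finite(prop) && log(stats::runif(1)) < prop - curr) {
          z1[c] <- z1p; z2[c] <- z2p; mu[c] <- mup; kap[c] <- kapp
          acc_window[c] <- acc_window[c] + 1
          if (it > config$n_adapt + config$n_burnin) acc_sample[c] <- acc_sample[c] + 1
        }
      }
      window <- window + 1L
      if (it <= config$n_adapt && window == 25L) {
        rate <- acc_window / 25
        fac <- exp(rate - 0.3)
        scale1 <- pmin(pmax(scale1 * fac, 1e-3), 10)
        scale2 <- pmin(pmax(scale2 * fac, 1e-3), 10)
        acc_window[] <- 0; window <- 0L
      } else if (window == 25L) {
        acc_window[] <- 0; window <- 0L
      }
    }

    j <- it - config$n_adapt - config$n_burnin
    if (j >= 1 && j %% config$thin == 0) {
      keep_row <- keep_row + 1L
      out[keep_row, ] <- c(mu, kap)
      if (save_theta) th_out[keep_row, ] <- th
    }
  }

  list(draws = out, theta = th_out,
       acc = if (update_cells) acc_sample / config$n_samples else rep(NA_real_, 4))
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set: %d chains x %d retained draws; outcome = %s\n",
              length(x$draws), nrow(x$draws[[1]]), x$outcome))
  cat("monitored:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Pooled posterior draws of one monitored parameter
#'
#' @param chains A `chain_set` from [run_mcmc()].
#' @param param Parameter name, e.g. `"mu_enthusiastic.massed"`.
#' @return Numeric vector concatenating the retained draws of all chains.
#' @export
pooled_draws <- function(chains, param) {
  if (!param %in% chains$param_names) {
    stop("pooled_draws: unknown parameter '", param, "'")
  }
  unlist(lapply(chains$draws, function(d) d[, param]), use.names = FALSE)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from m >= 2 chains of equal length n:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}}
#' with `B` the between-chain variance (`n` times the variance of the
#' chain means) and `W` the mean within-chain variance. Values near 1
#' indicate the chains are sampling the same distribution.
#'
#' @param chains List of equal-length numeric vectors, or a matrix with
#'   one chain per column.
#' @return Scalar PSRF; `NA` with a warning when the within-chain
#'   variance is zero (degenerate chains).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  if (!is.list(chains) || length(chains) < 2) {
    stop("gelman_rubin: at least two chains are required")
  }
  len <- vapply(chains, length, 0L)
  if (length(unique(len)) != 1 || len[1] < 2) {
    stop("gelman_rubin: chains must have equal lengths >= 2")
  }
  n <- len[1]
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, stats::var, 0))
  B <- n * stats::var(means)
  if (W == 0) {
    warning("gelman_rubin: zero within-chain variance; PSRF undefined")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' `ESS = N / (1 + 2 * sum(rho_t))`, with the autocorrelation sum
#' truncated by the initial-positive-sequence rule: consecutive lag pairs
#' `(rho_1 + rho_2), (rho_3 + rho_4), ...` are accumulated while their sum
#' stays positive. For a list of chains (or a matrix with one chain per
#' column) the per-chain ESS values are summed.
#'
#' @param x Numeric vector (one chain), list of vectors, or matrix.
#' @return Scalar ESS; `NA` with a warning for a constant chain.
#' @export
effective_sample_size <- function(x) {
  if (is.matrix(x)) x <- asplit(x, 2)
  if (is.list(x)) return(sum(vapply(x, effective_sample_size, 0)))
  N <- length(x)
  if (N < 10) stop("effective_sample_size: need at least 10 draws")
  if (stats::var(x) == 0) {
    warning("effective_sample_size: constant chain; ESS undefined")
    return(NA_real_)
  }
  lag_max <- min(N - 1, 2000L)
  rho <- as.vector(stats::acf(x, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  N / (1 + 2 * s)
}

#' Convergence diagnostics for every monitored parameter
#'
#' @param chains A `chain_set` from [run_mcmc()].
#' @return `data.frame` with one row per monitored parameter: `param`,
#'   `psrf` (Gelman-Rubin), `ess` (summed over chains), `mean`.
#' @export
diagnose <- function(chains) {
  rows <- lapply(chains$param_names, function(p) {
    per_chain <- lapply(chains$draws, function(d) d[, p])
    data.frame(param = p,
               psrf = if (length(per_chain) >= 2) gelman_rubin(per_chain) else NA_real_,
               ess = effective_sample_size(per_chain),
               mean = mean(unlist(per_chain)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Persist a chain set as one CSV per chain plus a JSON sidecar
#'
#' @param chains A `chain_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chain_set <- function(chains, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(chains$draws)) {
    utils::write.csv(as.data.frame(chains$draws[[ch]]),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE)
  }
  diag_df <- diagnose(chains)
  sidecar <- list(
    config = unclass(chains$config),
    prior = unclass(chains$prior),
    outcome = chains$outcome,
    acceptance = as.data.frame(chains$acceptance),
    psrf = stats::setNames(as.list(diag_df$psrf), diag_df$param),
    ess = stats::setNames(as.list(diag_df$ess), diag_df$param)
  )
  jsonlite::write_json(sidecar, file.path(dir, "chains.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
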