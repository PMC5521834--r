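#' Beta shape parameters from mode and concentration
#'
#' Converts the mode/concentration parameterization of a beta distribution
#' into its standard shape parameters. A beta distribution with mode
#' \eqn{\mu \in (0,1)} and concentration \eqn{\kappa > 2} has shapes
#' \deqn{\alpha = \mu(\kappa - 2) + 1, \qquad \beta = (1-\mu)(\kappa - 2) + 1,}
#' so that \eqn{(\alpha-1)/(\alpha+\beta-2) = \mu} and
#' \eqn{\alpha + \beta = \kappa}. Larger \eqn{\kappa} concentrates the
#' distribution more tightly around its mode; \eqn{\kappa = 2} is the
#' uniform boundary (\eqn{\alpha = \beta = 1}).
#'
#' @param mu Mode, in (0, 1).
#' @param kappa Concentration, >= 2 (the boundary value 2 is allowed and
#'   yields the uniform distribution regardless of `mu`).
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @seealso [mode_concentration_from_shapes()] for the inverse map,
#'   [cell_params()] for the bundled per-condition parameter object.
#' @examples
#' shapes_from_mode_concentration(0.25, 10)  # alpha = 3, beta = 7
#' @export
shapes_from_mode_concentration <- function(mu, kappa) {
  if (!is.numeric(mu) || !is.numeric(kappa)) {
    stop("shapes_from_mode_concentration: mu and kappa must be numeric")
  }
  if (any(mu <= 0 | mu >= 1)) {
    stop("shapes_from_mode_concentration: mu must lie strictly in (0, 1)")
  }
  if (any(kappa < 2)) {
    stop("shapes_from_mode_concentration: kappa must be >= 2 ",
         "(mode parameterization undefined below 2)")
  }
  c(alpha = mu * (kappa - 2) + 1, beta = (1 - mu) * (kappa - 2) + 1)
}

#' Mode and concentration from beta shape parameters
#'
#' Inverse of [shapes_from_mode_concentration()]: `mu = (alpha - 1) /
#' (alpha + beta - 2)`, `kappa = alpha + beta`. Requires `alpha, beta > 1`
#' so the mode is interior.
#'
#' @param alpha,beta Beta shape parameters, both > 1.
#' @return Named numeric vector with elements `mu` and `kappa`.
#' @export
mode_concentration_from_shapes <- function(alpha, beta) {
  if (any(alpha <= 1) || any(beta <= 1)) {
    stop("mode_concentration_from_shapes: alpha and beta must exceed 1 ",
         "for an interior mode")
  }
  c(mu = (alpha - 1) / (alpha + beta - 2), kappa = alpha + beta)
}

#' Gamma shape and rate from mode and standard deviation
#'
#' Solves for the unique gamma distribution with a given mode and standard
#' deviation. With mode \eqn{m \ge 0} and sd \eqn{s > 0} the rate is
#' \deqn{r = \frac{m + \sqrt{m^2 + 4 s^2}}{2 s^2}}
#' and the shape is \eqn{k = 1 + m r}, which satisfy
#' \eqn{(k-1)/r = m} and \eqn{\sqrt{k}/r = s} exactly. `mode = 0` gives the
#' exponential special case (`shape = 1`, `rate = 1/sd`).
#'
#' @param mode Gamma mode, >= 0.
#' @param sd Gamma standard deviation, > 0.
#' @return Named numeric vector with elements `shape` and `rate`.
#' @examples
#' gamma_shape_rate_from_mode_sd(10, 100)
#' @export
gamma_shape_rate_from_mode_sd <- function(mode, sd) {
  if (!is.numeric(mode) || mode < 0) {
    stop("gamma_shape_rate_from_mode_sd: mode must be >= 0")
  }
  if (!is.numeric(sd) || sd <= 0) {
    stop("gamma_shape_rate_from_mode_sd: sd must be > 0")
  }
  rate <- (mode + sqrt(mode^2 + 4 * sd^2)) / (2 * sd^2)
  c(shape = 1 + mode * rate, rate = rate)
}

#' Per-condition group-level parameters
#'
#' Bundles the mode `mu` and concentration `kappa` of one experimental
#' cell's beta distribution over participant-level recall probabilities,
#' together with the derived shape parameters.
#'
#' @param mu Mode of the cell's beta distribution, in (0, 1).
#' @param kappa Concentration, > 2.
#' @return Object of class `cell_params`: list with `mu`, `kappa`,
#'   `alpha`, `beta`.
#' @export
cell_params <- function(mu, kappa) {
  if (length(mu) != 1L || length(kappa) != 1L) {
    stop("cell_params: mu and kappa must be scalars")
  }
  if (kappa <= 2) {
    stop("cell_params: kappa must exceed 2")
  }
  sh <- shapes_from_mode_concentration(mu, kappa)
  structure(
    list(mu = mu, kappa = kappa,
         alpha = unname(sh["alpha"]), beta = unname(sh["beta"])),
    class = "cell_params"
  )
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("cell_params: mu = %.4g, kappa = %.4g (alpha = %.4g, beta = %.4g)\n",
              x$mu, x$kappa, x$alpha, x$beta))
  invisible(x)
}

#' Prior specification for the hierarchical beta-binomial model
#'
#' The group-level mode of each cell gets a Beta(`mu_shape1`, `mu_shape2`)
#' prior (default Beta(1, 1), uniform). The concentration gets a gamma
#' prior expressed through its mode and standard deviation (defaults: mode
#' 10, sd 100 -- vague, informed only by the scale of count data out of
#' 36). Because the mode/concentration map needs `kappa > 2`, the gamma
#' prior is placed by default on the shifted quantity `kappa - 2`, which
#' keeps every reachable state well defined; set `kappa_prior_on =
#' "kappa"` to place it on `kappa` itself (then states with `kappa <= 2`
#' are simply given zero prior mass).
#'
#' @param mu_shape1,mu_shape2 Beta prior shapes for each cell's mode.
#' @param kappa_mode Mode of the gamma prior on the (possibly shifted)
#'   concentration.
#' @param kappa_sd Standard deviation of that gamma prior.
#' @param kappa_prior_on Either `"kappa_minus_2"` (default) or `"kappa"`.
#' @return Object of class `prior_spec` with the inputs plus the derived
#'   gamma `shape` and `rate`.
#' @export
prior_spec <- function(mu_shape1 = 1, mu_shape2 = 1,
                       kappa_mode = 10, kappa_sd = 100,
                       kappa_prior_on = c("kappa_minus_2", "kappa")) {
  kappa_prior_on <- match.arg(kappa_prior_on)
  if (mu_shape1 <= 0 || mu_shape2 <= 0) {
    stop("prior_spec: beta prior shapes must be positive")
  }
  g <- gamma_shape_rate_from_mode_sd(kappa_mode, kappa_sd)
  structure(
    list(mu_shape1 = mu_shape1, mu_shape2 = mu_shape2,
         kappa_mode = kappa_mode, kappa_sd = kappa_sd,
         kappa_prior_on = kappa_prior_on,
         gamma_shape = unname(g["shape"]), gamma_rate = unname(g["rate"])),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec: mu ~ Beta(%g, %g); %s ~ Gamma(mode = %g, sd = %g)\n",
              x$mu_shape1, x$mu_shape2,
              if (x$kappa_prior_on == "kappa_minus_2") "kappa - 2" else "kappa",
              x$kappa_mode, x$kappa_sd))
  invisible(x)
}

# log prior density of a concentration value under a prior_spec;
# vectorized over kappa, -Inf outside the support
log_kappa_prior <- function(kappa, prior) {
  if (prior$kappa_prior_on == "kappa_minus_2") {
    x <- kappa - 2
  } else {
    x <- kappa
  }
  out <- rep(-Inf, length(kappa))
  ok <- x > 0 & kappa > 2
  out[ok] <- stats::dgamma(x[ok], shape = prior$gamma_shape,
                           rate = prior$gamma_rate, log = TRUE)
  out
}

#' Model state: group-level parameters plus participant-level probabilities
#'
#' @param cells Named list of four [cell_params()] objects, one per
#'   experimental cell, named `"<enthusiasm>.<sequence>"` (see
#'   [cell_labels()]).
#' @param theta Named numeric vector of per-participant recall
#'   probabilities, all strictly inside (0, 1); names are participant ids.
#' @return Object of class `model_state`.
#' @export
model_state <- function(cells, theta) {
  need <- cell_labels()
  if (!all(need %in% names(cells))) {
    stop("model_state: cells must cover all four conditions: ",
         paste(setdiff(need, names(cells)), collapse = ", "), " missing")
  }
  if (any(theta <= 0 | theta >= 1)) {
    stop("model_state: every theta must lie strictly in (0, 1)")
  }
  if (is.null(names(theta)) || anyDuplicated(names(theta))) {
    stop("model_state: theta must carry unique participant names")
  }
  structure(list(cells = cells, theta = theta), class = "model_state")
}

#' Canonical cell labels of the 2x2 design
#'
#' The four combinations of instruction enthusiasm and study sequence, in
#' a fixed order used throughout the package for parameter naming.
#'
#' @return Character vector `"enthusiastic.massed"`,
#'   `"enthusiastic.spaced"`, `"neutral.massed"`, `"neutral.spaced"`.
#' @export
cell_labels <- function() {
  as.vector(outer(c("enthusiastic", "neutral"), c("massed", "spaced"),
                  function(e, s) paste(e, s, sep = ".")))
}

#' Factor levels of the design
#' @name design-levels
#' @keywords internal
NULL

enthusiasm_levels <- function() c("enthusiastic", "neutral")
sequence_levels <- function() c("massed", "spaced")

# cell label for rows of a records table
record_cell <- function(records) {
  paste(records$enthusiasm, records$sequence, sep = ".")
}

#' Joint log posterior density of the hierarchical beta-binomial model
#'
#' Evaluates, up to nothing (all normalizing constants included), the sum
#' of the binomial log-likelihood of each participant's count given their
#' `theta`, the beta log-density of each `theta` under its cell's
#' mode/concentration parameters, the beta prior log-density of each
#' cell's `mu`, and the gamma prior log-density of each cell's
#' concentration. Returns `-Inf` for states outside the support (a `theta`
#' at or beyond 0/1, a `kappa` at or below 2) rather than erroring, so the
#' function can sit directly inside a Metropolis accept/reject step.
#'
#' @param state A [model_state()].
#' @param records Records table (see [simulate_experiment()] /
#'   [load_recall_table()]); may have zero rows for a prior-only value.
#' @param prior A [prior_spec()].
#' @param outcome Which count to treat as the binomial outcome:
#'   `"n_correct"` (recall accuracy) or `"n_attempted"` (non-blank
#'   responses).
#' @return Scalar log density.
#' @export
log_posterior <- function(state, records, prior = prior_spec(),
                          outcome = c("n_correct", "n_attempted")) {
  outcome <- match.arg(outcome)
  if (!inherits(state, "model_state")) stop("log_posterior: state must be a model_state")
  lp <- 0
  for (lab in cell_labels()) {
    cp <- state$cells[[lab]]
    if (cp$kappa <= 2) return(-Inf)
    lp <- lp + stats::dbeta(cp$mu, prior$mu_shape1, prior$mu_shape2, log = TRUE)
    lp <- lp + log_kappa_prior(cp$kappa, prior)
  }
  if (!is.finite(lp)) return(-Inf)
  if (nrow(records) == 0L) return(lp)

  validate_records(records, require_attempts = outcome == "n_attempted")
  ids <- as.character(records$participant_id)
  if (!all(ids %in% names(state$theta))) {
    stop("log_posterior: state does not cover participants: ",
         paste(utils::head(setdiff(ids, names(state$theta)), 3), collapse = ", "))
  }
  th <- state$theta[ids]
  if (any(th <= 0 | th >= 1)) return(-Inf)
  y <- records[[outcome]]
  n <- records$n_items
  lp <- lp + sum(stats::dbinom(y, n, th, log = TRUE))
  cl <- record_cell(records)
  for (lab in unique(cl)) {
    cp <- state$cells[[lab]]
    sel <- cl == lab
    lp <- lp + sum(stats::dbeta(th[sel], cp$alpha, cp$beta, log = TRUE))
  }
  lp
}

#' Conjugate full conditional of a participant-level probability
#'
#' Given the cell's beta parameters and the participant's count `y` out of
#' `n`, the full conditional of that participant's `theta` is
#' Beta(`alpha + y`, `beta + n - y`) exactly (beta-binomial conjugacy).
#'
#' @param cell A [cell_params()] object.
#' @param y Observed count, 0 <= y <= n.
#' @param n Number of trials.
#' @return Named numeric vector with elements `alpha` and `beta` of the
#'   conditional beta distribution.
#' @export
theta_full_conditional <- function(cell, y, n) {
  if (any(y < 0) || any(n < 0) || any(y > n)) {
    stop("theta_full_conditional: counts must satisfy 0 <= y <= n")
  }
  c(alpha = cell$alpha + y, beta = cell$beta + n - y)
}
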