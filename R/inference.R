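#' Highest density interval of posterior draws
#'
#' The narrowest window containing at least `mass` of the draws: the
#' draws are sorted, every contiguous window of `ceiling(mass * N)` draws
#' is examined, and the shortest one is returned (ties broken by the
#' lowest starting index, so the output is deterministic).
#'
#' @param samples Numeric vector of posterior draws (>= 20).
#' @param mass Probability mass of the interval, default 0.95.
#' @return Object of class `hdi_interval`: list with `lo`, `hi`, `mass`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (length(samples) < 20) {
    stop("hdi: need at least 20 draws")
  }
  if (mass <= 0 || mass >= 1) stop("hdi: mass must lie in (0, 1)")
  s <- sort(samples)
  N <- length(s)
  w <- ceiling(mass * N)
  if (w >= N) w <- N
  n_win <- N - w + 1L
  widths <- s[w:N] - s[1:n_win]
  i <- which.min(widths)  # lowest index on ties
  structure(list(lo = s[i], hi = s[i + w - 1L], mass = mass),
            class = "hdi_interval")
}

#' @export
print.hdi_interval <- function(x, ...) {
  cat(sprintf("%g%% HDI: [%.4g, %.4g]\n", 100 * x$mass, x$lo, x$hi))
  invisible(x)
}

#' Posterior mode via kernel density estimation
#'
#' The argmax over a 512-point grid of a Gaussian kernel density estimate
#' with Silverman's rule-of-thumb bandwidth. A constant sample returns
#' that constant.
#'
#' @param samples Numeric vector of draws (>= 100 unless constant).
#' @return Scalar mode estimate.
#' @export
posterior_mode <- function(samples) {
  u <- unique(samples)
  if (length(u) == 1L) return(u)
  if (length(samples) < 100) {
    stop("posterior_mode: need at least 100 draws")
  }
  d <- stats::density(samples, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

# assemble a contrast_summary from per-draw contrast values
summarize_contrast <- function(draws, name, scale, mass = 0.95) {
  h <- hdi(draws, mass)
  m <- posterior_mode(draws)
  structure(list(name = name, mode = m, hdi = h, scale = scale,
                 excludes_zero = (h$lo > 0 || h$hi < 0), draws = draws),
            class = "contrast_summary")
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf("%s: mode = %.3g (%g%% HDI: %.3g to %.3g) [%s]%s\n",
              x$name, x$mode, 100 * x$hdi$mass, x$hdi$lo, x$hdi$hi, x$scale,
              if (x$excludes_zero) " *HDI excludes 0*" else ""))
  invisible(x)
}

#' @export
as.data.frame.contrast_summary <- function(x, ...) {
  data.frame(name = x$name, mode = x$mode, hdi_lo = x$hdi$lo,
             hdi_hi = x$hdi$hi, mass = x$hdi$mass, scale = x$scale,
             excludes_zero = x$excludes_zero, stringsAsFactors = FALSE)
}

# pooled draws of one parameter family ("mu" or "kappa") as a 4-column
# matrix over cells
cell_draw_matrix <- function(chains, family) {
  cols <- paste0(family, "_", cell_labels())
  missing_cols <- setdiff(cols, chains$param_names)
  if (length(missing_cols)) {
    stop("chain_set is missing cell parameter(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sapply(cols, function(p) pooled_draws(chains, p))
}

# per-draw main-effect contrast on one parameter family; fixed level
# order: spaced - massed, enthusiastic - neutral
main_effect_draws <- function(chains, factor, family) {
  d <- cell_draw_matrix(chains, family)
  labs <- cell_labels()
  if (factor == "sequence") {
    hi <- grepl("\\.spaced$", labs); lo <- grepl("\\.massed$", labs)
  } else if (factor == "enthusiasm") {
    hi <- grepl("^enthusiastic\\.", labs); lo <- grepl("^neutral\\.", labs)
  } else {
    stop("unknown factor '", factor, "' (expected 'sequence' or 'enthusiasm')")
  }
  rowMeans(d[, hi, drop = FALSE]) - rowMeans(d[, lo, drop = FALSE])
}

#' Main-effect contrast on recall accuracy, in items
#'
#' For every retained draw, the unweighted mean of the two cell modes at
#' one factor level minus the mean at the other level, scaled by the
#' number of test items: the posterior distribution of the factor's
#' effect on the number of items recalled. Level order is fixed as
#' spaced - massed and enthusiastic - neutral, so a positive spacing
#' contrast means spaced study improved recall.
#'
#' @param chains A `chain_set` from [run_mcmc()] on the `n_correct`
#'   outcome.
#' @param factor `"sequence"` or `"enthusiasm"`.
#' @param n_items Test length used to express the effect in items.
#' @return A `contrast_summary` (posterior mode, 95% HDI, exclusion
#'   flag, and the per-draw values).
#' @export
mu_contrast_items <- function(chains, factor = c("sequence", "enthusiasm"),
                              n_items = 36) {
  factor <- match.arg(factor)
  draws <- main_effect_draws(chains, factor, "mu") * n_items
  nm <- if (factor == "sequence") "spacing effect (spaced - massed)"
        else "enthusiasm effect (enthusiastic - neutral)"
  summarize_contrast(draws, nm, "items")
}

#' Main-effect contrast on the concentration parameter
#'
#' Same construction as [mu_contrast_items()] but on the `kappa` draws and
#' unscaled. On an attempted-responses fit, where the mode sits at the
#' ceiling, a larger `kappa` means responses bunched more tightly at the
#' maximum, i.e. fewer items left blank.
#'
#' @inheritParams mu_contrast_items
#' @return A `contrast_summary` on the `kappa` scale.
#' @export
kappa_contrast <- function(chains, factor = c("sequence", "enthusiasm")) {
  factor <- match.arg(factor)
  draws <- main_effect_draws(chains, factor, "kappa")
  nm <- if (factor == "sequence") "spacing effect on kappa (spaced - massed)"
        else "enthusiasm effect on kappa (enthusiastic - neutral)"
  summarize_contrast(draws, nm, "kappa")
}

#' Interaction contrast (difference of differences)
#'
#' Per draw: the benefit of enthusiasm under massed study minus the
#' benefit of enthusiasm under spaced study,
#' `(enthusiastic - neutral | massed) - (enthusiastic - neutral | spaced)`,
#' scaled to items when `scale = "items"` (on the `mu` draws) or left on
#' the concentration scale when `scale = "kappa"`.
#'
#' @param chains A `chain_set`.
#' @param scale `"items"` (uses `mu` draws, multiplied by `n_items`) or
#'   `"kappa"`.
#' @param n_items Test length for the items scale.
#' @return A `contrast_summary`.
#' @export
interaction_contrast <- function(chains, scale = c("items", "kappa"),
                                 n_items = 36) {
  scale <- match.arg(scale)
  family <- if (scale == "items") "mu" else "kappa"
  d <- cell_draw_matrix(chains, family)
  labs <- cell_labels()
  em <- d[, labs == "enthusiastic.massed"]
  nm_ <- d[, labs == "neutral.massed"]
  es <- d[, labs == "enthusiastic.spaced"]
  ns <- d[, labs == "neutral.spaced"]
  draws <- (em - nm_) - (es - ns)
  if (scale == "items") draws <- draws * n_items
  summarize_contrast(draws,
                     "interaction (enthusiasm benefit massed - spaced)",
                     scale)
}

#' Difference between the two main effects, in items
#'
#' Per draw: the spacing main effect minus the enthusiasm main effect
#' (both in items). A positive mode with an HDI excluding zero says the
#' sequencing manipulation beat the instruction manipulation.
#'
#' @param chains A `chain_set`.
#' @param n_items Test length.
#' @return A `contrast_summary` on the items scale.
#' @export
effect_size_difference <- function(chains, n_items = 36) {
  draws <- (main_effect_draws(chains, "sequence", "mu") -
              main_effect_draws(chains, "enthusiasm", "mu")) * n_items
  summarize_contrast(draws, "spacing effect - enthusiasm effect", "items")
}

#' Write a list of contrast summaries as JSON
#'
#' @param contrasts List of `contrast_summary` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contrasts_json <- function(contrasts, path) {
  df <- do.call(rbind, lapply(contrasts, as.data.frame))
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
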