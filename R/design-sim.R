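#' Study design of a 2x2 instruction-by-sequencing experiment
#'
#' Describes the factorial design that drives the simulator: how many
#' paired-associate items are studied, how many times each is repeated,
#' and how many participants sit in each of the four cells (instruction
#' enthusiasm x study sequence). Defaults match a 36-item, 4-repetition
#' paired-associates task (144 study trials per participant).
#'
#' @param n_items Number of cue-target pairs studied and later tested.
#' @param n_reps Number of study repetitions of each pair.
#' @param n_per_cell Participants per cell. Either a single count applied
#'   to all four cells or a named vector over [cell_labels()] (useful to
#'   mimic the slightly unbalanced allocation of a real experiment).
#' @param seed Integer seed; every draw the design generates descends
#'   deterministically from it.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_items = 36, n_reps = 4, n_per_cell = 50, seed = 1) {
  if (n_items < 1 || n_reps < 1) {
    stop("study_design: n_items and n_reps must be >= 1")
  }
  labs <- cell_labels()
  if (length(n_per_cell) == 1L && is.null(names(n_per_cell))) {
    n_per_cell <- stats::setNames(rep(as.integer(n_per_cell), 4), labs)
  } else {
    if (!all(labs %in% names(n_per_cell))) {
      stop("study_design: named n_per_cell must cover all four cells")
    }
    n_per_cell <- stats::setNames(as.integer(n_per_cell[labs]), labs)
  }
  if (any(n_per_cell < 1)) stop("study_design: n_per_cell must be >= 1")
  structure(
    list(n_items = as.integer(n_items), n_reps = as.integer(n_reps),
         cells = labs, n_per_cell = n_per_cell, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d items x %d reps (%d study trials); n = %s (total %d)\n",
              x$n_items, x$n_reps, x$n_items * x$n_reps,
              paste(x$n_per_cell, collapse = "/"), sum(x$n_per_cell)))
  invisible(x)
}

#' Generate a massed or spaced study-phase trial sequence
#'
#' Builds one participant's ordered sequence of study trials (0-based item
#' indices, each item appearing exactly `n_reps` times):
#' * `"massed"` -- items are put in a uniformly random order and each
#'   item's repetitions are presented back-to-back, so the gap between
#'   consecutive occurrences of an item is always 1;
#' * `"spaced"` -- one uniformly random permutation of the items is
#'   presented, then presented again in the same order, `n_reps` times in
#'   total. Every repetition of an item therefore occurs only after all
#'   other items have been studied once more (gap exactly `n_items`).
#'
#' The spaced scheme is the unique block structure guaranteeing that all
#' other items intervene between any two repetitions; independent
#' per-block shuffles can violate that at block boundaries.
#'
#' @param condition `"massed"` or `"spaced"`.
#' @param n_items Number of distinct items, >= 1.
#' @param n_reps Repetitions per item, >= 1.
#' @param seed Integer seed; the sequence is a deterministic function of
#'   it.
#' @return Object of class `trial_sequence`: list with `condition` and
#'   `items` (integer vector of length `n_items * n_reps`).
#' @export
make_study_sequence <- function(condition, n_items, n_reps, seed = 1) {
  if (!condition %in% sequence_levels()) {
    stop("make_study_sequence: unknown sequence condition '", condition,
         "' (expected 'massed' or 'spaced')")
  }
  if (n_items < 1) stop("make_study_sequence: n_items must be >= 1")
  if (n_reps < 1) stop("make_study_sequence: n_reps must be >= 1")
  perm <- with_seed(seed, sample.int(n_items)) - 1L  # 0-based
  items <- if (condition == "massed") {
    rep(perm, each = n_reps)
  } else {
    rep(perm, times = n_reps)
  }
  structure(list(condition = condition, items = items),
            class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("trial_sequence (%s): %d trials over %d items\n",
              x$condition, length(x$items), length(unique(x$items))))
  invisible(x)
}

#' Write a trial sequence as a one-item-per-line CSV
#'
#' @param seq A [make_study_sequence()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_sequence <- function(seq, path) {
  utils::write.csv(data.frame(trial = seq_along(seq$items) - 1L,
                              item = seq$items),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw participant-level probabilities from a mode/concentration beta
#'
#' Samples from Beta(alpha, beta) with the shapes implied by mode `mu` and
#' concentration `kappa` (see [shapes_from_mode_concentration()]).
#'
#' @param mu Mode, in (0, 1).
#' @param kappa Concentration, > 2.
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of draws in (0, 1).
#' @export
draw_theta <- function(mu, kappa, n_draws, seed = 1) {
  if (kappa <= 2) {
    stop("draw_theta: kappa must exceed 2 (mode parameterization undefined)")
  }
  sh <- shapes_from_mode_concentration(mu, kappa)
  with_seed(seed, stats::rbeta(n_draws, sh["alpha"], sh["beta"]))
}

#' Simulate a complete 2x2 recall experiment
#'
#' Generates one synthetic dataset from the model's own generative chain.
#' For every participant in cell (e, s): a recall probability
#' `theta ~ Beta(alpha_es, beta_es)` is drawn from that cell's true
#' mode/concentration parameters, and the number of correct recalls is
#' `Binomial(n_items, theta)`. The number of attempted (non-blank)
#' responses is drawn the same way from `attempt_truth` -- typically with
#' a mode near 1 and a high concentration, reproducing the ceiling at
#' `n_items` seen in real recall data -- and then clamped so
#' `n_attempted >= n_correct` (a correct answer is necessarily
#' non-blank).
#'
#' @param design A [study_design()].
#' @param truth Named list over [cell_labels()] of [cell_params()] for the
#'   recall (correct-count) distribution.
#' @param attempt_truth Same structure for the attempted-response
#'   distribution.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   it (defaults to the design's seed).
#' @return Records `data.frame` with columns `participant_id`,
#'   `enthusiasm`, `sequence`, `n_items`, `n_correct`, `n_attempted`.
#' @export
simulate_experiment <- function(design, truth, attempt_truth,
                                seed = design$seed) {
  labs <- cell_labels()
  for (nm in c("truth", "attempt_truth")) {
    x <- get(nm)
    missing_cells <- setdiff(labs, names(x))
    if (length(missing_cells)) {
      stop("simulate_experiment: ", nm, " is missing cell(s): ",
           paste(missing_cells, collapse = ", "))
    }
  }
  with_seed(seed, {
    rows <- lapply(labs, function(lab) {
      m <- design$n_per_cell[[lab]]
      tr <- truth[[lab]]
      at <- attempt_truth[[lab]]
      th_y <- stats::rbeta(m, tr$alpha, tr$beta)
      y <- stats::rbinom(m, design$n_items, th_y)
      th_a <- stats::rbeta(m, at$alpha, at$beta)
      a <- pmax(stats::rbinom(m, design$n_items, th_a), y)
      es <- strsplit(lab, ".", fixed = TRUE)[[1]]
      data.frame(participant_id = paste0(lab, "_", seq_len(m)),
                 enthusiasm = es[1], sequence = es[2],
                 n_items = design$n_items, n_correct = y, n_attempted = a,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate two groups of rating-scale responses
#'
#' Fixture generator for the robust two-group comparison: each group's
#' values are `mean + sd * t(nu)` noise. With `nu` large the data are
#' near-normal; small `nu` produces the heavy tails the robust model is
#' built for.
#'
#' @param group_means,group_sds Length-2 numeric vectors (group 1, group 2).
#' @param nu Degrees of freedom of the t noise, > 1.
#' @param n_per_group Length-2 integer vector of group sizes.
#' @param group_labels Labels used in the output (default `"enthusiastic"`,
#'   `"neutral"`).
#' @param seed Integer seed.
#' @return `data.frame` with columns `group` and `value`.
#' @export
simulate_ratings <- function(group_means, group_sds, nu, n_per_group,
                             group_labels = c("enthusiastic", "neutral"),
                             seed = 1) {
  if (any(group_sds <= 0)) stop("simulate_ratings: sds must be positive")
  if (nu <= 1) stop("simulate_ratings: nu must exceed 1 (mean undefined)")
  stopifnot(length(group_means) == 2, length(group_sds) == 2,
            length(n_per_group) == 2, length(group_labels) == 2)
  with_seed(seed, {
    vals <- unlist(lapply(1:2, function(g) {
      group_means[g] + group_sds[g] * stats::rt(n_per_group[g], df = nu)
    }))
    data.frame(group = rep(group_labels, times = n_per_group),
               value = vals, stringsAsFactors = FALSE)
  })
}

#' Build a per-cell truth map for the simulator
#'
#' Convenience constructor for the `truth` / `attempt_truth` arguments of
#' [simulate_experiment()]: one [cell_params()] per cell, from vectors
#' recycled over [cell_labels()] order.
#'
#' @param mu Modes, length 1 or 4 (cell order: enthusiastic.massed,
#'   neutral.massed, enthusiastic.spaced, neutral.spaced).
#' @param kappa Concentrations, length 1 or 4.
#' @return Named list of `cell_params` over the four cells.
#' @export
make_cell_truth <- function(mu, kappa) {
  labs <- cell_labels()
  mu <- rep_len(mu, 4)
  kappa <- rep_len(kappa, 4)
  stats::setNames(lapply(1:4, function(i) cell_params(mu[i], kappa[i])), labs)
}

#' Default attempts-generating parameters
#'
#' A beta at mode 0.999 with concentration 40 puts roughly half the
#' simulated participants at the ceiling (all items attempted), matching
#' the strong ceiling typically seen in attempted-response counts, while
#' leaving enough spread below the ceiling for the concentration
#' parameter to be informative.
#'
#' @param mu Mode of the attempt distribution.
#' @param kappa Concentration.
#' @return Named list of `cell_params` over the four cells.
#' @export
default_attempt_truth <- function(mu = 0.999, kappa = 40) {
  make_cell_truth(mu, kappa)
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
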