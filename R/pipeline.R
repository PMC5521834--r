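#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# canonical record columns
RECORD_COLS <- c("participant_id", "enthusiasm", "sequence",
                 "n_items", "n_correct", "n_attempted")

# Validate a records table in place; stops with a labeled error on the
# first structural problem. Returns the (possibly type-coerced) table.
validate_records <- function(records, require_attempts = TRUE) {
  miss <- setdiff(RECORD_COLS, names(records))
  if (length(miss)) {
    stop("records: missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- row_problems(records)
  if (length(bad$row)) {
    stop("records: invalid row(s) ", paste(utils::head(bad$row, 5), collapse = ", "),
         ": ", bad$reason[1])
  }
  records
}

# per-row invariant check; returns list(row = indices, reason = messages)
row_problems <- function(records) {
  rows <- integer(0); reasons <- character(0)
  flag <- function(sel, why) {
    if (any(sel, na.rm = TRUE)) {
      sel[is.na(sel)] <- TRUE
      rows <<- c(rows, which(sel))
      reasons <<- c(reasons, rep(why, sum(sel)))
    }
  }
  flag(!records$enthusiasm %in% enthusiasm_levels(),
       "unknown enthusiasm label")
  flag(!records$sequence %in% sequence_levels(),
       "unknown sequence label")
  flag(records$n_correct < 0 | records$n_correct > records$n_attempted,
       "bounds violated: need 0 <= n_correct <= n_attempted")
  flag(records$n_attempted > records$n_items,
       "bounds violated: n_attempted exceeds n_items")
  ord <- order(rows)
  dup <- duplicated(rows[ord])
  list(row = rows[ord][!dup], reason = reasons[ord][!dup])
}

#' Load a canonical per-participant recall table from CSV
#'
#' Reads, optionally renames (for adapting an external deposit whose
#' column names differ), and validates the canonical schema:
#' `participant_id, enthusiasm, sequence, n_items, n_correct,
#' n_attempted`, plus any extra rating columns, which are carried
#' through untouched.
#'
#' @param path CSV file.
#' @param column_map Optional named character vector mapping canonical
#'   names to source column names, e.g.
#'   `c(n_correct = "num_exact_matches")`.
#' @param n_items If given, every row must declare this test length.
#' @param on_invalid `"error"` (default): stop at the first invalid row,
#'   citing its row number; `"drop"`: discard invalid rows and attach a
#'   `rejected` attribute listing their row numbers and reasons.
#' @return Validated records `data.frame`.
#' @export
load_recall_table <- function(path, column_map = NULL, n_items = NULL,
                              on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("load_recall_table: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("load_recall_table: empty table: ", path)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("load_recall_table: mapped source column '", src, "' not found")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  miss <- setdiff(RECORD_COLS, names(df))
  if (length(miss)) {
    stop("load_recall_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  if (!is.null(n_items)) {
    if (any(df$n_items != n_items)) {
      bad <- which(df$n_items != n_items)
      msg <- paste0("n_items differs from declared ", n_items,
                    " in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
      if (on_invalid == "error") stop("load_recall_table: ", msg)
      df <- df[-bad, , drop = FALSE]
    }
  }
  bad <- row_problems(df)
  if (length(bad$row)) {
    if (on_invalid == "error") {
      stop("load_recall_table: row ", bad$row[1], ": ", bad$reason[1])
    }
    rejected <- data.frame(row = bad$row, reason = bad$reason)
    df <- df[-bad$row, , drop = FALSE]
    message("load_recall_table: dropped ", nrow(rejected), " invalid row(s)")
    attr(df, "rejected") <- rejected
  }
  if (nrow(df) == 0L) stop("load_recall_table: no valid rows remain")
  rownames(df) <- NULL
  df
}

#' Write a records table as canonical CSV
#'
#' @param records Records `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recall_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics per condition and overall
#'
#' For each of the four cells and the whole sample: means and sample
#' standard deviations (n - 1 denominator) of correct, incorrect
#' (`n_attempted - n_correct`) and blank (`n_items - n_attempted`)
#' responses.
#'
#' @param records Records `data.frame`.
#' @return `data.frame` with one row per cell plus `"overall"`.
#' @export
summarize_descriptives <- function(records) {
  if (nrow(records) == 0L) stop("summarize_descriptives: empty records")
  validate_records(records)
  correct <- records$n_correct
  incorrect <- records$n_attempted - records$n_correct
  blank <- records$n_items - records$n_attempted
  cl <- record_cell(records)
  one <- function(sel, label) {
    data.frame(condition = label, n = sum(sel),
               correct_mean = mean(correct[sel]), correct_sd = stats::sd(correct[sel]),
               incorrect_mean = mean(incorrect[sel]), incorrect_sd = stats::sd(incorrect[sel]),
               blank_mean = mean(blank[sel]), blank_sd = stats::sd(blank[sel]),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(cell_labels(), function(lab) one(cl == lab, lab))
  rbind(do.call(rbind, rows), one(rep(TRUE, length(correct)), "overall"))
}

#' Pipeline configuration
#'
#' Bundles everything [run_full_analysis()] needs; a persisted config
#' plus the input data reproduce the outputs exactly.
#'
#' @param input Path to a canonical CSV, or a records `data.frame`.
#' @param config A [chain_config()] shared by all model fits.
#' @param prior A [prior_spec()].
#' @param n_items Test length used to scale contrasts to items.
#' @param ratings Optional named list of rating tables (each a
#'   `data.frame` with `group`, `value`) to compare with
#'   [fit_two_group_robust()].
#' @param out_dir Optional directory; when given, the report JSON, chain
#'   CSVs and figures are written there.
#' @param column_map Passed to [load_recall_table()] when `input` is a
#'   path.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, config = chain_config(),
                            prior = prior_spec(), n_items = 36,
                            ratings = NULL, out_dir = NULL,
                            column_map = NULL) {
  structure(list(input = input, config = config, prior = prior,
                 n_items = n_items, ratings = ratings, out_dir = out_dir,
                 column_map = column_map),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or accepts) the records table, computes descriptives, fits the
#' hierarchical beta-binomial model to the correct counts and to the
#' attempted counts, derives every reported contrast (both main effects,
#' the interaction and the difference of main effects on recall accuracy
#' in items; both main effects and the interaction on the attempts
#' concentration), runs convergence diagnostics, fits the robust
#' two-group model to any supplied rating items, and builds the figures.
#' When `out_dir` is set, a JSON report, chain CSVs and PNG figures are
#' written there; the report carries the master seed and a hash of the
#' configuration and data so outputs are traceable.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list (class `analysis_report`) with elements
#'   `records`, `descriptives`, `fit_correct`, `fit_attempted`,
#'   `contrasts` (named list of `contrast_summary`), `diagnostics`,
#'   `ratings` (named list of `robust_fit`), `figures`, `report` (the
#'   JSON-serializable summary).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  records <- if (is.character(cfg$input)) {
    load_recall_table(cfg$input, column_map = cfg$column_map)
  } else {
    validate_records(cfg$input)
  }

  desc <- summarize_descriptives(records)

  fit_y <- run_mcmc(records, prior = cfg$prior, config = cfg$config,
                    outcome = "n_correct")
  fit_a <- run_mcmc(records, prior = cfg$prior, config = cfg$config,
                    outcome = "n_attempted")

  contrasts <- list(
    mu_spacing = mu_contrast_items(fit_y, "sequence", cfg$n_items),
    mu_enthusiasm = mu_contrast_items(fit_y, "enthusiasm", cfg$n_items),
    mu_interaction = interaction_contrast(fit_y, "items", cfg$n_items),
    mu_effect_size_difference = effect_size_difference(fit_y, cfg$n_items),
    kappa_spacing = kappa_contrast(fit_a, "sequence"),
    kappa_enthusiasm = kappa_contrast(fit_a, "enthusiasm"),
    kappa_interaction = interaction_contrast(fit_a, "kappa")
  )

  diagnostics <- list(correct = diagnose(fit_y), attempted = diagnose(fit_a))

  rating_fits <- NULL
  if (!is.null(cfg$ratings)) {
    rating_fits <- lapply(cfg$ratings, function(tab) {
      fit_two_group_robust(tab$value, tab$group, config = cfg$config)
    })
  }

  figures <- list(
    counts_correct = plot_counts(records, "n_correct"),
    counts_attempted = plot_counts(records, "n_attempted"),
    contrasts_mu = plot_contrasts(contrasts[c("mu_spacing", "mu_enthusiasm",
                                              "mu_interaction")]),
    contrasts_kappa = plot_contrasts(contrasts[c("kappa_spacing",
                                                 "kappa_enthusiasm",
                                                 "kappa_interaction")])
  )

  provenance <- c(
    stats::setNames(rep("mu_contrast_items / interaction_contrast / effect_size_difference",
                        4),
                    c("mu_spacing", "mu_enthusiasm", "mu_interaction",
                      "mu_effect_size_difference")),
    stats::setNames(rep("kappa_contrast / interaction_contrast", 3),
                    c("kappa_spacing", "kappa_enthusiasm", "kappa_interaction")),
    descriptives = "summarize_descriptives",
    diagnostics = "gelman_rubin / effective_sample_size"
  )

  report <- list(
    seed = cfg$config$seed,
    config_hash = rlang::hash(list(unclass(cfg$config), unclass(cfg$prior),
                                   cfg$n_items, records)),
    n_participants = nrow(records),
    descriptives = desc,
    contrasts = do.call(rbind, lapply(contrasts, as.data.frame)),
    diagnostics = diagnostics,
    rating_differences = if (!is.null(rating_fits)) {
      do.call(rbind, lapply(rating_fits, function(f) as.data.frame(f$difference)))
    },
    provenance = as.list(provenance)
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    write_chain_set(fit_y, file.path(cfg$out_dir, "chains_correct"))
    write_chain_set(fit_a, file.path(cfg$out_dir, "chains_attempted"))
    for (nm in names(figures)) {
      ggplot2::ggsave(file.path(cfg$out_dir, paste0(nm, ".png")),
                      figures[[nm]], width = 6, height = 4, dpi = 150)
    }
  }

  invisible(structure(
    list(records = records, descriptives = desc,
         fit_correct = fit_y, fit_attempted = fit_a,
         contrasts = contrasts, diagnostics = diagnostics,
         ratings = rating_fits, figures = figures, report = report),
    class = "analysis_report"))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d participants\n", nrow(x$records)))
  for (ctr in x$contrasts) print(ctr)
  if (!is.null(x$ratings)) for (f in x$ratings) print(f$difference)
  invisible(x)
}

#' Dot plot of per-participant counts by condition
#'
#' One point per participant, horizontal bars at condition means --
#' the raw-data panel of the standard results figure.
#'
#' @param records Records `data.frame`.
#' @param outcome `"n_correct"` or `"n_attempted"`.
#' @return A ggplot object.
#' @export
plot_counts <- function(records, outcome = c("n_correct", "n_attempted")) {
  outcome <- match.arg(outcome)
  df <- data.frame(cell = record_cell(records), y = records[[outcome]])
  means <- stats::aggregate(y ~ cell, df, mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5,
                        position = ggplot2::position_jitter(
                          width = 0.15, height = 0.15, seed = nrow(df))) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(ymin = .data$y, ymax = .data$y),
                           width = 0.5, linewidth = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (outcome == "n_correct") "items correctly recalled"
                      else "attempted (non-blank) responses") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Posterior contrast densities with HDI bars
#'
#' @param contrasts Named list of `contrast_summary` objects.
#' @return A ggplot object (one facet per contrast, mode marked, HDI as
#'   a bar at the base).
#' @export
plot_contrasts <- function(contrasts) {
  dens <- do.call(rbind, lapply(names(contrasts), function(nm) {
    ctr <- contrasts[[nm]]
    d <- stats::density(ctr$draws, n = 256)
    data.frame(contrast = ctr$name, x = d$x, y = d$y)
  }))
  bars <- do.call(rbind, lapply(names(contrasts), function(nm) {
    ctr <- contrasts[[nm]]
    data.frame(contrast = ctr$name, lo = ctr$hdi$lo, hi = ctr$hdi$hi,
               mode = ctr$mode)
  }))
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_area(fill = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_segment(data = bars,
                          ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       y = 0, yend = 0),
                          linewidth = 1.5) +
    ggplot2::geom_point(data = bars,
                        ggplot2::aes(x = .data$mode, y = 0), size = 2) +
    ggplot2::facet_wrap(~contrast, ncol = 1, scales = "free") +
    ggplot2::labs(x = "posterior contrast", y = "density") +
    ggplot2::theme_minimal()
}
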