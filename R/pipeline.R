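#' Run the full energy-landscape analysis pipeline
#'
#' Executes every stage of the analysis on a cohort: per-subject
#' binarization, per-group pooling, pairwise maximum-entropy fitting,
#' landscape construction (minima, basins, disconnectivity, major/minor
#' classification), per-subject dynamic metrics on the subject's group
#' landscape, a Metropolis random-walk simulation per group, Welch group
#' comparisons, and score correlations. The per-group model / per-subject
#' dynamics split mirrors the study design the method was built for:
#' pattern statistics are too sparse to fit a model per subject, while
#' dynamic indices and score correlations are subject-level.
#'
#' @param cohort A [generate_cohort()] result, a [read_cohort()] result, or
#'   any list with `manifest` (columns `subject_id`, `group`, `score`) and
#'   `series` (named list of `T x N` numeric matrices).
#' @param fit_config List of [fit_mem()] settings (`step_alpha`, `tol`,
#'   `max_iter`).
#' @param walk_steps Steps of the per-group random-walk simulation.
#' @param walk_seed Seed of the simulation stage.
#' @param correlate_group Restrict score correlations to one group label,
#'   or `NULL` (default) to use all subjects.
#' @return An object of class `landscape_pipeline`: list with `groups`
#'   (named list per group: `fit`, `landscape`, `disconnectivity`,
#'   `labeling`, `simulated`), `metrics` (per-subject tibble joined with
#'   the manifest), `comparisons` (Welch tests per metric; `NULL` with one
#'   group), `correlations` (Pearson vs score), and `config`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' res <- run_landscape_pipeline(cohort)
#' res$comparisons
#' }
#' @export
run_landscape_pipeline <- function(cohort,
                                   fit_config = list(step_alpha = 0.2,
                                                     tol = 1e-5,
                                                     max_iter = 500000L),
                                   walk_steps = 100000L,
                                   walk_seed = 1L,
                                   correlate_group = NULL) {
  man <- cohort$manifest
  series <- cohort$series
  stopifnot(is.data.frame(man), all(c("subject_id", "group", "score") %in% names(man)),
            is.list(series), all(man$subject_id %in% names(series)))
  n_cols <- vapply(series, ncol, integer(1))
  if (length(unique(n_cols)) != 1L) {
    stop("Stage `validate`: subjects disagree on the number of channels (",
         paste(sort(unique(n_cols)), collapse = ", "), ").", call. = FALSE)
  }

  binary <- with_stage("binarize", lapply(series, binarize))
  states <- with_stage("encode", lapply(binary, encode_states))

  group_names <- unique(as.character(man$group))
  groups <- list()
  for (g in group_names) {
    ids <- man$subject_id[man$group == g]
    pooled <- with_stage("pool", pool_group(binary[ids]))
    fit <- with_stage("fit", fit_mem(pooled,
                                     step_alpha = fit_config$step_alpha,
                                     tol = fit_config$tol,
                                     max_iter = fit_config$max_iter))
    landscape <- with_stage("landscape", energy_landscape(fit))
    minima <- with_stage("landscape", find_local_minima(landscape))
    disc <- with_stage("landscape", build_disconnectivity(landscape, minima))
    labeling <- with_stage("classify", align_major_labels(
      classify_states(disc, landscape), landscape$n_rois))
    simulated <- with_stage("simulate",
                            simulated_metrics(landscape, labeling,
                                              n_steps = walk_steps,
                                              seed = walk_seed))
    groups[[g]] <- list(fit = fit, landscape = landscape,
                        disconnectivity = disc, labeling = labeling,
                        simulated = simulated)
  }

  metrics <- with_stage("dynamics", dplyr::bind_rows(lapply(
    man$subject_id,
    function(sid) {
      g <- as.character(man$group[man$subject_id == sid])
      subject_metrics(states[[sid]], groups[[g]]$labeling, subject_id = sid)
    })))
  metrics <- dplyr::left_join(man, metrics, by = "subject_id")

  comparisons <- NULL
  if (length(group_names) == 2L) {
    comparisons <- with_stage("stats", compare_groups(metrics))
  }
  corr_data <- metrics
  if (!is.null(correlate_group)) {
    corr_data <- metrics[metrics$group == correlate_group, , drop = FALSE]
  }
  correlations <- with_stage("stats", correlate_with_score(corr_data))

  structure(list(groups = groups, metrics = metrics,
                 comparisons = comparisons, correlations = correlations,
                 config = list(fit = fit_config, walk_steps = walk_steps,
                               walk_seed = walk_seed,
                               correlate_group = correlate_group)),
            class = "landscape_pipeline")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("Stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.landscape_pipeline <- function(x, ...) {
  cat("Energy-landscape pipeline:", length(x$groups), "group(s),",
      nrow(x$metrics), "subjects\n")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("  %s: %d minima, D2 = %s bits, converged = %s\n", g,
                nrow(gr$labeling$minima), signif(gr$fit$d2_bits, 3),
                gr$fit$converged))
  }
  invisible(x)
}

#' Serialize pipeline results
#'
#' Writes the per-subject metrics, group comparisons and correlations as
#' CSV, each group's fit and landscape as JSON, and a small run log with
#' the configuration.
#'
#' @param result A [run_landscape_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  stopifnot(inherits(result, "landscape_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$metrics, file.path(dir, "subject_metrics.csv"))
  if (!is.null(result$comparisons)) {
    readr::write_csv(result$comparisons, file.path(dir, "group_comparisons.csv"))
  }
  readr::write_csv(result$correlations, file.path(dir, "score_correlations.csv"))
  for (g in names(result$groups)) {
    gr <- result$groups[[g]]
    write_mem_fit(gr$fit, file.path(dir, paste0("fit_", g, ".json")))
    write_landscape(gr$landscape, gr$disconnectivity, gr$labeling,
                    file.path(dir, paste0("landscape_", g, ".json")))
  }
  jsonlite::write_json(
    list(r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("elascape")),
         config = result$config),
    file.path(dir, "run_log.json"), auto_unbox = TRUE)
  invisible(dir)
}
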