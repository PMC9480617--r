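default_thresholds <- list(
  EC = c(regression = 0.10, classification = 0.10),
  EO = c(regression = 0.05, classification = 0.20)
)

#' Configuration of a full analysis run
#'
#' Bundles every input and knob of [run_pipeline()]: the data source (a
#' synthetic [cohort_config()], a CoP CSV, or a precomputed feature table
#' with scores), the condition and task, the selection threshold (defaulting
#' to the condition-and-task-specific values 0.10 eyes-closed, 0.05
#' eyes-open regression, 0.20 eyes-open classification), the complexity
#' sweep budget and all seeds.
#'
#' @param input A [cohort_config()], or a list with `features` (data frame
#'   whose numeric columns are the 16 primaries) and `scores`, or a list
#'   with `cop_csv` (path) plus `scores` and `sampling_rate`.
#' @param condition `"EC"` or `"EO"`.
#' @param task `"regression"` or `"classification"`.
#' @param threshold Probe-risk retention threshold; `NULL` picks the
#'   condition-and-task default.
#' @param n_probes Number of random probes (default 100).
#' @param max_hidden Largest complexity tried (default 5).
#' @param fidelity `"test"` (20 LOO restarts per complexity) or `"paper"`
#'   (300); `n_restarts` overrides either.
#' @param n_restarts LOO restarts per complexity, or `NULL`.
#' @param screen_restarts Restarts for Jacobian screening fits.
#' @param fraction Training/validation fraction (default 0.70).
#' @param provenance Normalisation reference, `"whole-sample"` or
#'   `"training-only"`.
#' @param seeds Named list of integer seeds: `split`, `probes`, `restarts`,
#'   `baseline`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, condition = "EC",
                       task = c("regression", "classification"),
                       threshold = NULL, n_probes = 100, max_hidden = 5L,
                       fidelity = c("test", "paper"), n_restarts = NULL,
                       screen_restarts = 3L, fraction = 0.70,
                       provenance = c("whole-sample", "training-only"),
                       seeds = list()) {
  task <- match.arg(task)
  fidelity <- match.arg(fidelity)
  provenance <- match.arg(provenance)
  condition <- match.arg(condition, c("EC", "EO"))
  if (is.null(threshold)) threshold <- default_thresholds[[condition]][[task]]
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (is.null(n_restarts))
    n_restarts <- if (fidelity == "paper") 300L else 20L
  seeds <- utils::modifyList(list(split = 1L, probes = 1L, restarts = 1L,
                                  baseline = 1L), seeds)
  structure(list(input = input, condition = condition, task = task,
                 threshold = threshold, n_probes = n_probes,
                 max_hidden = as.integer(max_hidden),
                 n_restarts = as.integer(n_restarts),
                 screen_restarts = as.integer(screen_restarts),
                 fraction = fraction, provenance = provenance, seeds = seeds),
            class = "run_config")
}

resolve_input <- function(config) {
  input <- config$input
  if (inherits(input, "cohort_config")) {
    cohort <- simulate_cohort(input)
    recs <- cohort$recordings
    keep <- vapply(recs, function(r) r$condition == config$condition,
                   logical(1))
    if (!any(keep))
      stop(sprintf("condition %s was not simulated", config$condition),
           call. = FALSE)
    filtered <- lapply(recs[keep], lowpass_filter)
    features <- extract_feature_table(filtered)
    scores <- cohort$scores$score[match(features$subject_id,
                                        cohort$scores$subject_id)]
    return(list(features = features, scores = scores))
  }
  if (!is.null(input$cop_csv)) {
    recs <- read_cop_csv(input$cop_csv, input$sampling_rate)
    keep <- vapply(recs, function(r) r$condition == config$condition,
                   logical(1))
    filtered <- lapply(recs[keep], lowpass_filter)
    features <- extract_feature_table(filtered)
    scores <- input$scores[match(features$subject_id,
                                 names(input$scores) %||%
                                   seq_along(input$scores))]
    return(list(features = features, scores = as.numeric(scores)))
  }
  if (!is.null(input$features)) {
    return(list(features = input$features, scores = input$scores))
  }
  stop("unrecognised input: give a cohort_config, a cop_csv, or features + scores",
       call. = FALSE)
}

#' Run the full modelling pipeline
#'
#' Executes the analysis end to end for one condition and task: ingest (or
#' simulate) the recordings, low-pass filter, extract the 16 postural
#' features, z-score, build cross-terms, label by median split, draw the
#' stratified 70/30 split, select variables by OFR with random probes on
#' the training/validation rows only, sweep model complexity by Jacobian
#' screening and leave-one-out on the same rows, train the selected model
#' with multi-restart optimisation, and evaluate it on the held-out test
#' set against the task's baseline. The test rows never enter selection or
#' model choice. A rerun with the identical configuration reproduces every
#' artifact bit for bit.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes `selection.json`, `sweep.csv`,
#'   `model.json` and `report.json` there.
#' @return An object of class `sway_run`: the selection, sweep, final model,
#'   evaluation report, split bookkeeping and the configuration.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  data <- resolve_input(config)
  feat_cols <- data$features[vapply(data$features, is.numeric, logical(1))]
  feat_cols <- feat_cols[setdiff(names(feat_cols), c("sample_index"))]
  cohort <- labeled_cohort(feat_cols, data$scores,
                           fraction = config$fraction, stratify = TRUE,
                           split_seed = config$seeds$split,
                           provenance = config$provenance)
  trainval <- which(cohort$split == "trainval")
  test <- which(cohort$split == "test")
  y_all <- if (config$task == "regression") cohort$scores else cohort$status
  X_all <- cohort$candidates$values

  selection <- select_variables(X_all[trainval, , drop = FALSE],
                                y_all[trainval],
                                threshold = config$threshold,
                                n_probes = config$n_probes,
                                probe_seed = config$seeds$probes)
  if (!length(selection$retained))
    stop("stage selection: no variables retained; modelling refused",
         call. = FALSE)

  X_sel <- X_all[, selection$retained, drop = FALSE]
  sweep <- sweep_complexity(X_sel[trainval, , drop = FALSE], y_all[trainval],
                            task = config$task,
                            max_hidden = config$max_hidden,
                            n_restarts = config$n_restarts,
                            base_seed = config$seeds$restarts,
                            screen_restarts = config$screen_restarts)
  final <- slnn_multistart(X_sel[trainval, , drop = FALSE], y_all[trainval],
                           task = config$task,
                           n_hidden = sweep$selected$n_hidden,
                           n_restarts = max(config$n_restarts,
                                            config$screen_restarts),
                           base_seed = derive_seed(config$seeds$restarts,
                                                   99991L))$best

  report <- if (config$task == "regression") {
    evaluate_regression(final, X_sel[test, , drop = FALSE], y_all[test],
                        y_all[trainval])
  } else {
    evaluate_classifier(final, X_sel[test, , drop = FALSE], y_all[test],
                        baseline_seed = config$seeds$baseline)
  }
  trainval_report <- if (config$task == "regression") {
    evaluate_regression(final, X_sel[trainval, , drop = FALSE],
                        y_all[trainval], y_all[trainval])
  } else {
    evaluate_classifier(final, X_sel[trainval, , drop = FALSE],
                        y_all[trainval],
                        baseline_seed = config$seeds$baseline)
  }

  run <- structure(list(config = config, selection = selection,
                        sweep = sweep, model = final, report = report,
                        trainval_report = trainval_report,
                        split = cohort$split, median_used = cohort$median_used,
                        n_trainval = length(trainval), n_test = length(test)),
                   class = "sway_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_selection_json(selection, file.path(out_dir, "selection.json"))
    write_sweep_csv(sweep, file.path(out_dir, "sweep.csv"))
    write_model_json(final, file.path(out_dir, "model.json"),
                     normalization = cohort$primary_normalization)
    rep_out <- report
    rep_out$roc_points <- NULL
    jsonlite::write_json(
      list(condition = config$condition, task = config$task,
           threshold = config$threshold, seeds = config$seeds,
           n_trainval = run$n_trainval, n_test = run$n_test,
           selected_n_hidden = sweep$selected$n_hidden,
           test = unclass(rep_out)[setdiff(names(rep_out),
                                           c("predictions", "task"))],
           trainval = list(
             rmse = trainval_report$rmse %||% NULL,
             pearson_r = trainval_report$pearson_r %||% NULL,
             accuracy = trainval_report$accuracy %||% NULL,
             auc = trainval_report$auc %||% NULL)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.sway_run <- function(x, ...) {
  cat(sprintf("Pipeline run: condition %s, %s, threshold %.2f\n",
              x$config$condition, x$config$task, x$config$threshold))
  cat(sprintf("  %d trainval / %d test subjects, median score %g\n",
              x$n_trainval, x$n_test, x$median_used))
  cat(sprintf("  retained variables: %s\n",
              paste(x$selection$retained, collapse = "; ")))
  cat(sprintf("  selected complexity: %d hidden unit(s)\n",
              x$sweep$selected$n_hidden))
  print(x$report)
  invisible(x)
}
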