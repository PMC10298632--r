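# Threshold-0.5 evaluation: confusion counts, accuracy, sensitivity (true
# positive rate) and specificity (true negative rate), plus the ablation
# harness over input-sequence combinations.

#' Compute classification metrics at the fixed 0.5 threshold
#'
#' Accuracy = (TP + TN) / total, sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), all as percentages. A metric with an empty denominator
#' (e.g. specificity when no negatives were evaluated) is reported as `NA`
#' rather than 0 or 100.
#'
#' @param predictions Predicted labels in `{0, 1}`, or probabilities (values
#'   outside `{0, 1}` are thresholded at 0.5, ties to 1).
#' @param labels Ground-truth labels in `{0, 1}`, same length.
#' @param task,input_combination Optional annotations carried in the report.
#' @return An object of class `"metrics_report"`: list with `counts` (tp, tn,
#'   fp, fn), `accuracy`, `sensitivity`, `specificity` (percent), `task`,
#'   `input_combination`, `n`.
#' @export
compute_metrics <- function(predictions, labels, task = NA_character_,
                            input_combination = character(0)) {
  if (length(predictions) != length(labels)) {
    stop("'predictions' and 'labels' must have equal length", call. = FALSE)
  }
  if (!is_binary01(labels)) stop("'labels' must be binary 0/1", call. = FALSE)
  pred <- if (is_binary01(predictions)) predictions else
    as.integer(predictions >= 0.5)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
         accuracy = pct(tp + tn, length(labels)),
         sensitivity = pct(tp, tp + fn),
         specificity = pct(tn, tn + fp),
         task = task,
         input_combination = input_combination,
         n = length(labels)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f%%", round_half_up1(v))
  hdr <- if (!is.na(x$task)) sprintf(" [%s]", x$task) else ""
  comb <- if (length(x$input_combination) > 0) {
    sprintf(" (%s)", paste(x$input_combination, collapse = " + "))
  } else ""
  cat(sprintf("Metrics%s%s on %d exams\n", hdr, comb, x$n))
  cat(sprintf("  counts: tp %d, tn %d, fp %d, fn %d\n",
              x$counts["tp"], x$counts["tn"], x$counts["fp"], x$counts["fn"]))
  cat(sprintf("  accuracy %s, sensitivity %s, specificity %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity)))
  invisible(x)
}

#' Serialize / deserialize a metrics report as JSON
#'
#' @param report A `"metrics_report"`.
#' @param path JSON file path.
#' @return `save_metrics_report` returns `path` invisibly;
#'   `load_metrics_report` the report.
#' @export
save_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  payload <- unclass(report)
  payload$counts <- as.list(report$counts)  # keep names through JSON
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname save_metrics_report
#' @export
load_metrics_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- unlist(x$counts)
  structure(
    list(counts = counts,
         accuracy = x$accuracy %||% NA_real_,
         sensitivity = x$sensitivity %||% NA_real_,
         specificity = x$specificity %||% NA_real_,
         task = x$task %||% NA_character_,
         input_combination = as.character(x$input_combination %||% character(0)),
         n = x$n),
    class = "metrics_report")
}

#' Evaluate a fitted model on one split of a cohort
#'
#' One deterministic forward pass per exam at threshold 0.5. When explicit
#' `stats` are supplied they must match the model's preprocessing
#' fingerprint; a mismatch indicates the data were not preprocessed with the
#' model's training-split statistics and is an error.
#'
#' @param model A fitted [knet()] model.
#' @param data A cohort/directory as in [knet()].
#' @param split Split to evaluate (default `"test"`).
#' @param stats Optional [fit_norm_stats()] to cross-check against the
#'   model's fingerprint.
#' @return A `"metrics_report"`, with the per-exam prediction table attached
#'   as attribute `"predictions"`.
#' @export
evaluate_model <- function(model, data, split = "test", stats = NULL) {
  stopifnot(inherits(model, "knet"))
  if (!is.null(stats)) {
    same <- isTRUE(all.equal(stats$mean, model$fingerprint$mean)) &&
      isTRUE(all.equal(stats$sd, model$fingerprint$sd))
    if (!same) {
      stop("normalization statistics do not match the model's ",
           "preprocessing fingerprint", call. = FALSE)
    }
  }
  pred <- predict(model, data, split = split)
  rep <- compute_metrics(pred$label, pred$y, task = model$task,
                         input_combination = model$sequences)
  attr(rep, "predictions") <- pred
  rep
}

#' Default ablation grid: the seven input-sequence combinations
#'
#' The four single-sequence inputs and the three three-sequence
#' combinations of the standard knee protocol.
#'
#' @return A list of character vectors.
#' @export
ablation_combinations <- function() {
  list(
    "coronal_hybrid",
    "axial_t2",
    "sagittal_t1",
    "sagittal_t2",
    c("coronal_hybrid", "sagittal_t1", "sagittal_t2"),
    c("axial_t2", "coronal_hybrid", "sagittal_t1"),
    c("axial_t2", "sagittal_t1", "sagittal_t2")
  )
}

#' Train-and-evaluate ablation over input-sequence combinations
#'
#' Trains one MS-KNet per combination per task and evaluates it on the test
#' split, producing a matrix-shaped table: one row per combination, one
#' accuracy/sensitivity/specificity column triple per task.
#'
#' @param data A cohort/directory as in [knet()].
#' @param combinations List of sequence-type vectors (each of length 1-3);
#'   default [ablation_combinations()].
#' @param tasks Tasks to ablate (default all three).
#' @param seed Base seed; each fit derives its own deterministic seed.
#' @param ... Passed on to [knet()] (`epochs`, `backbone`, `lr`, ...).
#' @return A data frame of class `"ablation_table"` (`input` plus
#'   `<task>_accuracy`, `<task>_sensitivity`, `<task>_specificity` columns,
#'   percentages), with all individual `"metrics_report"`s attached as
#'   attribute `"reports"`.
#' @export
run_ablation <- function(data, combinations = ablation_combinations(),
                         tasks = TASKS, seed = 1L, ...) {
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  for (comb in combinations) {
    if (length(comb) < 1L || length(comb) > 3L) {
      stop("each combination must contain 1 to 3 sequence types", call. = FALSE)
    }
    if (!all(comb %in% SEQUENCE_TYPES)) {
      stop("unknown sequence type in combination: ",
           paste(setdiff(comb, SEQUENCE_TYPES), collapse = ", "),
           call. = FALSE)
    }
  }
  reports <- list()
  rows <- vector("list", length(combinations))
  for (ci in seq_along(combinations)) {
    comb <- combinations[[ci]]
    row <- list(input = paste(comb, collapse = " + "))
    for (ti in seq_along(tasks)) {
      task <- tasks[ti]
      fit_seed <- seed + 1000L * ci + ti
      model <- knet(data, task = task, sequences = comb, seed = fit_seed, ...)
      rep <- evaluate_model(model, data, split = "test")
      reports[[sprintf("%s|%s", row$input, task)]] <- rep
      row[[paste0(task, "_accuracy")]] <- rep$accuracy
      row[[paste0(task, "_sensitivity")]] <- rep$sensitivity
      row[[paste0(task, "_specificity")]] <- rep$specificity
    }
    rows[[ci]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  class(out) <- c("ablation_table", "data.frame")
  out
}

#' @export
print.ablation_table <- function(x, ...) {
  cat("Ablation over input-sequence combinations (test split, %)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) round_half_up1(v))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
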