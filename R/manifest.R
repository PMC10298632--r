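# Exam/label manifest: the table tying exam ids to per-sequence series paths,
# binary task labels and the train/test split.

MANIFEST_BASE_COLS <- c("exam_id", "patient_id", "split")

#' Validate a label manifest
#'
#' A manifest is a data frame with columns `exam_id`, `patient_id`, `split`
#' (`"train"` or `"test"`), one path column per sequence type present, and the
#' binary label columns `abnormality`, `meniscus`, `bone_edema`. Validation
#' enforces the label-consistency rule (an exam is abnormal whenever either
#' sub-task is positive), binary labels, unique exam ids, at most two exams
#' per patient, and disjoint train/test patients.
#'
#' @param df A data frame following the schema above.
#' @return The validated data frame with class `"label_manifest"`.
#' @export
label_manifest <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(MANIFEST_BASE_COLS, TASKS), names(df))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(MANIFEST_BASE_COLS, TASKS, SEQUENCE_TYPES))
  if (length(extra) > 0) {
    stop("unknown sequence_type column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$exam_id)) {
    stop("duplicated exam_id in manifest", call. = FALSE)
  }
  if (!all(df$split %in% c("train", "test"))) {
    stop("'split' must be 'train' or 'test'", call. = FALSE)
  }
  for (task in TASKS) {
    v <- df[[task]]
    if (!is.numeric(v) || !is_binary01(v)) {
      stop("label column '", task, "' must be binary 0/1", call. = FALSE)
    }
    df[[task]] <- as.integer(v)
  }
  bad <- df$abnormality < pmax(df$meniscus, df$bone_edema)
  if (any(bad)) {
    stop("label inconsistency: exam(s) ",
         paste(df$exam_id[bad], collapse = ", "),
         " have a positive sub-task label but abnormality = 0", call. = FALSE)
  }
  per_patient <- table(df$patient_id)
  if (any(per_patient > 2)) {
    stop("at most two exams per patient are allowed; offending patient(s): ",
         paste(names(per_patient)[per_patient > 2], collapse = ", "),
         call. = FALSE)
  }
  overlap <- intersect(df$patient_id[df$split == "train"],
                       df$patient_id[df$split == "test"])
  if (length(overlap) > 0) {
    stop("patient(s) appear in both train and test splits: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("label_manifest", "data.frame")
  df
}

#' Save a manifest as CSV
#'
#' @param manifest A [label_manifest()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "label_manifest"))
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a manifest CSV
#'
#' @param path CSV file written by [save_manifest()] (or following the same
#'   schema).
#' @return A [label_manifest()].
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (task in intersect(TASKS, names(df))) {
    v <- suppressWarnings(as.numeric(df[[task]]))
    if (anyNA(v)) stop("non-numeric label in column '", task, "'", call. = FALSE)
    df[[task]] <- v
  }
  label_manifest(df)
}

#' Summarize task prevalences per split
#'
#' For each split present (and overall), reports the number of exams, the
#' positive count per task, and the positive percentage rounded half-up to
#' one decimal — the convention of clinical cohort tables.
#'
#' @param manifest A [label_manifest()].
#' @return A data frame of class `"manifest_summary"` with columns `split`,
#'   `task`, `n`, `positives`, `percent`.
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "label_manifest"))
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  splits <- intersect(c("train", "test"), unique(manifest$split))
  groups <- c(as.list(splits), list(c("train", "test")))
  names(groups) <- c(splits, "overall")
  rows <- list()
  for (gname in names(groups)) {
    sub <- manifest[manifest$split %in% groups[[gname]], , drop = FALSE]
    for (task in TASKS) {
      pos <- sum(sub[[task]])
      rows[[length(rows) + 1L]] <- data.frame(
        split = gname, task = task, n = nrow(sub), positives = pos,
        percent = round_half_up1(100 * pos / nrow(sub)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("manifest_summary", "data.frame")
  out
}

#' @export
print.manifest_summary <- function(x, ...) {
  cat("Task prevalences by split\n")
  for (g in unique(x$split)) {
    sub <- x[x$split == g, , drop = FALSE]
    cat(sprintf("  %-8s (n = %d)\n", g, sub$n[1]))
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-12s %4d (%.1f%%)\n",
                  sub$task[i], sub$positives[i], sub$percent[i]))
    }
  }
  invisible(x)
}
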