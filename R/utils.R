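# Shared constants and small helpers.

#' MRI sequence types understood by the pipeline
#'
#' The four acquisition protocols of a routine non-contrast knee exam:
#' coronal hybrid (mixed T1/T2 weighting), axial T2, sagittal T1 and
#' sagittal T2.
#'
#' @export
SEQUENCE_TYPES <- c("coronal_hybrid", "axial_t2", "sagittal_t1", "sagittal_t2")

#' Binary classification tasks
#'
#' General abnormality, medial meniscus tear and bone marrow edema. Each exam
#' carries one 0/1 label per task; abnormality is 1 whenever either sub-task
#' label is 1.
#'
#' @export
TASKS <- c("abnormality", "meniscus", "bone_edema")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Round-half-up to one decimal, matching how clinical tables print percentages
# (base round() would round half to even).
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

# Population standard deviation (divides by n, not n - 1).
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

is_binary01 <- function(x) all(x %in% c(0, 1))
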