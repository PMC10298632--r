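# Synthetic multi-sequence knee phantom generator.
#
# The phantom is not an anatomical simulation: it is a smooth ellipse-and-band
# intensity field (two "bone" ellipses separated by a bright joint band)
# extruded across slices with slow through-slice drift, into which focal
# lesions are planted. Its purpose is to give every downstream stage —
# DICOM I/O, preprocessing, the CNN, training and evaluation — a fully
# deterministic, separable test bed without patient data.

PHANTOM_INTENSITY_SCALE <- 1000  # anatomy units -> stored integer pixel units

#' Configuration for the synthetic knee-phantom cohort
#'
#' Defaults reproduce the structure of a routine clinical cohort: task
#' prevalences of 71.1% (abnormality), 31.3% (meniscus tear) and 28.7%
#' (bone edema) with 9.2% meniscus/edema co-occurrence, slice counts between
#' 14 and 56, four co-registered sequence types derived from one shared
#' anatomy by deterministic contrast transforms, and a held-out test split of
#' 98/564 of exams.
#'
#' @param n_exams Number of exams to generate (>= 1).
#' @param prevalence_abnormal,prevalence_meniscus,prevalence_edema Marginal
#'   probabilities in `[0, 1]` that an exam is positive for each task.
#'   `prevalence_abnormal` must be at least the probability of meniscus-or-edema
#'   implied by the sub-task prevalences; the excess is realized as "other"
#'   focal abnormalities.
#' @param co_occurrence_rate Probability that an exam has both a meniscus tear
#'   and bone edema; at most `min(prevalence_meniscus, prevalence_edema)`.
#' @param slice_range Integer interval (length-2) of slice counts, within
#'   `[14, 56]`. Each exam draws its slice count uniformly from this range.
#' @param image_size Pre-resize spatial size in pixels (square slices).
#' @param lesion_contrast Peak lesion amplitude in anatomy units (the anatomy
#'   field spans roughly `[0.15, 1.3]`). Separability of the planted classes
#'   is governed by `lesion_contrast / noise_sd`.
#' @param noise_sd Standard deviation of the independent per-sequence Gaussian
#'   noise, in anatomy units.
#' @param sequence_types Subset of [SEQUENCE_TYPES] to generate per exam.
#' @param signal_sequences Subset of `sequence_types` whose images carry the
#'   lesion signal. Sequences outside this set image the lesion-free anatomy:
#'   useful for ablation experiments where only some streams are informative.
#' @param test_fraction Fraction of exams assigned to the test split.
#' @param seed Integer seed; the seed fully determines the cohort.
#' @return An object of class `"phantom_config"`.
#' @seealso [generate_cohort()]
#' @export
phantom_config <- function(n_exams,
                           prevalence_abnormal = 0.711,
                           prevalence_meniscus = 0.313,
                           prevalence_edema = 0.287,
                           co_occurrence_rate = 0.092,
                           slice_range = c(14L, 56L),
                           image_size = 256L,
                           lesion_contrast = 0.8,
                           noise_sd = 0.05,
                           sequence_types = SEQUENCE_TYPES,
                           signal_sequences = sequence_types,
                           test_fraction = 98 / 564,
                           seed = 1L) {
  if (!is.numeric(n_exams) || length(n_exams) != 1L || is.na(n_exams) || n_exams < 1) {
    stop("'n_exams' must be a positive integer", call. = FALSE)
  }
  n_exams <- as.integer(n_exams)
  for (p in c(prevalence_abnormal, prevalence_meniscus, prevalence_edema,
              co_occurrence_rate, test_fraction)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("prevalences, co-occurrence rate and test fraction must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (co_occurrence_rate > min(prevalence_meniscus, prevalence_edema) + 1e-12) {
    stop("'co_occurrence_rate' cannot exceed either sub-task prevalence", call. = FALSE)
  }
  p_any_sub <- prevalence_meniscus + prevalence_edema - co_occurrence_rate
  if (prevalence_abnormal < p_any_sub - 1e-12) {
    stop("'prevalence_abnormal' is below the meniscus-or-edema probability ",
         "implied by the sub-task prevalences", call. = FALSE)
  }
  slice_range <- as.integer(round(slice_range))
  if (length(slice_range) != 2L || slice_range[1] > slice_range[2] ||
      slice_range[1] < 14L || slice_range[2] > 56L) {
    stop("'slice_range' must be an integer interval within [14, 56]", call. = FALSE)
  }
  image_size <- as.integer(image_size)
  if (image_size < 32L || image_size %% 2L != 0L) {
    stop("'image_size' must be an even integer >= 32", call. = FALSE)
  }
  if (!is.numeric(lesion_contrast) || lesion_contrast <= 0) {
    stop("'lesion_contrast' must be positive", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be non-negative", call. = FALSE)
  }
  sequence_types <- match.arg(sequence_types, SEQUENCE_TYPES, several.ok = TRUE)
  signal_sequences <- match.arg(signal_sequences, SEQUENCE_TYPES, several.ok = TRUE)
  if (!all(signal_sequences %in% sequence_types)) {
    stop("'signal_sequences' must be a subset of 'sequence_types'", call. = FALSE)
  }
  structure(
    list(n_exams = n_exams,
         prevalence_abnormal = prevalence_abnormal,
         prevalence_meniscus = prevalence_meniscus,
         prevalence_edema = prevalence_edema,
         co_occurrence_rate = co_occurrence_rate,
         slice_range = slice_range,
         image_size = image_size,
         lesion_contrast = lesion_contrast,
         noise_sd = noise_sd,
         sequence_types = sequence_types,
         signal_sequences = signal_sequences,
         test_fraction = test_fraction,
         seed = as.integer(seed)),
    class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Phantom cohort configuration\n")
  cat(sprintf("  exams: %d  (test fraction %.3f)  seed: %d\n",
              x$n_exams, x$test_fraction, x$seed))
  cat(sprintf("  prevalences: abnormality %.3f, meniscus %.3f, edema %.3f (co-occurrence %.3f)\n",
              x$prevalence_abnormal, x$prevalence_meniscus,
              x$prevalence_edema, x$co_occurrence_rate))
  cat(sprintf("  slices per exam: %d-%d, %dx%d pixels\n",
              x$slice_range[1], x$slice_range[2], x$image_size, x$image_size))
  cat(sprintf("  lesion contrast %.3f, noise sd %.3f (ratio %.1f)\n",
              x$lesion_contrast, x$noise_sd,
              if (x$noise_sd > 0) x$lesion_contrast / x$noise_sd else Inf))
  cat("  sequences:", paste(x$sequence_types, collapse = ", "), "\n")
  if (!setequal(x$signal_sequences, x$sequence_types)) {
    cat("  signal restricted to:", paste(x$signal_sequences, collapse = ", "), "\n")
  }
  invisible(x)
}

# Smooth ellipse membership in [0, 1]: ~1 inside, ~0 outside, soft edge.
ellipse_field <- function(X, Y, cx, cy, ax, ay, soft = 0.08) {
  d2 <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2
  stats::plogis((1 - d2) / soft)
}

# Deterministic per-sequence contrast transforms applied to the shared
# anatomy. sagittal_t1 is the identity reference; sagittal_t2 is a gamma
# (T2-like) re-weighting; axial_t2 a nonlinear inverted window; coronal_hybrid
# the mean of the T1 and T2 contrasts.
sequence_contrast <- function(x, sequence_type) {
  switch(sequence_type,
    sagittal_t1    = x,
    sagittal_t2    = pmax(x, 0)^0.7,
    axial_t2       = pmax(1.15 - x, 0)^1.3,
    coronal_hybrid = (x + pmax(x, 0)^0.7) / 2,
    stop("unknown sequence_type: ", sequence_type, call. = FALSE))
}

# Sample the per-exam anatomy/lesion geometry. Lesion geometry is always
# sampled, even for negative exams: the unused "candidate" region is kept so
# that oracle classifiers can compare the same region across classes.
sample_exam_geometry <- function(s, cfg) {
  # anatomy jitter is kept small relative to the lesion signal: the phantom's
  # job is to carry a learnable class difference, not to model anatomical
  # variability (which would require far larger cohorts to average out)
  g <- list()
  g$cx <- stats::runif(1, 0.48, 0.52)
  g$femur <- list(cy = stats::runif(1, 0.255, 0.275), ax = stats::runif(1, 0.29, 0.31),
                  ay = stats::runif(1, 0.155, 0.165))
  g$tibia <- list(cy = stats::runif(1, 0.725, 0.745), ax = stats::runif(1, 0.29, 0.31),
                  ay = stats::runif(1, 0.155, 0.165))
  g$band_tilt <- stats::runif(1, -0.03, 0.03)
  g$band_width <- stats::runif(1, 0.034, 0.040)
  g$drift <- stats::runif(1, 0.02, 0.04)
  g$phase <- stats::runif(1, 0, 2 * pi)

  span <- function(min_len, max_len) {
    len <- sample(min_len:max_len, 1L)
    len <- min(len, s)
    k0 <- sample.int(s - len + 1L, 1L)
    c(k0, k0 + len - 1L)
  }
  # meniscus: crescent on the joint band, wide enough (~6-9 px at the
  # network's 224 input) to stay resolvable after the backbone's
  # downsampling stages
  mx <- stats::runif(1, 0.42, 0.58)
  g$meniscus <- list(
    cx = mx, cy = 0.5 + g$band_tilt * (mx - 0.5),
    r0 = stats::runif(1, 0.09, 0.12), rw = stats::runif(1, 0.03, 0.045),
    arc_center = pi / 2, arc_width = stats::runif(1, 1.0, 1.4),
    slices = span(4L, 7L))
  # edema: diffuse blob inside one bone
  bone <- if (stats::runif(1) < 0.5) g$femur else g$tibia
  g$edema <- list(
    cx = g$cx + stats::runif(1, -0.3, 0.3) * bone$ax,
    cy = bone$cy + stats::runif(1, -0.3, 0.3) * bone$ay,
    sigma = stats::runif(1, 0.08, 0.11),
    slices = span(5L, 9L))
  # other abnormality: focal bright spot anywhere central
  g$other <- list(
    cx = stats::runif(1, 0.38, 0.62), cy = stats::runif(1, 0.38, 0.62),
    sigma = stats::runif(1, 0.04, 0.06),
    slices = span(3L, 5L))
  g
}

# 2-D lesion intensity profile (anatomy units; signed) for one lesion type.
lesion_profile <- function(X, Y, geom, type, contrast) {
  if (type == "meniscus") {
    d <- sqrt((X - geom$cx)^2 + (Y - geom$cy)^2)
    ring <- exp(-((d - geom$r0)^2) / (2 * geom$rw^2))
    ang <- atan2(Y - geom$cy, X - geom$cx)
    dang <- abs(((ang - geom$arc_center + pi) %% (2 * pi)) - pi)
    sector <- exp(-(dang^2) / (2 * geom$arc_width^2))
    -contrast * ring * sector          # hypointense crescent discontinuity
  } else if (type == "edema") {
    d2 <- (X - geom$cx)^2 + (Y - geom$cy)^2
    contrast * exp(-d2 / (2 * geom$sigma^2))  # diffuse hyperintense blob
  } else {
    d2 <- (X - geom$cx)^2 + (Y - geom$cy)^2
    contrast * exp(-d2 / (2 * geom$sigma^2))  # small focal hyperintensity
  }
}

#' Generate a synthetic phantom cohort
#'
#' Draws task labels at the configured prevalences, builds one shared smooth
#' anatomy per exam, plants lesions for the positive tasks (each spanning at
#' least three consecutive slices), derives each requested sequence type from
#' the same anatomy by a deterministic contrast transform, adds independent
#' Gaussian noise, and quantizes to integer pixel units. The same seed yields
#' a bit-identical cohort.
#'
#' Lesion *candidate* geometry is sampled for every exam regardless of label,
#' and the candidate region masks are stored with each exam, so that
#' region-based oracle classifiers can be evaluated on positives and negatives
#' alike (see [lesion_region_means()]).
#'
#' @param config A [phantom_config()].
#' @return An object of class `"phantom_cohort"`: a list with elements
#'   `exams` (named list of exams, each holding `exam_id`, a named list
#'   `series` of [mri_series()] objects, a named integer `labels` vector and
#'   compact lesion masks), `manifest` (a [label_manifest()] data frame) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_exams
    pm <- cfg$prevalence_meniscus
    pe <- cfg$prevalence_edema
    co <- cfg$co_occurrence_rate
    p_any_sub <- pm + pe - co
    p_other <- if (p_any_sub < 1) {
      (cfg$prevalence_abnormal - p_any_sub) / (1 - p_any_sub)
    } else 0

    men <- stats::rbinom(n, 1L, pm)
    ed <- integer(n)
    for (i in seq_len(n)) {
      p_ed <- if (men[i] == 1L) {
        if (pm > 0) co / pm else 0
      } else {
        if (pm < 1) (pe - co) / (1 - pm) else 0
      }
      ed[i] <- stats::rbinom(1L, 1L, min(max(p_ed, 0), 1))
    }
    oth <- integer(n)
    neither <- men == 0L & ed == 0L
    oth[neither] <- stats::rbinom(sum(neither), 1L, min(max(p_other, 0), 1))
    abn <- as.integer(men == 1L | ed == 1L | oth == 1L)

    hw <- cfg$image_size
    ax_grid <- seq(0, 1, length.out = hw)
    Y <- matrix(ax_grid, hw, hw)          # row coordinate, grows downward
    X <- matrix(ax_grid, hw, hw, byrow = TRUE)

    slice_choices <- cfg$slice_range[1]:cfg$slice_range[2]
    exams <- vector("list", n)
    for (i in seq_len(n)) {
      s <- slice_choices[sample.int(length(slice_choices), 1L)]
      g <- sample_exam_geometry(s, cfg)
      lab <- c(abnormality = abn[i], meniscus = men[i], bone_edema = ed[i])
      applied <- c(meniscus = men[i] == 1L, edema = ed[i] == 1L,
                   other = oth[i] == 1L)

      profiles <- list(
        meniscus = lesion_profile(X, Y, g$meniscus, "meniscus", cfg$lesion_contrast),
        edema = lesion_profile(X, Y, g$edema, "edema", cfg$lesion_contrast),
        other = lesion_profile(X, Y, g$other, "other", cfg$lesion_contrast))
      masks <- lapply(names(profiles), function(nm) {
        list(idx = which(abs(profiles[[nm]]) > 0.3 * cfg$lesion_contrast),
             slices = g[[nm]]$slices,
             applied = unname(applied[[nm]]))
      })
      names(masks) <- names(profiles)

      # anatomy and lesion field per slice
      anat <- array(0, c(s, hw, hw))
      lesion <- array(0, c(s, hw, hw))
      for (k in seq_len(s)) {
        drift <- g$drift * (k - (s + 1) / 2) / s
        scale_k <- 1 + 0.1 * sin(2 * pi * k / s + g$phase)
        fem <- ellipse_field(X, Y, g$cx + drift, g$femur$cy,
                             g$femur$ax * scale_k, g$femur$ay * scale_k)
        tib <- ellipse_field(X, Y, g$cx + drift, g$tibia$cy,
                             g$tibia$ax * scale_k, g$tibia$ay * scale_k)
        y_band <- 0.5 + g$band_tilt * (X - 0.5)
        band <- exp(-((Y - y_band)^2) / (2 * g$band_width^2))
        anat[k, , ] <- 0.15 + 0.6 * fem + 0.55 * tib + 0.3 * band
        les_k <- matrix(0, hw, hw)
        for (nm in names(profiles)) {
          sl <- masks[[nm]]$slices
          if (applied[[nm]] && k >= sl[1] && k <= sl[2]) {
            les_k <- les_k + profiles[[nm]]
          }
        }
        lesion[k, , ] <- les_k
      }

      exam_id <- sprintf("exam_%04d", i)
      series <- list()
      for (sq in cfg$sequence_types) {
        base <- if (sq %in% cfg$signal_sequences) anat + lesion else anat
        img <- sequence_contrast(base, sq)
        if (cfg$noise_sd > 0) {
          img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
        }
        px <- array(as.integer(round(pmin(pmax(img, 0), 4) * PHANTOM_INTENSITY_SCALE)),
                    dim = c(s, hw, hw))
        series[[sq]] <- mri_series(px, exam_id = exam_id, sequence_type = sq)
      }
      exams[[i]] <- list(exam_id = exam_id, series = series, labels = lab,
                         masks = masks, n_slices = s)
    }
    names(exams) <- vapply(exams, `[[`, "", "exam_id")

    # split and patient assignment: test patients each contribute one exam and
    # are disjoint from training patients; ~7.7% of training exams share a
    # patient pairwise (at most two exams per patient).
    # test split balances abnormal and normal exams (falling back to the
    # other class when one runs short), mirroring clinical test-set design
    n_test <- max(0L, min(n - 1L, as.integer(round(cfg$test_fraction * n))))
    test_idx <- integer(0)
    if (n_test > 0) {
      pos_idx <- which(abn == 1L)
      neg_idx <- which(abn == 0L)
      n_pos_t <- min(length(pos_idx), ceiling(n_test / 2))
      n_neg_t <- min(length(neg_idx), n_test - n_pos_t)
      n_pos_t <- min(length(pos_idx), n_test - n_neg_t)
      draw <- function(idx, k) {
        if (k <= 0) return(integer(0))
        idx[sample.int(length(idx), k)]
      }
      test_idx <- sort(c(draw(pos_idx, n_pos_t), draw(neg_idx, n_neg_t)))
    }
    split <- rep("train", n)
    split[test_idx] <- "test"
    patient <- character(n)
    train_idx <- which(split == "train")
    n_dup <- floor(0.077 * length(train_idx))
    pid <- 0L
    j <- 1L
    while (j <= length(train_idx)) {
      pid <- pid + 1L
      patient[train_idx[j]] <- sprintf("pat_%04d", pid)
      if (n_dup > 0 && j < length(train_idx)) {
        patient[train_idx[j + 1L]] <- sprintf("pat_%04d", pid)
        n_dup <- n_dup - 1L
        j <- j + 2L
      } else {
        j <- j + 1L
      }
    }
    for (i in test_idx) {
      pid <- pid + 1L
      patient[i] <- sprintf("pat_%04d", pid)
    }

    manifest <- data.frame(
      exam_id = names(exams),
      patient_id = patient,
      split = split,
      stringsAsFactors = FALSE)
    for (sq in cfg$sequence_types) manifest[[sq]] <- ""
    manifest$abnormality <- abn
    manifest$meniscus <- men
    manifest$bone_edema <- ed
    manifest <- label_manifest(manifest)

    structure(list(exams = exams, manifest = manifest, config = cfg),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  n <- length(x$exams)
  cat(sprintf("Phantom cohort: %d exams (%d train / %d test), %d sequence type(s)\n",
              n, sum(x$manifest$split == "train"), sum(x$manifest$split == "test"),
              length(x$config$sequence_types)))
  pos <- colSums(x$manifest[, TASKS, drop = FALSE])
  cat(sprintf("  positives: abnormality %d, meniscus %d, bone_edema %d\n",
              pos["abnormality"], pos["meniscus"], pos["bone_edema"]))
  invisible(x)
}

# Expand an exam's compact candidate mask for one lesion type into a logical
# s x h x w volume (TRUE on candidate lesion voxels).
lesion_mask_volume <- function(exam, type = c("meniscus", "edema", "other")) {
  type <- match.arg(type)
  m <- exam$masks[[type]]
  s <- exam$n_slices
  hw <- dim(exam$series[[1]]$pixels)[2]
  vol <- array(FALSE, c(s, hw, hw))
  plane <- matrix(FALSE, hw, hw)
  plane[m$idx] <- TRUE
  for (k in m$slices[1]:m$slices[2]) vol[k, , ] <- plane
  vol
}

#' Mean pixel intensity over each exam's candidate lesion region
#'
#' For every exam, averages the pixel values of one sequence over the exam's
#' candidate region for the given lesion type (the region is defined for
#' negatives too, where no lesion was planted). A simple threshold on this
#' statistic is an oracle classifier for the planted signal, independent of
#' any CNN.
#'
#' @param cohort A `"phantom_cohort"`.
#' @param sequence_type Which sequence to measure.
#' @param task `"meniscus"`, `"edema"` or `"other"`.
#' @return A data frame with `exam_id`, `label` (whether the lesion was
#'   planted) and `mean_intensity` (stored pixel units).
#' @export
lesion_region_means <- function(cohort, sequence_type = "sagittal_t1",
                                task = c("meniscus", "edema", "other")) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  task <- match.arg(task)
  sequence_type <- match.arg(sequence_type, cohort$config$sequence_types)
  rows <- lapply(cohort$exams, function(ex) {
    m <- ex$masks[[task]]
    px <- ex$series[[sequence_type]]$pixels
    hw <- dim(px)[2]
    plane <- matrix(FALSE, hw, hw)
    plane[m$idx] <- TRUE
    vals <- unlist(lapply(m$slices[1]:m$slices[2], function(k) {
      sl <- px[k, , ]
      sl[plane]
    }))
    data.frame(exam_id = ex$exam_id, label = as.integer(m$applied),
               mean_intensity = mean(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
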