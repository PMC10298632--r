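# Fixtures built in code: small phantom cohorts, a cohort-shaped manifest
# mirroring a published clinical table, and random fused volumes.

# Small, fast cohort: low resolution, few slices, one or two sequences.
tiny_cohort <- function(n = 8, seqs = "sagittal_t1", seed = 7,
                        slice_range = c(14, 15), image_size = 64,
                        test_fraction = 0.25, ...) {
  generate_cohort(phantom_config(
    n_exams = n, sequence_types = seqs, slice_range = slice_range,
    image_size = image_size, test_fraction = test_fraction, seed = seed, ...))
}

# Manifest with the label counts of the reference clinical cohort:
# 466 train / 98 test exams; train: 335 abnormal, 127 meniscus, 132 edema,
# 38 co-occurring; test: 66 abnormal, 50 meniscus, 30 edema, 14 co-occurring.
paper_shaped_manifest <- function() {
  build_split <- function(n, n_men, n_ed, n_co, n_abn, split, offset) {
    men <- ed <- integer(n)
    men[seq_len(n_men)] <- 1L
    ed[seq_len(n_co)] <- 1L                                  # co-occurring
    ed[(n_men + 1):(n_men + (n_ed - n_co))] <- 1L            # edema only
    abn <- as.integer(men | ed)
    n_other <- n_abn - sum(abn)
    stopifnot(n_other >= 0)
    neither <- which(abn == 0L)
    abn[neither[seq_len(n_other)]] <- 1L
    data.frame(
      exam_id = sprintf("ex_%04d", offset + seq_len(n)),
      patient_id = sprintf("pt_%04d", offset + seq_len(n)),
      split = split, abnormality = abn, meniscus = men, bone_edema = ed,
      stringsAsFactors = FALSE)
  }
  label_manifest(rbind(
    build_split(466, 127, 132, 38, 335, "train", 0),
    build_split(98, 50, 30, 14, 66, "test", 466)))
}

# Random array with the fused-volume contract (for model shape tests).
random_fused_volume <- function(s, seed = 1) {
  with_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    force(code)
  }
  with_seed(seed, structure(array(stats::rnorm(s * 3 * 224 * 224),
                                  c(s, 3, 224, 224)),
                            class = "fused_volume"))
}

# Fused volume derived from a real phantom series (windowed full range).
phantom_fused_volume <- function(cohort, exam = 1, seq = "sagittal_t1",
                                 stats = NULL) {
  ser <- resize_series(cohort$exams[[exam]]$series[[seq]], 224)
  if (is.null(stats)) stats <- fit_norm_stats(list(ser))
  suppressWarnings(fuse_volume(ser, stats))
}
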