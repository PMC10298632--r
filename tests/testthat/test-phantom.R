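# Synthetic phantom generator: guards, determinism, label statistics,
# lesion/label coupling and oracle separability.

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(n_exams = 0), "positive integer")
  expect_error(phantom_config(n_exams = 10, prevalence_meniscus = 1.2),
               "\\[0, 1\\]")
  expect_error(phantom_config(n_exams = 10, prevalence_meniscus = 0.2,
                              prevalence_edema = 0.2, co_occurrence_rate = 0.3),
               "co_occurrence_rate")
  expect_error(phantom_config(n_exams = 10, prevalence_abnormal = 0.1,
                              prevalence_meniscus = 0.4,
                              prevalence_edema = 0.3,
                              co_occurrence_rate = 0.1),
               "prevalence_abnormal")
  expect_error(phantom_config(n_exams = 10, slice_range = c(10, 20)),
               "\\[14, 56\\]")
  expect_error(phantom_config(n_exams = 10, slice_range = c(14, 60)),
               "\\[14, 56\\]")
  expect_error(phantom_config(n_exams = 10, signal_sequences = "axial_t2",
                              sequence_types = "sagittal_t1"),
               "subset")
})

test_that("positive counts fall in the binomial high-probability interval", {
  cfg <- phantom_config(n_exams = 100, prevalence_meniscus = 0.5,
                        prevalence_edema = 0.2, co_occurrence_rate = 0.1,
                        prevalence_abnormal = 0.65,
                        sequence_types = "sagittal_t1",
                        slice_range = c(14, 14), image_size = 32, seed = 7)
  co <- generate_cohort(cfg)
  n_men <- sum(co$manifest$meniscus)
  # central 99.9% binomial interval computed from the CDF
  lo <- qbinom(5e-4, 100, 0.5)
  hi <- qbinom(1 - 5e-4, 100, 0.5)
  expect_gte(n_men, lo)
  expect_lte(n_men, hi)
  # abnormality holds its consistency rule by construction
  expect_true(all(co$manifest$abnormality >=
                    pmax(co$manifest$meniscus, co$manifest$bone_edema)))
})

test_that("the seed fully determines the cohort", {
  cfg <- phantom_config(n_exams = 4, sequence_types = c("sagittal_t1", "axial_t2"),
                        slice_range = c(14, 16), image_size = 48, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  for (i in seq_along(a$exams)) {
    for (sq in names(a$exams[[i]]$series)) {
      expect_identical(a$exams[[i]]$series[[sq]]$pixels,
                       b$exams[[i]]$series[[sq]]$pixels)
    }
  }
  c <- generate_cohort(phantom_config(n_exams = 4,
                                      sequence_types = c("sagittal_t1", "axial_t2"),
                                      slice_range = c(14, 16), image_size = 48,
                                      seed = 8))
  expect_false(identical(a$exams[[1]]$series$sagittal_t1$pixels,
                         c$exams[[1]]$series$sagittal_t1$pixels))
})

test_that("planted lesions span at least three consecutive slices", {
  co <- tiny_cohort(n = 20, seed = 3, slice_range = c(14, 20))
  for (ex in co$exams) {
    for (type in c("meniscus", "edema", "other")) {
      sl <- ex$masks[[type]]$slices
      expect_gte(sl[2] - sl[1] + 1, 3)
      expect_gte(sl[1], 1)
      expect_lte(sl[2], ex$n_slices)
    }
  }
})

test_that("labels couple to the planted signal and vanish off-lesion", {
  cfg <- phantom_config(n_exams = 40, prevalence_meniscus = 0.5,
                        prevalence_edema = 0.2, co_occurrence_rate = 0.1,
                        prevalence_abnormal = 0.6,
                        sequence_types = "sagittal_t1",
                        slice_range = c(14, 14), image_size = 64, seed = 5)
  co <- generate_cohort(cfg)
  rm_scale <- 1000  # stored pixel units per anatomy unit
  reg <- lesion_region_means(co, "sagittal_t1", task = "meniscus")
  pos <- reg$mean_intensity[reg$label == 1]
  neg <- reg$mean_intensity[reg$label == 0]
  # hypointense crescent: positives clearly darker inside the candidate region
  expect_lt(mean(pos), mean(neg) - cfg$noise_sd * rm_scale)

  # outside every candidate lesion region the class means agree to within the
  # noise scale: the label carries no signal once lesion voxels are masked
  off_means <- vapply(co$exams, function(ex) {
    px <- ex$series$sagittal_t1$pixels
    excl <- matrix(FALSE, dim(px)[2], dim(px)[3])
    for (type in c("meniscus", "edema", "other")) {
      excl[ex$masks[[type]]$idx] <- TRUE
    }
    keep <- !excl
    mean(vapply(seq_len(dim(px)[1]), function(k) mean(px[k, , ][keep]), 0))
  }, 0)
  men_lab <- co$manifest$meniscus[match(names(co$exams), co$manifest$exam_id)]
  gap <- abs(mean(off_means[men_lab == 1]) - mean(off_means[men_lab == 0]))
  expect_lt(gap, cfg$noise_sd * rm_scale)
})

test_that("a threshold on lesion-region mean separates classes without a CNN", {
  cfg <- phantom_config(n_exams = 40, prevalence_meniscus = 0.5,
                        prevalence_edema = 0.2, co_occurrence_rate = 0.1,
                        prevalence_abnormal = 0.6,
                        sequence_types = "sagittal_t1",
                        slice_range = c(14, 14), image_size = 64, seed = 9)
  expect_gte(cfg$lesion_contrast, 3 * cfg$noise_sd)  # separable regime
  reg <- lesion_region_means(generate_cohort(cfg), "sagittal_t1", "meniscus")
  # best single threshold (oracle classifier)
  cand <- sort(reg$mean_intensity)
  thr <- (head(cand, -1) + tail(cand, -1)) / 2
  acc <- vapply(thr, function(t) {
    mean((reg$mean_intensity < t) == (reg$label == 1))
  }, 0)
  expect_gte(max(acc), 0.95)
})
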