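# DICOM writer/reader round trips, ordering, guards, resizing, and the
# manifest schema.

test_that("write/read round trip is pixel-lossless with correct file count", {
  co <- tiny_cohort(n = 1, seqs = c("sagittal_t1", "axial_t2"),
                    slice_range = c(14, 14), image_size = 32, seed = 2,
                    test_fraction = 0)
  ex <- co$exams[[1]]
  dir <- withr::local_tempdir()
  paths <- write_dicom_exam(ex, dir)
  expect_length(paths, 2 * 14)
  for (sq in c("sagittal_t1", "axial_t2")) {
    ser <- read_dicom_series(file.path(dir, ex$exam_id, sq))
    expect_equal(max(abs(ser$pixels - ex$series[[sq]]$pixels)), 0)
    expect_identical(ser$sequence_type, sq)
  }
})

test_that("slice order follows InstanceNumber, not on-disk file names", {
  co <- tiny_cohort(n = 1, slice_range = c(14, 14), image_size = 32, seed = 4,
                    test_fraction = 0)
  ex <- co$exams[[1]]
  dir <- withr::local_tempdir()
  write_dicom_exam(ex, dir)
  sdir <- file.path(dir, ex$exam_id, "sagittal_t1")
  # rename so lexicographic order disagrees with acquisition order
  files <- list.files(sdir, full.names = TRUE)
  new_names <- file.path(sdir, sprintf("%s.dcm", rev(letters[seq_along(files)])))
  stopifnot(all(file.rename(files, new_names)))
  ser <- read_dicom_series(sdir)
  expect_equal(max(abs(ser$pixels - ex$series$sagittal_t1$pixels)), 0)
})

test_that("mixed series directories and empty directories are rejected", {
  co <- tiny_cohort(n = 1, seqs = c("sagittal_t1", "axial_t2"),
                    slice_range = c(14, 14), image_size = 32, seed = 2,
                    test_fraction = 0)
  dir <- withr::local_tempdir()
  write_dicom_exam(co$exams[[1]], dir)
  eid <- co$exams[[1]]$exam_id
  t1 <- file.path(dir, eid, "sagittal_t1")
  file.copy(file.path(dir, eid, "axial_t2", "slice_001.dcm"),
            file.path(t1, "intruder.dcm"))
  expect_error(read_dicom_series(t1), "SeriesInstanceUIDs")
  empty <- withr::local_tempdir()
  expect_error(read_dicom_series(empty), "no DICOM files")
})

test_that("pydicom independently reads files the native writer produced", {
  co <- tiny_cohort(n = 1, slice_range = c(14, 14), image_size = 32, seed = 6,
                    test_fraction = 0)
  ex <- co$exams[[1]]
  dir <- withr::local_tempdir()
  write_dicom_exam(ex, dir)
  f <- file.path(dir, ex$exam_id, "sagittal_t1", "slice_003.dcm")
  script <- sprintf(
    "import pydicom; d = pydicom.dcmread(r'%s'); print(int(d.InstanceNumber), int(d.pixel_array.sum()), d.pixel_array.shape[0], d.pixel_array.shape[1])",
    f)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  vals <- as.numeric(strsplit(trimws(out[length(out)]), " ")[[1]])
  expect_equal(vals[1], 3)
  expect_equal(vals[2], sum(ex$series$sagittal_t1$pixels[3, , ]))
  expect_equal(vals[3:4], c(32, 32))
})

test_that("resize honors the shape contract and preserves constants", {
  arr <- array(runif(20 * 256 * 256, 0, 1000), c(20, 256, 256))
  ser <- mri_series(arr, "e1", "sagittal_t1")
  out <- resize_series(ser, 224)
  expect_equal(dim(out$pixels), c(20, 224, 224))

  const <- mri_series(array(7, c(2, 32, 32)), "e2", "sagittal_t1")
  rc <- resize_series(const, 224)
  expect_equal(range(rc$pixels), c(7, 7))

  id <- mri_series(array(runif(2 * 224 * 224), c(2, 224, 224)), "e3")
  expect_identical(resize_series(id, 224)$pixels, id$pixels)
  expect_error(resize_series(ser, 0), "positive")
})

test_that("resize round trip on smooth phantom slices has bounded error", {
  co <- tiny_cohort(n = 1, slice_range = c(14, 14), image_size = 64, seed = 8,
                    test_fraction = 0, noise_sd = 0)
  ser <- co$exams[[1]]$series$sagittal_t1
  back <- resize_series(resize_series(ser, 224), 64)
  rng <- diff(range(ser$pixels))
  expect_lt(max(abs(back$pixels - ser$pixels)), 0.02 * rng)
})

test_that("manifest round trip is lossless and invariants are enforced", {
  co <- tiny_cohort(n = 6, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  save_manifest(co$manifest, path)
  loaded <- load_manifest(path)
  expect_equal(as.data.frame(loaded), as.data.frame(co$manifest))

  base <- data.frame(exam_id = c("a", "b"), patient_id = c("p1", "p2"),
                     split = c("train", "test"),
                     abnormality = c(0L, 1L), meniscus = c(1L, 0L),
                     bone_edema = c(0L, 0L), stringsAsFactors = FALSE)
  expect_error(label_manifest(base), "abnormality = 0")
  ok <- base; ok$abnormality <- c(1L, 1L)
  expect_s3_class(label_manifest(ok), "label_manifest")

  bad_col <- ok; bad_col$mystery_seq <- "x"
  expect_error(label_manifest(bad_col), "unknown sequence_type")
  bad_lab <- ok; bad_lab$meniscus <- c(2, 0)
  expect_error(label_manifest(bad_lab), "binary")
  dup <- rbind(ok, ok[1, ], ok[1, ])
  dup$exam_id <- c("a", "b", "c", "d")
  dup$split <- "train"
  expect_error(label_manifest(dup), "two exams per patient")
  leak <- ok; leak$patient_id <- c("p1", "p1")
  expect_error(label_manifest(leak), "both train and test")
})

test_that("summary percentages reproduce count/total with half-up rounding", {
  m <- paper_shaped_manifest()
  s <- summarize_manifest(m)
  pick <- function(split, task) s$percent[s$split == split & s$task == task]
  expect_equal(pick("overall", "abnormality"), 71.1)  # 401 of 564
  expect_equal(pick("train", "meniscus"), 27.3)       # 127 of 466
  expect_equal(pick("train", "abnormality"), 71.9)    # 335 of 466
  expect_equal(pick("train", "bone_edema"), 28.3)     # 132 of 466
  expect_equal(pick("test", "abnormality"), 67.3)     # 66 of 98
  expect_equal(pick("test", "meniscus"), 51.0)        # 50 of 98
  expect_equal(pick("test", "bone_edema"), 30.6)      # 30 of 98
  expect_equal(pick("overall", "meniscus"), 31.4)     # 177 of 564, computed

  zero <- label_manifest(data.frame(
    exam_id = sprintf("e%d", 1:10), patient_id = sprintf("p%d", 1:10),
    split = "train", abnormality = 0L, meniscus = 0L, bone_edema = 0L,
    stringsAsFactors = FALSE))
  sz <- summarize_manifest(zero)
  expect_true(all(sz$percent == 0))
  expect_error(summarize_manifest(zero[0, ]), "empty")
})
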