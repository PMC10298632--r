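# Windowing, normalization, LBP, Haar DWT and channel fusion.

series_from <- function(values, dim3) {
  mri_series(array(values, dim3), "e1", "sagittal_t1")
}

test_that("windowing zeroes out-of-range pixels and is idempotent", {
  ser <- series_from(c(5, 50, 500), c(1, 1, 3))
  w <- intensity_window(10, 100)
  expect_equal(as.numeric(apply_window(ser, w)$pixels), c(0, 50, 0))

  full <- intensity_window()
  expect_identical(apply_window(ser, full)$pixels, ser$pixels)

  set.seed(1)
  rnd <- series_from(runif(4 * 16 * 16, 0, 200), c(4, 16, 16))
  win <- intensity_window(30, 150)
  out <- apply_window(rnd, win)
  # brute-force scan: zeroed fraction equals out-of-range fraction
  outside <- sum(rnd$pixels < 30 | rnd$pixels > 150)
  expect_equal(sum(out$pixels == 0), outside)
  expect_identical(apply_window(out, win)$pixels, out$pixels)
  expect_error(intensity_window(5, 5), "below")
})

test_that("normalization stats match hand arithmetic and a two-pass oracle", {
  ser <- series_from(c(0, 0, 10, 10), c(1, 2, 2))
  st <- fit_norm_stats(list(ser))
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 5)

  expect_error(fit_norm_stats(list(series_from(rep(7, 4), c(1, 2, 2)))),
               "degenerate")

  co <- tiny_cohort(n = 6, seed = 12, image_size = 64)
  series <- lapply(co$exams, function(ex) ex$series$sagittal_t1)
  st2 <- fit_norm_stats(series)
  allpx <- unlist(lapply(series, function(s) as.numeric(s$pixels)))
  m_oracle <- mean(allpx)                       # two-pass oracle
  sd_oracle <- sqrt(mean((allpx - m_oracle)^2))
  expect_equal(st2$mean, m_oracle, tolerance = 1e-6)
  expect_equal(st2$sd, sd_oracle, tolerance = 1e-6)
})

test_that("z-normalization standardizes the training set to mean 0, sd 1", {
  st <- structure(list(mean = 100, sd = 10,
                       window = intensity_window(), n_pixels = 1,
                       n_series = 1), class = "norm_stats")
  ser <- series_from(c(120, 100), c(1, 1, 2))
  z <- normalize_series(ser, st)$pixels
  expect_equal(as.numeric(z), c(2, 0))

  co <- tiny_cohort(n = 5, seed = 13, image_size = 64)
  series <- lapply(co$exams, function(ex) ex$series$sagittal_t1)
  st2 <- fit_norm_stats(series)
  zs <- unlist(lapply(series, function(s) normalize_series(s, st2)$pixels))
  expect_lt(abs(mean(zs)), 1e-6)
  expect_lt(abs(sqrt(mean((zs - mean(zs))^2)) - 1), 1e-6)
})

test_that("LBP follows the clockwise-from-top-left >= convention", {
  expect_true(all(lbp_map(matrix(3.7, 8, 8)) == 255L))

  # center 5; neighbors clockwise from top-left: 6,7,8,9,1,2,3,4
  # comparisons >= 5: 1,1,1,1,0,0,0,0 -> MSB-first code 0b11110000 = 240
  patch <- matrix(c(6, 4, 3,
                    7, 5, 2,
                    8, 9, 1), 3, 3)
  expect_equal(lbp_map(patch)[2, 2], 240L)
  expect_error(lbp_map(array(1, c(2, 2, 2))), "2-D")
})

test_that("LBP is invariant under strictly monotone maps on tie-free images", {
  set.seed(42)
  vals <- sample(seq_len(64 * 64))  # all distinct: no neighbor ties
  sl <- matrix(vals, 64, 64)
  base <- lbp_map(sl)
  for (f in list(function(x) x^3, function(x) exp(x / 5000),
                 function(x) 5 * x - 100)) {
    expect_identical(lbp_map(f(sl)), base)  # pixelwise oracle comparison
  }
})

test_that("Haar DWT matches its closed-form identities and an explicit oracle", {
  const <- matrix(3, 16, 16)
  sb <- dwt_haar2(const)
  expect_equal(range(sb$LL), c(6, 6))     # LL of constant c is 2c
  expect_true(all(abs(c(sb$LH, sb$HL, sb$HH)) < 1e-12))
  expect_equal(range(dwt_map(const)), c(6, 6))

  set.seed(3)
  x <- matrix(rnorm(32 * 32), 32, 32)
  sb <- dwt_haar2(x)
  # Parseval: orthonormal filter bank preserves energy
  e_in <- sum(x^2)
  e_out <- sum(sb$LL^2) + sum(sb$LH^2) + sum(sb$HL^2) + sum(sb$HH^2)
  expect_equal(e_out, e_in, tolerance = 1e-4)

  # independent 2x2 filter-bank oracle, written as explicit loops
  oracle <- function(m) {
    hh <- nrow(m) / 2; ww <- ncol(m) / 2
    out <- list(LL = matrix(0, hh, ww), LH = matrix(0, hh, ww),
                HL = matrix(0, hh, ww), HH = matrix(0, hh, ww))
    for (i in seq_len(hh)) {
      for (j in seq_len(ww)) {
        blk <- m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
        a <- blk[1, 1]; b <- blk[1, 2]; cc <- blk[2, 1]; d <- blk[2, 2]
        out$LL[i, j] <- (a + b + cc + d) / 2
        out$LH[i, j] <- (a + b - cc - d) / 2
        out$HL[i, j] <- (a - b + cc - d) / 2
        out$HH[i, j] <- (a - b - cc + d) / 2
      }
    }
    out
  }
  step <- matrix(0, 16, 16); step[, 9:16] <- 1; step[5:8, ] <- step[5:8, ] + 2
  ours <- dwt_haar2(step)
  ref <- oracle(step)
  for (nm in names(ref)) expect_equal(ours[[nm]], ref[[nm]], tolerance = 1e-6)

  expect_error(dwt_haar2(matrix(0, 15, 16)), "even")
})

test_that("the exported DWT map is a low-pass with bounded variance gain", {
  co <- tiny_cohort(n = 2, seed = 21, image_size = 64)
  for (ex in co$exams) {
    sl <- resize_series(ex$series$sagittal_t1, 224)$pixels[1, , ]
    m <- dwt_map(sl)
    v_in <- mean((sl - mean(sl))^2)
    v_out <- mean((m - mean(m))^2)
    expect_lte(v_out, 4 * v_in + 1e-8)
  }
})

test_that("fusion stacks normalized original, LBP and DWT channels", {
  co <- tiny_cohort(n = 2, seed = 17, image_size = 64,
                    slice_range = c(14, 14))
  ser <- resize_series(co$exams[[1]]$series$sagittal_t1, 224)
  st <- fit_norm_stats(list(ser))
  fv <- fuse_volume(ser, st)
  expect_equal(dim(fv), c(14, 3, 224, 224))
  expect_true(all(is.finite(fv)))

  # channel 1 is exactly the z-normalized original
  z <- normalize_series(ser, st)$pixels
  expect_equal(fv[, 1, , ], z)

  # channels 2-3 standardized per slice
  for (k in c(1, 7)) {
    for (ch in 2:3) {
      m <- fv[k, ch, , ]
      expect_lt(abs(mean(m)), 1e-5)
      expect_lt(abs(sqrt(mean((m - mean(m))^2)) - 1), 1e-5)
    }
  }

  # determinism: identical input and stats give bit-identical volumes
  expect_identical(fv, fuse_volume(ser, st))

  # constant slice: texture channels fall back to zeros with a warning
  cs <- mri_series(array(5, c(1, 224, 224)), "e", "sagittal_t1")
  cst <- structure(list(mean = 1, sd = 2, window = intensity_window(),
                        n_pixels = 1, n_series = 1), class = "norm_stats")
  expect_warning(cfv <- fuse_volume(cs, cst), "constant")
  expect_true(all(cfv[1, 2, , ] == 0))

  wrong <- mri_series(array(1, c(2, 64, 64)), "e", "sagittal_t1")
  expect_error(fuse_volume(wrong, cst), "224")
})

test_that("fused volumes round-trip through the binary container", {
  fv <- random_fused_volume(2, seed = 5)
  attr(fv, "exam_id") <- "e9"; attr(fv, "sequence_type") <- "axial_t2"
  path <- withr::local_tempfile()
  save_fused_volume(fv, path)
  back <- load_fused_volume(path)
  expect_equal(unclass(back)[seq_along(back)], unclass(fv)[seq_along(fv)])
  expect_identical(dim(back), dim(fv))
  expect_identical(attr(back, "sequence_type"), "axial_t2")
})
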