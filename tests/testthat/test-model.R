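# Shape contracts, pooling and attention semantics, forward determinism and
# multi-stream fusion equivalences.

test_that("the shape contract chain holds across slice counts", {
  p <- knet_params("sagittal_t1", seed = 1)
  for (s in c(14L, 30L, 56L)) {
    fv <- random_fused_volume(s, seed = s)
    feats <- extract_slice_features(fv, p)
    expect_equal(dim(feats), c(s, 256, 7, 7))
    pooled <- pool_slices(feats)
    expect_equal(dim(pooled), c(s, 256))
    emb <- aggregate_slices(pooled, p$streams[[1]]$attn)
    expect_length(as.numeric(emb), 256)
    w <- attr(emb, "weights")
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-6)
    out <- forward_knet(fv, p)
    expect_gte(out$probability, 0)
    expect_lte(out$probability, 1)
  }
  bad <- structure(array(0, c(2, 2, 224, 224)), class = "fused_volume")
  expect_error(extract_slice_features(bad, p), "3 x 224 x 224")
})

test_that("slice features are computed independently per slice", {
  p <- knet_params("sagittal_t1", seed = 2)
  fv <- random_fused_volume(4, seed = 3)
  fv2 <- fv
  fv2[2, , , ] <- fv2[1, , , ]  # duplicate slice 1 into slot 2
  f2 <- extract_slice_features(fv2, p)
  expect_equal(f2[1, , , ], f2[2, , , ])

  perm <- c(3, 1, 4, 2)
  fvp <- structure(unclass(fv)[perm, , , , drop = FALSE],
                   class = "fused_volume")
  f <- extract_slice_features(fv, p)
  fp <- extract_slice_features(fvp, p)
  expect_equal(fp, f[perm, , , , drop = FALSE])
})

test_that("spatial pooling equals the brute-force 49-element mean", {
  ones <- array(1, c(2, 256, 7, 7))
  expect_true(all(pool_slices(ones) == 1))

  set.seed(9)
  feats <- array(rnorm(3 * 256 * 7 * 7), c(3, 256, 7, 7))
  pooled <- pool_slices(feats)
  for (k in 1:3) {
    for (ch in c(1, 100, 256)) {
      acc <- 0
      for (i in 1:7) for (j in 1:7) acc <- acc + feats[k, ch, i, j]
      expect_equal(pooled[k, ch], acc / 49, tolerance = 1e-6)
    }
  }
  expect_error(pool_slices(array(0, c(2, 128, 7, 7))), "256")
})

test_that("attention aggregation is convex and permutation-invariant", {
  attn <- list(u = rnorm(256, 0, 0.1), c = 0.3)

  one <- matrix(rnorm(256), 1, 256)
  emb <- aggregate_slices(one, attn)
  expect_equal(as.numeric(emb), as.numeric(one))   # softmax over one element

  same <- matrix(rep(rnorm(256), each = 5), 5, 256)
  emb2 <- aggregate_slices(same, attn)
  expect_equal(as.numeric(emb2), as.numeric(same[1, ]), tolerance = 1e-12)

  set.seed(5)
  for (s in 2:6) {
    pooled <- matrix(rnorm(s * 256), s, 256)
    perm <- sample(s)
    a <- aggregate_slices(pooled, attn)
    b <- aggregate_slices(pooled[perm, , drop = FALSE], attn)
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
  }
})

test_that("the head follows the logistic threshold rule with ties to 1", {
  p <- knet_params("sagittal_t1", seed = 4)
  fv <- random_fused_volume(3, seed = 6)

  p0 <- p
  p0$head$v[] <- 0; p0$head$b <- 0
  out <- forward_knet(fv, p0)
  expect_identical(out$probability, 0.5)  # logistic(0) exactly
  expect_identical(out$label, 1L)         # tie at 0.5 goes to 1

  p49 <- p0; p49$head$b <- qlogis(0.49)
  expect_identical(forward_knet(fv, p49)$label, 0L)
  p51 <- p0; p51$head$b <- qlogis(0.51)
  expect_identical(forward_knet(fv, p51)$label, 1L)

  # eval-mode determinism
  a <- forward_knet(fv, p)
  b <- forward_knet(fv, p)
  expect_identical(a$probability, b$probability)
})

test_that("multi-stream fusion reduces to single-stream when tied", {
  fv <- random_fused_volume(5, seed = 8)

  p1 <- knet_params("sagittal_t1", seed = 5)
  single <- forward_knet(fv, p1)
  ms1 <- forward_msknet(list(sagittal_t1 = fv), p1)
  expect_equal(ms1$probability, single$probability, tolerance = 1e-12)

  # three streams, branch weights tied, identical volumes -> same output
  p3 <- knet_params(c("sagittal_t1", "axial_t2", "coronal_hybrid"), seed = 5)
  p3$head <- p1$head
  for (sq in p3$stream_sequences) {
    p3$streams[[sq]]$layers <- p1$streams[[1]]$layers
    p3$streams[[sq]]$attn <- p1$streams[[1]]$attn
  }
  ms3 <- forward_msknet(list(sagittal_t1 = fv, axial_t2 = fv,
                             coronal_hybrid = fv), p3)
  expect_equal(ms3$probability, single$probability, tolerance = 1e-10)

  # stream-order permutation with weights permuted accordingly
  pa <- knet_params(c("sagittal_t1", "axial_t2"), seed = 9)
  fv2 <- random_fused_volume(4, seed = 10)
  pb <- pa
  pb$stream_sequences <- rev(pa$stream_sequences)
  pb$streams <- pa$streams[rev(names(pa$streams))]
  va <- forward_msknet(list(sagittal_t1 = fv, axial_t2 = fv2), pa)
  vb <- forward_msknet(list(sagittal_t1 = fv, axial_t2 = fv2), pb)
  expect_equal(va$probability, vb$probability, tolerance = 1e-12)
})

test_that("stream configuration is validated", {
  expect_error(knet_params(c("sagittal_t1", "sagittal_t1")), "duplicate")
  expect_error(knet_params(SEQUENCE_TYPES), "1 and 3")
  expect_error(knet_params("sagittal_t1", backbone = "alexnet_pretrained"),
               "not bundled")
  p2 <- knet_params(c("sagittal_t1", "axial_t2"), seed = 2)
  fv <- random_fused_volume(3, seed = 2)
  expect_error(forward_msknet(list(sagittal_t1 = fv), p2), "missing stream")
  expect_error(forward_msknet(list(sagittal_t1 = fv, axial_t2 = fv,
                                   sagittal_t2 = fv), p2),
               "not configured")
})

test_that("the frozen AlexNet-shaped backbone honors the same contract", {
  p <- knet_params("sagittal_t1", backbone = "alexnet_random", seed = 3)
  fv <- random_fused_volume(2, seed = 4)
  feats <- extract_slice_features(fv, p)
  expect_equal(dim(feats), c(2, 256, 7, 7))
  out <- forward_knet(fv, p)
  expect_gte(out$probability, 0)
  expect_lte(out$probability, 1)
})
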