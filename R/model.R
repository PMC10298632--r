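# KNet and MS-KNet: per-slice convolutional feature extraction to 256 x 7 x 7,
# spatial average pooling to a 256-vector per slice, softmax-attention
# weighted aggregation over slices to one 256-dim exam embedding, optional
# averaging fusion over up to three sequence streams, and a logistic
# classification head with the fixed 0.5 decision threshold.

KNET_FEATURE_CHANNELS <- 256L
KNET_SPATIAL_OUT <- 7L

# Layer specs per backbone. tiny_cnn downsamples 224 -> 56 with a fixed 4x4
# box average, then three strided convolutions to 256 x 7 x 7; all of it is
# trainable. alexnet_random is the classic AlexNet feature stack with random
# weights, frozen during training (only attention + head train), with an
# adaptive pooling stage fixing the 6x6 grid to the 7x7 output contract.
tiny_cnn_specs <- function() {
  list(conv_spec(3L, 16L, 5L, 2L, 2L),    # 56 -> 28
       conv_spec(16L, 32L, 3L, 2L, 1L),   # 28 -> 14
       conv_spec(32L, 256L, 3L, 2L, 1L))  # 14 -> 7
}

alexnet_specs <- function() {
  list(conv_spec(3L, 64L, 11L, 4L, 2L),   # 224 -> 55
       conv_spec(64L, 192L, 5L, 1L, 2L),  # 27 -> 27 (after pool)
       conv_spec(192L, 384L, 3L, 1L, 1L),
       conv_spec(384L, 256L, 3L, 1L, 1L),
       conv_spec(256L, 256L, 3L, 1L, 1L))
}

init_backbone <- function(backbone) {
  if (backbone == "tiny_cnn") {
    lapply(tiny_cnn_specs(), conv_init)
  } else {
    lapply(alexnet_specs(), conv_init)
  }
}

init_attention <- function(dim = KNET_FEATURE_CHANNELS) {
  list(u = stats::rnorm(dim, 0, 1 / sqrt(dim)), c = 0)
}

#' KNet / MS-KNet model parameters
#'
#' Creates a randomly initialized model: one convolutional backbone and one
#' attention module per stream, plus a single shared classification head on
#' the (averaged) 256-dim exam embedding. The `tiny_cnn` backbone (a
#' three-layer strided conv stack on a 4x-downsampled input, emitting the
#' same 256 x 7 x 7 feature contract) is fully trainable and sized for
#' desk-scale experiments; `alexnet_random` is the classic five-conv AlexNet
#' feature stack with random weights, kept frozen during training.
#' Pretrained AlexNet weights are not bundled, so `alexnet_pretrained` is
#' rejected with guidance.
#'
#' @param stream_sequences Character vector (length 1-3) of sequence types,
#'   one per stream.
#' @param backbone `"tiny_cnn"` (default), `"alexnet_random"`, or
#'   `"alexnet_pretrained"` (rejected).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"knet_params"`.
#' @export
knet_params <- function(stream_sequences = "sagittal_t1",
                        backbone = c("tiny_cnn", "alexnet_random",
                                     "alexnet_pretrained"),
                        seed = 1L) {
  backbone <- match.arg(backbone)
  if (backbone == "alexnet_pretrained") {
    stop("pretrained AlexNet weights are not bundled with this package; ",
         "use backbone = 'tiny_cnn' (trainable) or 'alexnet_random'",
         call. = FALSE)
  }
  stream_sequences <- match.arg(stream_sequences, SEQUENCE_TYPES,
                                several.ok = TRUE)
  n_streams <- length(stream_sequences)
  if (n_streams < 1L || n_streams > 3L) {
    stop("between 1 and 3 stream sequences are supported", call. = FALSE)
  }
  if (anyDuplicated(stream_sequences)) {
    stop("duplicate sequence types across streams", call. = FALSE)
  }
  with_seed(seed, {
    streams <- lapply(stream_sequences, function(sq) {
      list(sequence_type = sq, layers = init_backbone(backbone),
           attn = init_attention())
    })
    names(streams) <- stream_sequences
    head <- list(v = stats::rnorm(KNET_FEATURE_CHANNELS, 0,
                                  1 / sqrt(KNET_FEATURE_CHANNELS)),
                 b = 0)
    structure(list(backbone = backbone,
                   stream_sequences = stream_sequences,
                   n_streams = n_streams,
                   embed_dim = KNET_FEATURE_CHANNELS,
                   seed = as.integer(seed),
                   streams = streams, head = head),
              class = "knet_params")
  })
}

#' @export
print.knet_params <- function(x, ...) {
  cat(sprintf("KNet parameters: %s backbone, %d stream(s) [%s], embed dim %d\n",
              x$backbone, x$n_streams,
              paste(x$stream_sequences, collapse = ", "), x$embed_dim))
  invisible(x)
}

check_fused_volume <- function(volume) {
  d <- dim(volume)
  if (length(d) != 4L || d[2] != 3L || d[3] != 224L || d[4] != 224L) {
    stop("expected a fused volume of shape s x 3 x 224 x 224", call. = FALSE)
  }
  d[1]
}

# Parameter-independent input preparation: per-slice channel-last layout,
# plus the fixed 4x box-average downsampling of the tiny_cnn front end.
# Preparing once per volume (instead of per forward pass) is what makes
# multi-epoch training affordable, and the prepared stack is ~16x smaller
# than the fused volume, so it is also what gets cached across epochs.
as_input_stack <- function(volume, backbone) {
  if (inherits(volume, "knet_input_stack")) {
    if (!identical(attr(volume, "backbone"), backbone)) {
      stop("input stack was prepared for a different backbone", call. = FALSE)
    }
    return(volume)
  }
  s <- check_fused_volume(volume)
  slices <- vector("list", s)
  for (k in seq_len(s)) {
    x <- aperm(array(volume[k, , , ], c(3L, 224L, 224L)), c(2, 3, 1))
    if (backbone == "tiny_cnn") x <- avgpool_hwc(x, knet_cache_pool_matrix())
    slices[[k]] <- x
  }
  structure(list(slices = slices), class = "knet_input_stack",
            backbone = backbone)
}

# Forward pass of one backbone on one prepared slice.
backbone_forward_slice <- function(x0, layers, backbone, keep_cache = FALSE) {
  if (backbone == "tiny_cnn") {
    c1 <- conv_forward(x0, layers[[1]], keep_cache); a1 <- relu(c1$y)
    c2 <- conv_forward(a1, layers[[2]], keep_cache); a2 <- relu(c2$y)
    c3 <- conv_forward(a2, layers[[3]], keep_cache); a3 <- relu(c3$y)
    cache <- if (keep_cache) list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                                  a1 = a1, a2 = a2, a3 = a3) else NULL
    list(f = a3, cache = cache)
  } else {
    y <- relu(conv_forward(x0, layers[[1]])$y)
    y <- maxpool_hwc(y, 3L, 2L)
    y <- relu(conv_forward(y, layers[[2]])$y)
    y <- maxpool_hwc(y, 3L, 2L)
    y <- relu(conv_forward(y, layers[[3]])$y)
    y <- relu(conv_forward(y, layers[[4]])$y)
    y <- relu(conv_forward(y, layers[[5]])$y)
    y <- maxpool_hwc(y, 3L, 2L)
    list(f = adaptive_avgpool_hwc(y, KNET_SPATIAL_OUT), cache = NULL)
  }
}

# Memoized 56 x 224 box-average pooling matrix.
knet_env <- new.env(parent = emptyenv())
knet_cache_pool_matrix <- function() {
  if (is.null(knet_env$P56)) knet_env$P56 <- pool_matrix(224L, 4L)
  knet_env$P56
}

#' Extract per-slice convolutional features
#'
#' Runs the stream's backbone independently on every slice of a fused volume
#' (no cross-slice mixing) and returns the `s x 256 x 7 x 7` feature stack.
#'
#' @param volume A `"fused_volume"` of shape `s x 3 x 224 x 224`.
#' @param params A [knet_params()].
#' @param stream Stream index or sequence-type name (default: first stream).
#' @return Numeric array `s x 256 x 7 x 7`.
#' @export
extract_slice_features <- function(volume, params, stream = 1L) {
  stopifnot(inherits(params, "knet_params"))
  stack <- as_input_stack(volume, params$backbone)
  s <- length(stack$slices)
  branch <- params$streams[[stream]]
  out <- array(0, c(s, KNET_FEATURE_CHANNELS, KNET_SPATIAL_OUT, KNET_SPATIAL_OUT))
  for (k in seq_len(s)) {
    f <- backbone_forward_slice(stack$slices[[k]], branch$layers,
                                params$backbone)$f
    out[k, , , ] <- aperm(f, c(3, 1, 2))  # (7,7,256) -> (256,7,7)
  }
  out
}

#' Average-pool slice features over the spatial grid
#'
#' Reduces `s x 256 x 7 x 7` features to an `s x 256` matrix by the mean over
#' each slice's 7 x 7 spatial grid, per channel.
#'
#' @param features Array `s x 256 x 7 x 7` from [extract_slice_features()].
#' @return Numeric matrix `s x 256`.
#' @export
pool_slices <- function(features) {
  d <- dim(features)
  if (length(d) != 4L || d[2] != KNET_FEATURE_CHANNELS ||
      d[3] != KNET_SPATIAL_OUT || d[4] != KNET_SPATIAL_OUT) {
    stop("expected features of shape s x 256 x 7 x 7", call. = FALSE)
  }
  s <- d[1]
  out <- matrix(0, s, d[2])
  for (k in seq_len(s)) {
    out[k, ] <- rowMeans(matrix(features[k, , , ], d[2],
                                KNET_SPATIAL_OUT * KNET_SPATIAL_OUT))
  }
  out
}

#' Aggregate pooled slice vectors into one exam embedding
#'
#' The "weighted downsampling" over slices: a learned linear map scores each
#' slice's 256-vector, scores pass through a softmax over slices, and the
#' embedding is the weight-sum of the slice vectors. Weights are a
#' probability vector, so the embedding is a convex combination of slice
#' vectors — permutation-invariant and equal to the single slice vector when
#' `s = 1`.
#'
#' @param pooled Numeric matrix `s x 256` from [pool_slices()].
#' @param attn Attention parameters: list with 256-vector `u` and scalar `c`
#'   (e.g. `params$streams[[i]]$attn`).
#' @return The 256-dim embedding, with the slice weights attached as
#'   attribute `"weights"`.
#' @export
aggregate_slices <- function(pooled, attn) {
  if (!is.matrix(pooled) || ncol(pooled) != KNET_FEATURE_CHANNELS) {
    stop("expected a pooled matrix of shape s x 256", call. = FALSE)
  }
  if (nrow(pooled) < 1L) stop("at least one slice is required", call. = FALSE)
  scores <- as.numeric(pooled %*% attn$u + attn$c)
  w <- softmax(scores)
  emb <- as.numeric(crossprod(pooled, w))
  attr(emb, "weights") <- w
  emb
}

head_forward <- function(emb, head) {
  z <- sum(emb * head$v) + head$b
  stats::plogis(z)
}

# Full single-stream forward with optional caches for backprop.
knet_forward_stream <- function(volume, branch, backbone, keep_cache = FALSE) {
  stack <- as_input_stack(volume, backbone)
  s <- length(stack$slices)
  pooled <- matrix(0, s, KNET_FEATURE_CHANNELS)
  caches <- if (keep_cache) vector("list", s) else NULL
  for (k in seq_len(s)) {
    bf <- backbone_forward_slice(stack$slices[[k]], branch$layers, backbone,
                                 keep_cache)
    pooled[k, ] <- colMeans(matrix(bf$f, KNET_SPATIAL_OUT^2,
                                   KNET_FEATURE_CHANNELS))
    if (keep_cache) caches[[k]] <- bf$cache
  }
  emb <- aggregate_slices(pooled, branch$attn)
  list(embedding = emb, pooled = pooled, weights = attr(emb, "weights"),
       caches = caches)
}

#' Single-stream KNet forward pass
#'
#' @param volume A `"fused_volume"` of shape `s x 3 x 224 x 224`.
#' @param params A [knet_params()].
#' @param stream Stream index or sequence-type name.
#' @return A list with `probability` (in `[0, 1]`), `label` (1 iff
#'   probability >= 0.5), `embedding` (256-vector) and `weights` (slice
#'   attention weights).
#' @export
forward_knet <- function(volume, params, stream = 1L) {
  stopifnot(inherits(params, "knet_params"))
  st <- knet_forward_stream(volume, params$streams[[stream]], params$backbone)
  p <- head_forward(st$embedding, params$head)
  list(probability = p, label = as.integer(p >= 0.5),
       embedding = as.numeric(st$embedding), weights = st$weights)
}

#' Multi-stream KNet forward pass
#'
#' Each stream processes its own sequence's fused volume through its own
#' backbone and attention; the per-stream embeddings are fused by an
#' arithmetic mean and classified by the single shared head. With one stream
#' this reduces exactly to [forward_knet()].
#'
#' @param streams Named list mapping sequence type to `"fused_volume"`; names
#'   must match `params$stream_sequences`.
#' @param params A [knet_params()].
#' @return As [forward_knet()], plus `stream_embeddings`.
#' @export
forward_msknet <- function(streams, params) {
  stopifnot(inherits(params, "knet_params"))
  missing_streams <- setdiff(params$stream_sequences, names(streams))
  if (length(missing_streams) > 0) {
    stop("missing stream volume(s): ", paste(missing_streams, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(streams), params$stream_sequences)
  if (length(unknown) > 0) {
    stop("volume(s) for sequence(s) not configured as streams: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  embs <- lapply(params$stream_sequences, function(sq) {
    knet_forward_stream(streams[[sq]], params$streams[[sq]],
                        params$backbone)$embedding
  })
  fused <- Reduce(`+`, lapply(embs, as.numeric)) / length(embs)
  p <- head_forward(fused, params$head)
  list(probability = p, label = as.integer(p >= 0.5), embedding = fused,
       stream_embeddings = embs)
}
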