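# Class-weighted binary cross-entropy training of KNet / MS-KNet.
#
# The objective per exam is L = -alpha * y * log(p) - (1 - y) * log(1 - p):
# the weighting factor multiplies only the positive term, compensating class
# imbalance. alpha defaults to the negative/positive count ratio on the
# training split. Optimization is Adam with a batch of one exam (slice counts
# vary between exams, which makes cross-exam batching awkward); the tiny_cnn
# backbone trains end to end, the alexnet_random backbone stays frozen and
# only attention + head train.

#' Class-weighted binary cross-entropy
#'
#' `loss = mean(-alpha * y * log(p) - (1 - y) * log(1 - p))` with predictions
#' clamped to `[eps, 1 - eps]` for numerical safety. The weight multiplies
#' only the positive term, so for `y = 0` the loss does not depend on
#' `alpha`.
#'
#' @param y_hat Predicted probabilities in `[0, 1]` (vectorized).
#' @param y Ground-truth labels in `{0, 1}`, same length.
#' @param alpha Positive-class weight, `> 0` (scalar).
#' @param eps Probability clamp floor.
#' @return The mean loss (non-negative scalar).
#' @export
weighted_bce <- function(y_hat, y, alpha = 1, eps = 1e-7) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("'alpha' must be a positive scalar", call. = FALSE)
  }
  if (length(y_hat) != length(y)) {
    stop("'y_hat' and 'y' must have equal length", call. = FALSE)
  }
  if (!is_binary01(y)) stop("'y' must be binary 0/1", call. = FALSE)
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  mean(-alpha * y * log(p) - (1 - y) * log(1 - p))
}

#' Negative/positive class-weight ratio for a task
#'
#' The automatic weighting policy: `alpha = N_negative / N_positive` on the
#' training split, so positives and negatives contribute equal total weight.
#'
#' @param manifest A [label_manifest()].
#' @param task One of [TASKS].
#' @param split Which split to count (default `"train"`).
#' @return The scalar weight.
#' @export
compute_alpha <- function(manifest, task = TASKS, split = "train") {
  stopifnot(inherits(manifest, "label_manifest"))
  task <- match.arg(task)
  labels <- manifest[[task]][manifest$split == split]
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate task '", task, "': both classes must be present in the ",
         split, " split", call. = FALSE)
  }
  n_neg / n_pos
}

# ---- parameter flattening for the optimizer -------------------------------

trainable_param_list <- function(params,
                                 train_backbone = params$backbone == "tiny_cnn") {
  out <- list()
  for (i in seq_len(params$n_streams)) {
    st <- params$streams[[i]]
    if (train_backbone) {
      for (j in seq_along(st$layers)) {
        out[[sprintf("s%d.l%d.W", i, j)]] <- st$layers[[j]]$W
        out[[sprintf("s%d.l%d.b", i, j)]] <- st$layers[[j]]$b
      }
    }
    out[[sprintf("s%d.attn.u", i)]] <- st$attn$u
    out[[sprintf("s%d.attn.c", i)]] <- st$attn$c
  }
  out[["head.v"]] <- params$head$v
  out[["head.b"]] <- params$head$b
  out
}

set_param_list <- function(params, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "head") {
      params$head[[if (parts[2] == "v") "v" else "b"]] <- flat[[nm]]
    } else {
      i <- as.integer(sub("s", "", parts[1]))
      if (parts[2] == "attn") {
        params$streams[[i]]$attn[[parts[3]]] <- flat[[nm]]
      } else {
        j <- as.integer(sub("l", "", parts[2]))
        params$streams[[i]]$layers[[j]][[parts[3]]] <- flat[[nm]]
      }
    }
  }
  params
}

# ---- backward pass --------------------------------------------------------

# Gradient of the weighted BCE w.r.t. the head logit z (p = plogis(z)):
# dL/dz = -alpha * y * (1 - p) + (1 - y) * p.
bce_logit_grad <- function(p, y, alpha) {
  -alpha * y * (1 - p) + (1 - y) * p
}

# Backward through softmax attention for one stream.
# Returns grads for u, c and the pooled slice matrix.
attention_backward <- function(demb, pooled, w, u) {
  dw <- as.numeric(pooled %*% demb)
  ds <- w * (dw - sum(w * dw))
  list(du = as.numeric(crossprod(pooled, ds)),
       dc = sum(ds),
       dpooled = tcrossprod(w, demb) + tcrossprod(ds, u))
}

# Backward through the tiny_cnn backbone for one slice.
backbone_backward_slice <- function(dpooled_k, layers, cache) {
  df <- array(rep(dpooled_k, each = KNET_SPATIAL_OUT^2) / KNET_SPATIAL_OUT^2,
              c(KNET_SPATIAL_OUT, KNET_SPATIAL_OUT, KNET_FEATURE_CHANNELS))
  df <- df * (cache$a3 > 0)
  g3 <- conv_backward(df, layers[[3]], cache$c3, need_dx = TRUE)
  d2 <- g3$dx * (cache$a2 > 0)
  g2 <- conv_backward(d2, layers[[2]], cache$c2, need_dx = TRUE)
  d1 <- g2$dx * (cache$a1 > 0)
  g1 <- conv_backward(d1, layers[[1]], cache$c1, need_dx = FALSE)
  list(g1 = g1, g2 = g2, g3 = g3)
}

# Forward + backward of one exam; returns loss, probability and flat grads.
knet_exam_grads <- function(stream_volumes, params, y, alpha,
                            train_backbone = params$backbone == "tiny_cnn") {
  n_str <- params$n_streams
  fw <- lapply(params$stream_sequences, function(sq) {
    knet_forward_stream(stream_volumes[[sq]], params$streams[[sq]],
                        params$backbone, keep_cache = train_backbone)
  })
  names(fw) <- params$stream_sequences
  fused <- Reduce(`+`, lapply(fw, function(f) as.numeric(f$embedding))) / n_str
  p <- head_forward(fused, params$head)
  loss <- weighted_bce(p, y, alpha)
  dz <- bce_logit_grad(p, y, alpha)

  grads <- list()
  grads[["head.v"]] <- dz * fused
  grads[["head.b"]] <- dz
  dfused <- dz * params$head$v
  for (i in seq_len(n_str)) {
    st <- fw[[i]]
    branch <- params$streams[[i]]
    demb <- dfused / n_str
    ab <- attention_backward(demb, st$pooled, st$weights, branch$attn$u)
    grads[[sprintf("s%d.attn.u", i)]] <- ab$du
    grads[[sprintf("s%d.attn.c", i)]] <- ab$dc
    if (train_backbone) {
      acc <- NULL
      for (k in seq_len(nrow(st$pooled))) {
        g <- backbone_backward_slice(ab$dpooled[k, ], branch$layers,
                                     st$caches[[k]])
        if (is.null(acc)) {
          acc <- g
        } else {
          for (l in c("g1", "g2", "g3")) {
            acc[[l]]$dW <- acc[[l]]$dW + g[[l]]$dW
            acc[[l]]$db <- acc[[l]]$db + g[[l]]$db
          }
        }
      }
      for (j in 1:3) {
        gl <- acc[[sprintf("g%d", j)]]
        grads[[sprintf("s%d.l%d.W", i, j)]] <- gl$dW
        grads[[sprintf("s%d.l%d.b", i, j)]] <- gl$db
      }
    }
  }
  list(loss = loss, probability = p, grads = grads)
}

# ---- data plumbing --------------------------------------------------------

# Fetch one raw series for an exam from an in-memory cohort or a DICOM tree.
fetch_series <- function(source, exam_id, sequence_type, manifest) {
  if (inherits(source, "phantom_cohort")) {
    ser <- source$exams[[exam_id]]$series[[sequence_type]]
    if (is.null(ser)) {
      stop("exam ", exam_id, " has no ", sequence_type, " series", call. = FALSE)
    }
    ser
  } else {
    rel <- manifest[[sequence_type]][manifest$exam_id == exam_id]
    if (length(rel) != 1L || is.na(rel) || rel == "") {
      stop("manifest has no ", sequence_type, " path for exam ", exam_id,
           call. = FALSE)
    }
    read_dicom_series(file.path(source, rel), exam_id = exam_id,
                      sequence_type = sequence_type)
  }
}

# resize -> window -> fuse pipeline for one series.
build_fused <- function(source, exam_id, sequence_type, manifest, window,
                        stats, lbp = TRUE, dwt = TRUE) {
  ser <- fetch_series(source, exam_id, sequence_type, manifest)
  ser <- resize_series(ser, 224L)
  ser <- apply_window(ser, window)
  suppressWarnings(fuse_volume(ser, stats, lbp = lbp, dwt = dwt))
}

resolve_source <- function(x) {
  if (inherits(x, "phantom_cohort")) {
    list(source = x, manifest = x$manifest)
  } else if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    list(source = x, manifest = load_manifest(file.path(x, "manifest.csv")))
  } else if (is.list(x) && !is.null(x$dir) && !is.null(x$manifest)) {
    list(source = x$dir, manifest = label_manifest(x$manifest))
  } else {
    stop("'data' must be a phantom_cohort, a DICOM tree directory containing ",
         "manifest.csv, or list(dir =, manifest =)", call. = FALSE)
  }
}

# Streaming fit of normalization statistics over the training split.
fit_stats_streaming <- function(source, manifest, exam_ids, sequences, window) {
  n <- 0; s1 <- 0; s2 <- 0
  for (eid in exam_ids) {
    for (sq in sequences) {
      ser <- fetch_series(source, eid, sq, manifest)
      ser <- resize_series(ser, 224L)
      px <- apply_window(ser, window)$pixels
      n <- n + length(px); s1 <- s1 + sum(px); s2 <- s2 + sum(px^2)
    }
  }
  m <- s1 / n
  sd <- sqrt(max(s2 / n - m^2, 0))
  if (sd <= 0 || !is.finite(sd)) {
    stop("degenerate training set: windowed pixel variance is zero",
         call. = FALSE)
  }
  structure(list(mean = m, sd = sd, window = window, n_pixels = n,
                 n_series = length(exam_ids) * length(sequences)),
            class = "norm_stats")
}

# ---- the fitting function -------------------------------------------------

#' Fit a KNet / MS-KNet classifier
#'
#' The central modelling function: fits a slice-aggregating CNN for one
#' binary task on the training split of a cohort, using class-weighted
#' binary cross-entropy (weight `alpha` = negative/positive ratio unless
#' given) and Adam with a batch of one exam. Normalization statistics are
#' fitted on the training split only; test exams are never touched during
#' training, and supplying a test exam id in `train_ids` is an error.
#'
#' @param data A `"phantom_cohort"`, a directory containing a DICOM tree plus
#'   `manifest.csv`, or `list(dir =, manifest =)`.
#' @param task One of [TASKS].
#' @param sequences Sequence types used as input streams (1-3).
#' @param backbone See [knet_params()].
#' @param epochs Number of passes over the training split.
#' @param lr Adam learning rate for the attention and classification head.
#' @param lr_backbone Adam learning rate for the convolutional backbone
#'   (ignored for the frozen `alexnet_random` backbone).
#' @param alpha Positive-class weight; `NULL` (default) uses the
#'   negative/positive training ratio.
#' @param window An [intensity_window()] (default full range).
#' @param lbp,dwt Enable the texture channels of the fused input.
#' @param train_ids Optional explicit set of training exam ids (must all be
#'   in the train split).
#' @param cache_limit Approximate memory bound (bytes) for caching fused
#'   volumes across epochs; above it they are recomputed on the fly.
#' @param seed Seed governing weight initialization and exam shuffling.
#' @param verbose Print the per-epoch mean loss.
#' @return An object of class `"knet"` with components `params`, `stats`,
#'   `alpha`, `task`, `sequences`, `log` (epoch, mean_loss, seed),
#'   `train_predictions` and the matched `call`.
#' @seealso [predict.knet()], [evaluate_model()], [run_ablation()]
#' @export
knet <- function(data, task = TASKS, sequences = "sagittal_t1",
                 backbone = "tiny_cnn", epochs = 10L, lr = 5e-3,
                 lr_backbone = 1e-4, alpha = NULL,
                 window = intensity_window(),
                 lbp = TRUE, dwt = TRUE, train_ids = NULL,
                 cache_limit = 3e9, seed = 1L, verbose = FALSE) {
  task <- match.arg(task)
  src <- resolve_source(data)
  manifest <- src$manifest
  if (epochs < 1L) stop("'epochs' must be >= 1", call. = FALSE)
  sequences <- match.arg(sequences, SEQUENCE_TYPES, several.ok = TRUE)

  all_train <- manifest$exam_id[manifest$split == "train"]
  if (is.null(train_ids)) {
    train_ids <- all_train
  } else {
    leaked <- setdiff(train_ids, all_train)
    if (length(leaked) > 0) {
      stop("train_ids contain exam(s) outside the train split: ",
           paste(leaked, collapse = ", "), call. = FALSE)
    }
  }
  if (length(train_ids) == 0) stop("empty training set", call. = FALSE)

  labels <- manifest[[task]][match(train_ids, manifest$exam_id)]
  if (is.null(alpha)) {
    n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
    if (n_pos == 0 || n_neg == 0) {
      stop("degenerate task '", task,
           "': both classes must be present for training", call. = FALSE)
    }
    alpha <- n_neg / n_pos
  }

  stats <- fit_stats_streaming(src$source, manifest, train_ids, sequences,
                               window)

  # cache fused volumes across epochs when they fit in memory
  slice_counts <- vapply(train_ids, function(eid) {
    dim(fetch_series(src$source, eid, sequences[1], manifest)$pixels)[1]
  }, 0)
  input_side <- if (backbone == "tiny_cnn") 56 else 224
  est_bytes <- sum(slice_counts) * length(sequences) * 3 * input_side^2 * 8
  use_cache <- est_bytes <= cache_limit
  cache <- if (use_cache) new.env(parent = emptyenv()) else NULL
  get_streams <- function(eid) {
    if (use_cache && !is.null(cache[[eid]])) return(cache[[eid]])
    vols <- lapply(sequences, function(sq) {
      as_input_stack(
        build_fused(src$source, eid, sq, manifest, window, stats, lbp, dwt),
        backbone)
    })
    names(vols) <- sequences
    if (use_cache) cache[[eid]] <- vols
    vols
  }

  params <- knet_params(sequences, backbone = backbone, seed = seed)
  train_backbone <- backbone == "tiny_cnn" && lr_backbone > 0
  flat <- trainable_param_list(params, train_backbone)
  state <- adam_init(flat)
  # parameter-group learning rates: the attention + head learn fast on
  # quasi-static features while the backbone fine-tunes slowly, which keeps
  # batch-of-one Adam from churning the feature space faster than the head
  # can track it
  lr_map <- vapply(names(flat), function(nm) {
    if (grepl("^s\\d+\\.l\\d+\\.", nm)) lr_backbone else lr
  }, 0)
  log_rows <- vector("list", epochs)

  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(train_ids))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        eid <- train_ids[ord[ii]]
        y <- labels[ord[ii]]
        res <- knet_exam_grads(get_streams(eid), params, y, alpha,
                               train_backbone)
        losses[ii] <- res$loss
        upd <- adam_step(flat, res$grads, state, lr_map)
        flat <- upd$params
        state <- upd$state
        params <- set_param_list(params, flat)
      }
      log_rows[[ep]] <- data.frame(epoch = ep, mean_loss = mean(losses),
                                   seed = seed)
      if (verbose) {
        message(sprintf("epoch %d/%d: mean loss %.4f", ep, epochs,
                        mean(losses)))
      }
    }
  })
  log <- do.call(rbind, log_rows)

  train_pred <- vapply(train_ids, function(eid) {
    forward_msknet(get_streams(eid), params)$probability
  }, 0)

  structure(
    list(params = params, stats = stats, window = window, alpha = alpha,
         task = task, sequences = sequences, backbone = backbone,
         epochs = epochs, lr = lr, lr_backbone = lr_backbone,
         lbp = lbp, dwt = dwt, seed = seed,
         log = log,
         train_predictions = data.frame(
           exam_id = train_ids, y = labels,
           probability = unname(train_pred),
           label = as.integer(train_pred >= 0.5),
           stringsAsFactors = FALSE),
         fingerprint = list(mean = stats$mean, sd = stats$sd,
                            window = c(stats$window$low, stats$window$high),
                            task = task, n_train = length(train_ids)),
         call = match.call()),
    class = "knet")
}

#' @export
print.knet <- function(x, ...) {
  cat(sprintf("KNet classifier for task '%s'\n", x$task))
  cat(sprintf("  streams: %s (%s backbone)\n",
              paste(x$sequences, collapse = " + "), x$backbone))
  cat(sprintf("  trained %d epoch(s), alpha = %.3f, final mean loss %.4f\n",
              x$epochs, x$alpha, x$log$mean_loss[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.knet <- function(object, ...) {
  tp <- object$train_predictions
  acc <- mean(tp$label == tp$y)
  cat(sprintf("KNet classifier: task '%s', %d stream(s) [%s], %s backbone\n",
              object$task, length(object$sequences),
              paste(object$sequences, collapse = ", "), object$backbone))
  cat(sprintf("  training exams: %d (positives %d), alpha %.3f\n",
              nrow(tp), sum(tp$y), object$alpha))
  cat(sprintf("  normalization: mean %.3f, sd %.3f\n",
              object$stats$mean, object$stats$sd))
  cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              object$log$mean_loss[1], object$log$mean_loss[nrow(object$log)],
              object$epochs))
  cat(sprintf("  training accuracy at threshold 0.5: %.3f\n", acc))
  invisible(object)
}

#' @export
coef.knet <- function(object, ...) {
  out <- list(head = c(object$params$head$v, bias = object$params$head$b))
  for (sq in object$sequences) {
    out[[paste0("attention.", sq)]] <-
      c(object$params$streams[[sq]]$attn$u,
        bias = object$params$streams[[sq]]$attn$c)
  }
  out
}

#' @export
residuals.knet <- function(object, ...) {
  r <- object$train_predictions$y - object$train_predictions$probability
  names(r) <- object$train_predictions$exam_id
  r
}

#' @export
plot.knet <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$mean_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean weighted BCE",
                 main = sprintf("KNet training loss (task: %s)", x$task), ...)
  invisible(x)
}

#' Predict injury probabilities for exams of a cohort
#'
#' One deterministic forward pass per exam through the fitted model, using
#' the model's own preprocessing statistics (fitted on its training split).
#'
#' @param object A fitted [knet()] model.
#' @param newdata A cohort/directory as in [knet()].
#' @param split Which exams to score: `"test"` (default), `"train"` or
#'   `"all"`.
#' @param ... Unused.
#' @return A data frame with `exam_id`, `y` (true label for the model's
#'   task), `probability` and `label` (threshold 0.5; ties go to 1).
#' @export
predict.knet <- function(object, newdata, split = c("test", "train", "all"),
                         ...) {
  split <- match.arg(split)
  src <- resolve_source(newdata)
  manifest <- src$manifest
  rows <- if (split == "all") manifest else manifest[manifest$split == split, ]
  if (nrow(rows) == 0) stop("no exams in split '", split, "'", call. = FALSE)
  probs <- vapply(rows$exam_id, function(eid) {
    vols <- lapply(object$sequences, function(sq) {
      build_fused(src$source, eid, sq, manifest, object$window, object$stats,
                  object$lbp, object$dwt)
    })
    names(vols) <- object$sequences
    forward_msknet(vols, object$params)$probability
  }, 0)
  data.frame(exam_id = rows$exam_id, y = rows[[object$task]],
             probability = unname(probs),
             label = as.integer(probs >= 0.5),
             stringsAsFactors = FALSE)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint bundles the weights, configuration and the preprocessing
#' statistics fingerprint, so evaluation can verify it scores data
#' preprocessed consistently with training.
#'
#' @param model A fitted [knet()] model.
#' @param path Checkpoint file path.
#' @return `save_knet` returns `path` invisibly; `load_knet` the model.
#' @export
save_knet <- function(model, path) {
  stopifnot(inherits(model, "knet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_knet
#' @export
load_knet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "knet")) stop("not a knet checkpoint: ", path,
                                     call. = FALSE)
  model
}
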