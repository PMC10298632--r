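# Feature-fusion preprocessing: intensity windowing, training-set
# z-normalization, LBP and Haar-DWT alternative representations, and the
# 3-channel fused volume the network consumes.

#' Intensity range of interest
#'
#' Pixels strictly outside `[low, high]` are zeroed before normalization.
#' Clinically these bands are chosen per task by radiologists; the package
#' ships a permissive full-range default since no published values exist.
#'
#' @param low,high Window bounds in intensity units, `low < high`.
#' @return An object of class `"intensity_window"`.
#' @export
intensity_window <- function(low = -Inf, high = Inf) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (!(low < high)) stop("window 'low' must be below 'high'", call. = FALSE)
  structure(list(low = low, high = high), class = "intensity_window")
}

#' Zero pixels outside the intensity range of interest
#'
#' Pixels strictly below `window$low` or strictly above `window$high` are set
#' to 0; in-range pixels are unchanged. The operation is idempotent as long
#' as 0 itself is not strictly inside an all-positive window's excluded zone
#' (with the shipped full-range default it always is idempotent).
#'
#' @param series An [mri_series()].
#' @param window An [intensity_window()].
#' @return The windowed [mri_series()].
#' @export
apply_window <- function(series, window) {
  stopifnot(inherits(series, "mri_series"), inherits(window, "intensity_window"))
  px <- series$pixels
  px[px < window$low | px > window$high] <- 0
  series$pixels <- px
  series
}

#' Fit normalization statistics on a training set
#'
#' Computes the mean and population standard deviation over *all* pixels of
#' all windowed training series. These statistics parameterize the
#' z-normalization z = (x - mean) / sd applied to every series, train or
#' test, so that no test-set information leaks into preprocessing.
#'
#' @param training_series List of [mri_series()] from the training split.
#' @param window An [intensity_window()] applied before accumulation
#'   (default: full range, a no-op).
#' @return An object of class `"norm_stats"` with fields `mean`, `sd`,
#'   `window`, `n_pixels`, `n_series`.
#' @export
fit_norm_stats <- function(training_series, window = intensity_window()) {
  if (inherits(training_series, "mri_series")) {
    training_series <- list(training_series)
  }
  stopifnot(length(training_series) >= 1L,
            all(vapply(training_series, inherits, TRUE, "mri_series")),
            inherits(window, "intensity_window"))
  n <- 0; s1 <- 0; s2 <- 0
  for (ser in training_series) {
    px <- apply_window(ser, window)$pixels
    n <- n + length(px)
    s1 <- s1 + sum(px)
    s2 <- s2 + sum(px^2)
  }
  m <- s1 / n
  var_pop <- max(s2 / n - m^2, 0)
  sd <- sqrt(var_pop)
  if (sd <= 0 || !is.finite(sd)) {
    stop("degenerate training set: windowed pixel variance is zero",
         call. = FALSE)
  }
  structure(list(mean = m, sd = sd, window = window,
                 n_pixels = n, n_series = length(training_series)),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("Normalization stats: mean %.4f, sd %.4f (%d series, %g pixels)\n",
              x$mean, x$sd, x$n_series, x$n_pixels))
  if (is.finite(x$window$low) || is.finite(x$window$high)) {
    cat(sprintf("  window: [%g, %g]\n", x$window$low, x$window$high))
  }
  invisible(x)
}

#' Z-normalize a series with training-set statistics
#'
#' Every pixel becomes `z = (x - mean) / sd`.
#'
#' @param series An [mri_series()] (already windowed).
#' @param stats A [fit_norm_stats()] result with `sd > 0`.
#' @return The normalized [mri_series()].
#' @export
normalize_series <- function(series, stats) {
  stopifnot(inherits(series, "mri_series"), inherits(stats, "norm_stats"))
  if (stats$sd <= 0) stop("normalization sd must be positive", call. = FALSE)
  series$pixels <- (series$pixels - stats$mean) / stats$sd
  series
}

#' Local binary pattern map of one slice
#'
#' Classic 8-neighbor radius-1 LBP: for each pixel, the 8 neighbors are
#' compared to the center with `>=`; each comparison contributes one bit,
#' ordered clockwise from the top-left neighbor with the top-left as the most
#' significant bit. Borders are handled by edge replication. Codes lie in
#' `[0, 255]`; a constant image codes to 255 everywhere (all ties, and ties
#' count as 1 under the `>=` convention). The map is invariant under strictly
#' increasing intensity transforms on images without equal-valued
#' neighbor pairs.
#'
#' @param slice A 2-D numeric matrix.
#' @return An integer matrix of the same size with values in `[0, 255]`.
#' @export
lbp_map <- function(slice) {
  if (!is.matrix(slice)) stop("'slice' must be a 2-D matrix", call. = FALSE)
  h <- nrow(slice); w <- ncol(slice)
  p <- rbind(slice[1, , drop = FALSE], slice, slice[h, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, w, drop = FALSE])
  ri <- 2:(h + 1); ci <- 2:(w + 1)
  # neighbors clockwise from top-left; top-left is the most significant bit
  code <- 128L * (p[ri - 1, ci - 1] >= slice) +
           64L * (p[ri - 1, ci    ] >= slice) +
           32L * (p[ri - 1, ci + 1] >= slice) +
           16L * (p[ri,     ci + 1] >= slice) +
            8L * (p[ri + 1, ci + 1] >= slice) +
            4L * (p[ri + 1, ci    ] >= slice) +
            2L * (p[ri + 1, ci - 1] >= slice) +
            1L * (p[ri,     ci - 1] >= slice)
  matrix(as.integer(code), h, w)
}

#' Single-level 2-D Haar wavelet decomposition
#'
#' Orthonormal Haar filter bank on non-overlapping 2x2 blocks. For block
#' values a (top-left), b (top-right), c (bottom-left), d (bottom-right):
#' LL = (a+b+c+d)/2, LH = (a+b-c-d)/2, HL = (a-b+c-d)/2, HH = (a-b-c+d)/2.
#' The transform preserves energy (Parseval): the sum of squares over the
#' four subbands equals the sum of squares of the input. A constant image of
#' value `c` has LL constant at `2c` and zero detail subbands.
#'
#' @param slice A 2-D numeric matrix with even height and width.
#' @return A list with matrices `LL`, `LH`, `HL`, `HH`, each half-size.
#' @export
dwt_haar2 <- function(slice) {
  if (!is.matrix(slice)) stop("'slice' must be a 2-D matrix", call. = FALSE)
  h <- nrow(slice); w <- ncol(slice)
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop("Haar DWT requires even spatial dimensions", call. = FALSE)
  }
  a <- slice[seq(1, h, 2), seq(1, w, 2)]
  b <- slice[seq(1, h, 2), seq(2, w, 2)]
  c <- slice[seq(2, h, 2), seq(1, w, 2)]
  d <- slice[seq(2, h, 2), seq(2, w, 2)]
  list(LL = (a + b + c + d) / 2,
       LH = (a + b - c - d) / 2,
       HL = (a - b + c - d) / 2,
       HH = (a - b - c + d) / 2)
}

#' DWT channel map of one slice
#'
#' The low-pass (LL) approximation subband of the single-level Haar
#' decomposition, upsampled bilinearly back to the slice's original size so
#' it stays spatially registered with the other channels.
#'
#' @param slice A 2-D numeric matrix with even dimensions.
#' @return A numeric matrix of the input size.
#' @export
dwt_map <- function(slice) {
  ll <- dwt_haar2(slice)$LL
  h <- nrow(slice); w <- ncol(slice)
  up <- EBImage::resize(ll, w = h, h = w, filter = "bilinear")
  matrix(up, h, w)
}

#' Fuse a series into the network's 3-channel representation
#'
#' Builds the `s x 3 x 224 x 224` input stack: channel 1 is the z-normalized
#' original slice, channels 2 and 3 are the LBP and DWT maps of the windowed
#' (pre-normalization) slice, each standardized per slice to zero mean and
#' unit (population) sd so the channels are commensurate for a shared first
#' convolution. A channel that is constant on some slice (zero sd) falls back
#' to zeros there, with a warning.
#'
#' @param series An [mri_series()] already windowed and resized to 224 x 224.
#' @param stats A [fit_norm_stats()] result from the training split.
#' @param lbp,dwt Enable each texture channel; a disabled channel is zeros.
#' @return An object of class `"fused_volume"`: the array of dimension
#'   `c(s, 3, 224, 224)` with `exam_id` and `sequence_type` attributes.
#' @export
fuse_volume <- function(series, stats, lbp = TRUE, dwt = TRUE) {
  stopifnot(inherits(series, "mri_series"), inherits(stats, "norm_stats"))
  d <- dim(series$pixels)
  if (d[2] != 224L || d[3] != 224L) {
    stop("fuse_volume expects slices resized to 224 x 224 (got ",
         d[2], "x", d[3], ")", call. = FALSE)
  }
  s <- d[1]
  out <- array(0, c(s, 3L, 224L, 224L))
  norm <- normalize_series(series, stats)
  fallback <- FALSE
  standardize <- function(m) {
    sd <- sd_pop(m)
    if (sd <= 0 || !is.finite(sd)) {
      fallback <<- TRUE
      return(matrix(0, nrow(m), ncol(m)))
    }
    (m - mean(m)) / sd
  }
  for (k in seq_len(s)) {
    raw_sl <- series$pixels[k, , ]
    out[k, 1, , ] <- norm$pixels[k, , ]
    if (lbp) out[k, 2, , ] <- standardize(lbp_map(raw_sl))
    if (dwt) out[k, 3, , ] <- standardize(dwt_map(raw_sl))
  }
  if (fallback) {
    warning("constant LBP/DWT channel on at least one slice; using zeros",
            call. = FALSE)
  }
  structure(out, exam_id = series$exam_id,
            sequence_type = series$sequence_type, class = "fused_volume")
}

#' Persist / load a fused volume as a flat binary array with a JSON sidecar
#'
#' The array is stored as little-endian doubles at `path`; `path.json` holds
#' the dimensions, exam id, sequence type and the normalization statistics
#' used, so a stored volume can be checked against a model's preprocessing
#' fingerprint.
#'
#' @param volume A `"fused_volume"`.
#' @param path Output file path (binary payload; sidecar at `path.json`).
#' @param stats Optional [fit_norm_stats()] recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
save_fused_volume <- function(volume, path, stats = NULL) {
  stopifnot(inherits(volume, "fused_volume"))
  con <- file(path, "wb")
  writeBin(as.vector(unclass(volume)), con, size = 8, endian = "little")
  close(con)
  side <- list(dim = dim(volume),
               exam_id = attr(volume, "exam_id"),
               sequence_type = attr(volume, "sequence_type"))
  if (!is.null(stats)) {
    side$stats <- list(mean = stats$mean, sd = stats$sd,
                       window = c(stats$window$low, stats$window$high))
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_fused_volume
#' @export
load_fused_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(side$dim)
  v <- readBin(path, "double", n = n, size = 8, endian = "little")
  structure(array(v, side$dim), exam_id = side$exam_id,
            sequence_type = side$sequence_type, class = "fused_volume")
}
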