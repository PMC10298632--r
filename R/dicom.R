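# Minimal DICOM Part 10 codec (explicit VR little endian) and the MRI series
# container. The codec supports exactly the dialect this package writes —
# single-frame monochrome MR images, 16-bit unsigned pixels, RescaleSlope 1 /
# RescaleIntercept 0 by default — plus enough generality to re-read series
# with arbitrary rescale values and to skip unknown elements.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_MR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.4"
DICOM_IMPLEMENTATION_UID <- "2.25.834772083571"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Construct an MRI series
#'
#' The fundamental slice-stack container: an `s x h x w` array of pixel
#' intensities, slices ordered by acquisition position (InstanceNumber),
#' tagged with the exam it belongs to and its sequence type.
#'
#' @param pixels Numeric array of dimension `c(s, h, w)` with `s >= 1`.
#' @param exam_id,sequence_type Identification tags. `sequence_type` must be
#'   one of [SEQUENCE_TYPES] (or `NA` for untagged data).
#' @return An object of class `"mri_series"`.
#' @export
mri_series <- function(pixels, exam_id = NA_character_,
                       sequence_type = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("'pixels' must be a 3-D array of dimension (slices, height, width)",
         call. = FALSE)
  }
  if (dim(pixels)[1] < 1L) stop("a series needs at least one slice", call. = FALSE)
  if (!is.na(sequence_type)) {
    sequence_type <- match.arg(sequence_type, SEQUENCE_TYPES)
  }
  structure(list(exam_id = exam_id, sequence_type = sequence_type,
                 pixels = pixels),
            class = "mri_series")
}

#' @export
print.mri_series <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("MRI series %s / %s: %d slices of %dx%d, intensity range [%g, %g]\n",
              x$exam_id, x$sequence_type, d[1], d[2], d[3],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.mri_series <- function(x) dim(x$pixels)

# Deterministic UID derived from a string: two independent polynomial hashes
# under the 2.25 (UUID-derived) root. Not globally unique, but stable and
# collision-free at phantom-cohort scale.
uid_from_string <- function(s) {
  chars <- utf8ToInt(s)
  h1 <- 7; h2 <- 13
  for (c in chars) {
    h1 <- (h1 * 131 + c) %% 999999937
    h2 <- (h2 * 137 + c) %% 999999893
  }
  sprintf("2.25.%d%d", h1, h2)
}

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# Encode one data element (explicit VR little endian).
dicom_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(paste(value, collapse = "\\"))
    if (length(v) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      v <- c(v, pad)
    }
  } else {
    v <- value  # already raw
  }
  hdr <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), raw_u32(length(v)), v)
  } else {
    if (length(v) > 65535L) stop("value too long for short VR", call. = FALSE)
    c(hdr, raw_u16(length(v)), v)
  }
}

# Pixel matrix (h x w, integers in [0, 65535]) -> row-major uint16 LE bytes.
encode_pixels_u16 <- function(m) {
  v <- as.integer(round(t(m)))  # DICOM stores rows consecutively
  if (any(v < 0L | v > 65535L)) {
    stop("pixel values outside the unsigned 16-bit range", call. = FALSE)
  }
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, raw(), size = 2, endian = "little")
}

# Write one slice as a DICOM Part 10 file.
dicom_write_slice <- function(path, pixels, meta) {
  ds <- c(
    dicom_element(0x0008, 0x0016, "UI", DICOM_MR_SOP_CLASS),
    dicom_element(0x0008, 0x0018, "UI", meta$sop_instance_uid),
    dicom_element(0x0008, 0x0060, "CS", "MR"),
    dicom_element(0x0008, 0x103E, "LO", meta$series_description),
    dicom_element(0x0010, 0x0010, "PN", meta$patient_id),
    dicom_element(0x0010, 0x0020, "LO", meta$patient_id),
    dicom_element(0x0020, 0x000D, "UI", meta$study_uid),
    dicom_element(0x0020, 0x000E, "UI", meta$series_uid),
    dicom_element(0x0020, 0x0013, "IS", as.character(meta$instance_number)),
    dicom_element(0x0020, 0x0032, "DS",
                  sprintf("0\\0\\%.1f", 4.0 * meta$instance_number)),
    dicom_element(0x0028, 0x0002, "US", raw_u16(1L)),
    dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", raw_u16(nrow(pixels))),
    dicom_element(0x0028, 0x0011, "US", raw_u16(ncol(pixels))),
    dicom_element(0x0028, 0x0100, "US", raw_u16(16L)),
    dicom_element(0x0028, 0x0101, "US", raw_u16(16L)),
    dicom_element(0x0028, 0x0102, "US", raw_u16(15L)),
    dicom_element(0x0028, 0x0103, "US", raw_u16(0L)),
    dicom_element(0x0028, 0x1052, "DS", "0"),
    dicom_element(0x0028, 0x1053, "DS", "1"),
    dicom_element(0x7FE0, 0x0010, "OW", encode_pixels_u16(pixels))
  )
  meta_elems <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dicom_element(0x0002, 0x0002, "UI", DICOM_MR_SOP_CLASS),
    dicom_element(0x0002, 0x0003, "UI", meta$sop_instance_uid),
    dicom_element(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
    dicom_element(0x0002, 0x0012, "UI", DICOM_IMPLEMENTATION_UID)
  )
  out <- c(raw(128), charToRaw("DICM"),
           dicom_element(0x0002, 0x0000, "UL", raw_u32(length(meta_elems))),
           meta_elems, ds)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# Parse one DICOM Part 10 file written in explicit VR little endian.
dicom_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file: ", path, call. = FALSE)
  }
  pos <- 133L
  n <- length(bytes)
  u16at <- function(p) readBin(bytes[p:(p + 1L)], "integer", size = 2,
                               endian = "little", signed = FALSE)
  u32at <- function(p) readBin(bytes[p:(p + 3L)], "integer", size = 4,
                               endian = "little")
  elems <- list()
  while (pos + 7L <= n) {
    group <- u16at(pos); elem <- u16at(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% LONG_VRS) {
        len <- u32at(pos + 8L); vstart <- pos + 12L
      } else {
        len <- u16at(pos + 6L); vstart <- pos + 8L
      }
    } else {
      stop("implicit VR or non-conformant element encountered in ", path,
           call. = FALSE)
    }
    if (len < 0 || vstart + len - 1L > n) {
      stop("truncated DICOM element in ", path, call. = FALSE)
    }
    value <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    elems[[sprintf("%04X,%04X", group, elem)]] <- list(vr = vr, value = value)
    pos <- vstart + len
  }
  get_str <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NA_character_)
    v <- e$value[e$value != as.raw(0)]  # strip UI null padding
    trimws(rawToChar(v))
  }
  get_us <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NA_integer_)
    readBin(e$value[1:2], "integer", size = 2, endian = "little", signed = FALSE)
  }
  ts <- get_str("0002,0010")
  if (!is.na(ts) && ts != DICOM_TS_EXPLICIT_LE) {
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  }
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  bits <- get_us("0028,0100")
  if (is.na(bits) || bits != 16L) {
    stop("only 16-bit pixel data is supported", call. = FALSE)
  }
  slope <- suppressWarnings(as.numeric(get_str("0028,1053")))
  intercept <- suppressWarnings(as.numeric(get_str("0028,1052")))
  if (is.na(slope)) slope <- 1
  if (is.na(intercept)) intercept <- 0
  pe <- elems[["7FE0,0010"]]
  if (is.null(pe)) stop("no pixel data in ", path, call. = FALSE)
  v <- readBin(pe$value, "integer", n = length(pe$value) / 2L, size = 2,
               endian = "little", signed = FALSE)
  if (length(v) != rows * cols) {
    stop("pixel data length does not match Rows x Columns in ", path,
         call. = FALSE)
  }
  pixels <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE) * slope + intercept
  ipp <- get_str("0020,0032")
  zpos <- if (!is.na(ipp)) {
    suppressWarnings(as.numeric(strsplit(ipp, "\\\\")[[1]][3]))
  } else NA_real_
  list(pixels = pixels,
       instance_number = suppressWarnings(as.integer(get_str("0020,0013"))),
       series_uid = get_str("0020,000E"),
       series_description = get_str("0008,103E"),
       patient_id = get_str("0010,0020"),
       z_position = zpos)
}

#' Write one phantom exam as DICOM files
#'
#' Writes one Part 10 file per slice per sequence under
#' `dir/<exam_id>/<sequence_type>/slice_###.dcm`, with monotone
#' InstanceNumber and one SeriesInstanceUID per sequence. Files round-trip
#' through [read_dicom_series()] to pixel-identical arrays.
#'
#' @param exam One element of a `"phantom_cohort"`'s `exams` list.
#' @param dir Output directory (created if needed).
#' @param patient_id Patient identifier recorded in the files.
#' @return Invisibly, the character vector of written file paths.
#' @export
write_dicom_exam <- function(exam, dir, patient_id = exam$exam_id) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir, call. = FALSE)
  }
  study_uid <- uid_from_string(paste0("study/", exam$exam_id))
  paths <- character(0)
  for (sq in names(exam$series)) {
    sdir <- file.path(dir, exam$exam_id, sq)
    if (!dir.exists(sdir) && !dir.create(sdir, recursive = TRUE)) {
      stop("cannot create directory: ", sdir, call. = FALSE)
    }
    series_uid <- uid_from_string(paste0("series/", exam$exam_id, "/", sq))
    px <- exam$series[[sq]]$pixels
    for (k in seq_len(dim(px)[1])) {
      path <- file.path(sdir, sprintf("slice_%03d.dcm", k))
      dicom_write_slice(path, px[k, , ], list(
        sop_instance_uid = uid_from_string(
          paste0("sop/", exam$exam_id, "/", sq, "/", k)),
        series_uid = series_uid, study_uid = study_uid,
        series_description = sq, patient_id = patient_id,
        instance_number = k))
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Write a whole phantom cohort as a DICOM tree plus manifest
#'
#' @param cohort A `"phantom_cohort"`.
#' @param dir Output root directory.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return Invisibly, the manifest (with series paths relative to `dir`);
#'   also saved as `dir/manifest.csv`.
#' @export
write_dicom_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty (use overwrite = TRUE): ",
         dir, call. = FALSE)
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir, call. = FALSE)
  }
  manifest <- cohort$manifest
  for (ex in cohort$exams) {
    pid <- manifest$patient_id[manifest$exam_id == ex$exam_id]
    write_dicom_exam(ex, dir, patient_id = pid)
    for (sq in names(ex$series)) {
      manifest[[sq]][manifest$exam_id == ex$exam_id] <-
        file.path(ex$exam_id, sq)
    }
  }
  manifest <- label_manifest(manifest)
  save_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a DICOM series directory into an MRI series
#'
#' Reads every `.dcm` file in `path`, checks that all belong to one series
#' (single SeriesInstanceUID) with consistent slice shapes, orders slices by
#' InstanceNumber (falling back to the ImagePositionPatient normal-axis
#' coordinate when InstanceNumber is absent), and applies
#' RescaleSlope/RescaleIntercept.
#'
#' @param path Directory containing the DICOM files of one series.
#' @param exam_id,sequence_type Optional tags; when omitted, the sequence type
#'   is taken from the SeriesDescription tag if it matches a known type.
#' @return An [mri_series()].
#' @export
read_dicom_series <- function(path, exam_id = NA_character_,
                              sequence_type = NA_character_) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) {
    stop("no DICOM files found in ", path, call. = FALSE)
  }
  slices <- lapply(files, dicom_read_file)
  uids <- unique(vapply(slices, `[[`, "", "series_uid"))
  if (length(uids) != 1L) {
    stop("directory mixes ", length(uids), " SeriesInstanceUIDs: ", path,
         call. = FALSE)
  }
  shapes <- vapply(slices, function(s) paste(dim(s$pixels), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent slice shapes in ", path, call. = FALSE)
  }
  inst <- vapply(slices, function(s) as.numeric(s$instance_number %||% NA), 0)
  if (anyNA(inst)) {
    inst <- vapply(slices, function(s) s$z_position %||% NA_real_, 0)
    if (anyNA(inst)) {
      stop("slices carry neither InstanceNumber nor ImagePositionPatient",
           call. = FALSE)
    }
  }
  ord <- order(inst)
  slices <- slices[ord]
  h <- nrow(slices[[1]]$pixels); w <- ncol(slices[[1]]$pixels)
  px <- array(0, c(length(slices), h, w))
  for (k in seq_along(slices)) px[k, , ] <- slices[[k]]$pixels
  if (is.na(sequence_type)) {
    sd <- slices[[1]]$series_description
    if (!is.na(sd) && sd %in% SEQUENCE_TYPES) sequence_type <- sd
  }
  if (is.na(exam_id)) exam_id <- slices[[1]]$patient_id
  mri_series(px, exam_id = exam_id, sequence_type = sequence_type)
}

#' Resize every slice of a series to a square spatial size
#'
#' Bilinear resampling (via EBImage); the slice count is unchanged. Resizing
#' to the input size is an exact identity.
#'
#' @param series An [mri_series()] with `h, w >= 2`.
#' @param size Target side length in pixels (default 224, the network's input
#'   size).
#' @return An [mri_series()] of dimension `s x size x size`.
#' @export
resize_series <- function(series, size = 224L) {
  stopifnot(inherits(series, "mri_series"))
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("'size' must be a positive integer", call. = FALSE)
  d <- dim(series$pixels)
  if (d[2] < 2L || d[3] < 2L) stop("slices must be at least 2x2", call. = FALSE)
  if (d[2] == size && d[3] == size) return(series)
  stack <- aperm(series$pixels, c(2, 3, 1))           # h x w x s
  res <- EBImage::resize(stack, w = size, h = size, filter = "bilinear")
  out <- aperm(array(res, c(size, size, d[1])), c(3, 1, 2))
  mri_series(out, exam_id = series$exam_id, sequence_type = series$sequence_type)
}
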