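#' A single calibrated B-scan
#'
#' Wraps one grayscale cross-sectional OCT image. Pixels are stored as a
#' numeric matrix (rows = axial/depth, columns = lateral) with intensities
#' in \[0, 255\].
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @param index Position of the B-scan within its series (0-based, 0-60 for
#'   the default 61-scan cube).
#' @param calibration An [oct_calibration()] object.
#' @return An object of class `"bscan"`.
#' @export
bscan <- function(pixels, index = 0L, calibration = default_calibration()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must have positive dimensions")
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]")
  if (!is_calibration(calibration))
    stop("'calibration' must be an oct_calibration object")
  structure(list(pixels = pixels, index = as.integer(index),
                 calibration = calibration),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("B-scan #%d: %d x %d px, %.3f um^2/px\n", x$index,
              nrow(x$pixels), ncol(x$pixels),
              x$calibration$pixel_area_um2))
  invisible(x)
}

.SIDES  <- c("RE", "LE")
.GROUPS <- c("MEPI", "Ms", "control")
.SEXES  <- c("male", "female")
.WEEKS  <- c(0L, 2L, 4L, 6L, 8L, 12L, 18L, 24L)

#' Per-eye OCT scan series
#'
#' An ordered collection of B-scans from one eye at one follow-up week,
#' with the study metadata attached: animal id, eye side (RE = intervened
#' right eye, LE = left eye), group (MEPI = episcleral-vein sclerosis
#' model, Ms = intracameral microsphere model, control), sex and week.
#'
#' @param bscans List of [bscan()] objects sharing dimensions and
#'   calibration.
#' @param animal_id Character animal identifier.
#' @param side `"RE"` or `"LE"`.
#' @param group `"MEPI"`, `"Ms"` or `"control"`.
#' @param sex `"male"` or `"female"`.
#' @param week Follow-up week, one of 0, 2, 4, 6, 8, 12, 18, 24.
#' @return An object of class `"eye_scan_series"`.
#' @export
eye_scan_series <- function(bscans, animal_id = "A0", side = "RE",
                            group = "control", sex = "female", week = 0L) {
  side <- match.arg(side, .SIDES)
  group <- match.arg(group, .GROUPS)
  sex <- match.arg(sex, .SEXES)
  week <- as.integer(week)
  if (!week %in% .WEEKS)
    stop("'week' must be one of ", paste(.WEEKS, collapse = ", "))
  if (!is.list(bscans) || length(bscans) < 1L ||
      !all(vapply(bscans, inherits, logical(1), "bscan")))
    stop("'bscans' must be a non-empty list of bscan objects")
  dims <- vapply(bscans, function(b) dim(b$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all B-scans in a series must share identical dimensions")
  areas <- vapply(bscans, function(b) b$calibration$pixel_area_um2, numeric(1))
  if (any(abs(areas - areas[1]) > 1e-12))
    stop("all B-scans in a series must share the same calibration")
  structure(list(animal_id = as.character(animal_id), side = side,
                 group = group, sex = sex, week = week, bscans = bscans),
            class = "eye_scan_series")
}

#' @export
print.eye_scan_series <- function(x, ...) {
  cat(sprintf("Eye scan series: animal %s %s, group %s, %s, week %d; %d b-scans of %d x %d px\n",
              x$animal_id, x$side, x$group, x$sex, x$week,
              length(x$bscans), nrow(x$bscans[[1]]$pixels),
              ncol(x$bscans[[1]]$pixels)))
  invisible(x)
}

#' @export
length.eye_scan_series <- function(x) length(x$bscans)

#' Convert an RGB frame to grayscale
#'
#' Applies the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114), the
#' usual convention for video-exported frames, rounds to the nearest
#' integer and clips to \[0, 255\]. Already-gray input (a plain matrix, or
#' a single-channel array) is passed through unchanged, so the conversion
#' is idempotent.
#'
#' @param frame Numeric matrix (already gray) or h x w x 3 array with
#'   channel values in \[0, 255\].
#' @return Numeric matrix of gray intensities in \[0, 255\].
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (!is.array(frame) || length(dim(frame)) != 3L)
    stop("'frame' must be a matrix or a 3-D array")
  nc <- dim(frame)[3]
  if (nc == 1L) return(frame[, , 1])
  if (nc != 3L)
    stop("RGB frame must have exactly 3 channels, got ", nc)
  if (min(frame) < 0 || max(frame) > 255)
    stop("channel values must lie in [0, 255]")
  g <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  pmin(pmax(round(g), 0), 255)
}

# ---- minimal uncompressed 8-bit RIFF/AVI container ----
# Only the palettized 8-bit DIB layout is supported: it is lossless, widely
# readable, and sufficient for grayscale B-scan stacks.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.fourcc <- function(s) charToRaw(s)

#' Write a grayscale image stack as an uncompressed AVI video
#'
#' Writes frames as 8-bit palettized device-independent bitmaps inside a
#' standard RIFF/AVI container (codec-free, lossless), one video stream,
#' with an `idx1` index. Pixels round-trip exactly through [read_avi()].
#'
#' @param frames List of numeric matrices with intensities in \[0, 255\]
#'   (rounded to integers on write), all of identical dimensions.
#' @param path Output file path.
#' @param fps Nominal frame rate (metadata only).
#' @return `path`, invisibly.
#' @export
write_avi <- function(frames, path, fps = 25) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions")
  h <- dims[1, 1]; w <- dims[2, 1]
  stride <- 4L * ((w + 3L) %/% 4L)
  frame_bytes <- stride * h
  n <- length(frames)

  # grayscale palette: 256 RGBQUADs (b, g, r, reserved)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
  bmih <- c(.u32(40L), .u32(w), .u32(h), .u16(1L), .u16(8L), .u32(0L),
            .u32(frame_bytes), .u32(0L), .u32(0L), .u32(256L), .u32(0L))
  strf <- c(.fourcc("strf"), .u32(40L + 1024L), bmih, pal)
  strh <- c(.fourcc("strh"), .u32(56L), .fourcc("vids"), .fourcc("DIB "),
            .u32(0L), .u16(0L), .u16(0L), .u32(0L), .u32(1L),
            .u32(as.integer(fps)), .u32(0L), .u32(n), .u32(frame_bytes),
            .u32(-1L), .u32(0L), .u16(0L), .u16(0L), .u16(w), .u16(h))
  strl_body <- c(.fourcc("strl"), strh, strf)
  strl <- c(.fourcc("LIST"), .u32(length(strl_body)), strl_body)
  avih <- c(.fourcc("avih"), .u32(56L),
            .u32(as.integer(round(1e6 / fps))), .u32(frame_bytes * fps),
            .u32(0L), .u32(16L), .u32(n), .u32(0L), .u32(1L),
            .u32(frame_bytes), .u32(w), .u32(h),
            .u32(0L), .u32(0L), .u32(0L), .u32(0L))
  hdrl_body <- c(.fourcc("hdrl"), avih, strl)
  hdrl <- c(.fourcc("LIST"), .u32(length(hdrl_body)), hdrl_body)

  enc_frame <- function(px) {
    m <- matrix(0L, nrow = stride, ncol = h)
    m[seq_len(w), ] <- t(pmin(pmax(round(px), 0), 255)[h:1, , drop = FALSE])
    as.raw(m)
  }
  chunks <- lapply(frames, function(px)
    c(.fourcc("00db"), .u32(frame_bytes), enc_frame(px)))
  movi_body <- c(list(.fourcc("movi")), chunks)
  movi_body <- do.call(c, movi_body)
  movi <- c(.fourcc("LIST"), .u32(length(movi_body)), movi_body)

  # idx1 offsets are measured from the 'movi' fourcc
  offs <- 4L + (seq_len(n) - 1L) * (8L + frame_bytes)
  idx_entries <- do.call(c, lapply(offs, function(o)
    c(.fourcc("00db"), .u32(16L), .u32(o), .u32(frame_bytes))))
  idx1 <- c(.fourcc("idx1"), .u32(length(idx_entries)), idx_entries)

  body <- c(.fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(.fourcc("RIFF"), .u32(length(body)), body), con)
  invisible(path)
}

.read_u32 <- function(raw, off) {
  readBin(raw[off + 1:4], "integer", size = 4, endian = "little")
}
.read_u16 <- function(raw, off) {
  readBin(raw[off + 1:2], "integer", size = 2, signed = FALSE,
          endian = "little")
}
.read_cc <- function(raw, off) rawToChar(raw[off + 1:4])

#' Read an uncompressed AVI video as a grayscale image stack
#'
#' Parses the RIFF/AVI container written by [write_avi()] (or any other
#' writer producing uncompressed 8-bit palettized or 24-bit RGB DIB
#' frames). RGB frames are converted with [to_grayscale()].
#'
#' @param path AVI file path.
#' @return List of numeric matrices, one per frame, in frame order.
#' @export
read_avi <- function(path) {
  if (!file.exists(path)) stop("cannot read AVI: ", path)
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  if (sz < 12 || .read_cc(raw, 0) != "RIFF" || .read_cc(raw, 8) != "AVI ")
    stop("not a RIFF/AVI file: ", path)

  width <- height <- bitcount <- NA_integer_
  frames <- list()

  walk <- function(off, end) {
    while (off + 8 <= end) {
      cc <- .read_cc(raw, off)
      len <- .read_u32(raw, off + 4)
      body <- off + 8
      if (cc == "LIST") {
        walk(body + 4, body + len)
      } else if (cc == "strf" && is.na(width)) {
        width <<- .read_u32(raw, body + 4)
        height <<- .read_u32(raw, body + 8)
        bitcount <<- .read_u16(raw, body + 14)
        if (.read_u32(raw, body + 16) != 0L)
          stop("compressed AVI streams are not supported")
      } else if (cc %in% c("00db", "00dc") && len > 0) {
        frames[[length(frames) + 1L]] <<- raw[body + seq_len(len)]
      }
      off <- body + len + (len %% 2L)  # chunks are word-aligned
    }
  }
  walk(12, sz)

  if (is.na(width) || is.na(bitcount))
    stop("no video stream format found in ", path)
  if (!bitcount %in% c(8L, 24L))
    stop("only 8-bit and 24-bit uncompressed AVI frames are supported")
  if (length(frames) == 0L) stop("AVI contains no frames: ", path)

  bpp <- bitcount %/% 8L
  stride <- 4L * ((width * bpp + 3L) %/% 4L)
  lapply(frames, function(bytes) {
    if (length(bytes) < stride * height)
      stop("truncated AVI frame")
    m <- matrix(as.integer(bytes[seq_len(stride * height)]), nrow = stride)
    if (bpp == 1L) {
      t(m[seq_len(width), height:1, drop = FALSE])
    } else {
      # bottom-up rows of b, g, r triples
      b <- t(m[seq(1L, by = 3L, length.out = width), height:1, drop = FALSE])
      g <- t(m[seq(2L, by = 3L, length.out = width), height:1, drop = FALSE])
      r <- t(m[seq(3L, by = 3L, length.out = width), height:1, drop = FALSE])
      to_grayscale(array(c(r, g, b), dim = c(height, width, 3L)))
    }
  })
}

.read_frame_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png = png::readPNG(f),
    tif = ,
    tiff = tiff::readTIFF(f),
    stop("unsupported frame format: ", f))
  # png/tiff readers return values in [0, 1]
  if (length(dim(img)) == 3L) img <- to_grayscale(img * 255) else
    img <- round(img * 255)
  img
}

#' Read a per-eye OCT B-scan series
#'
#' Reads an AVI video or a directory of numbered PNG/TIFF frames into an
#' [eye_scan_series()]. RGB frames are grayscale-converted; frames are
#' taken in file/frame order, which defines the B-scan index.
#'
#' @param path AVI file, or directory of PNG/TIFF frames named with
#'   zero-padded indices.
#' @param animal_id,side,group,sex,week Eye metadata; see
#'   [eye_scan_series()].
#' @param calibration An [oct_calibration()] for every frame.
#' @return An `"eye_scan_series"` object.
#' @export
read_series <- function(path, animal_id = "A0", side = "RE",
                        group = "control", sex = "female", week = 0L,
                        calibration = default_calibration()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no PNG/TIFF frames found in ", path)
    frames <- lapply(files, .read_frame_file)
  } else if (file.exists(path)) {
    frames <- read_avi(path)
  } else {
    stop("cannot read series: ", path)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have inconsistent sizes in ", path)
  bscans <- lapply(seq_along(frames), function(i)
    bscan(frames[[i]], index = i - 1L, calibration = calibration))
  eye_scan_series(bscans, animal_id = animal_id, side = side, group = group,
                  sex = sex, week = week)
}

.OPACITY_COLS <- c("animal_id", "side", "group", "sex", "week",
                   "bscan_index", "label", "n_pixels", "area_um2",
                   "mean_intensity", "eccentricity", "orientation_deg",
                   "size_class")

#' Write the per-opacity table as CSV
#'
#' One row per detected opacity, stable column order: animal_id, side,
#' group, sex, week, bscan_index, label, n_pixels, area_um2,
#' mean_intensity, eccentricity, orientation_deg, size_class.
#'
#' @param opacities Data frame of opacity records (extra columns dropped;
#'   missing metadata columns filled with NA).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_opacity_table <- function(opacities, path) {
  df <- as.data.frame(opacities)
  for (col in .OPACITY_COLS) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[, .OPACITY_COLS, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-eye summary rows as CSV
#'
#' @param summaries Data frame of per-eye summaries (one row per
#'   eye x week), e.g. rows from [summarize_eye()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}
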