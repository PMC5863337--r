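# File interchange: baseline multi-page TIFF (8-bit grayscale, uncompressed),
# JSON sidecars for calibration metadata, CSV for traces and the ECG.
# The TIFF codec is intentionally minimal -- it covers the package's own
# artifacts (little-endian, compression 1, one sample per pixel) and refuses
# anything else rather than guessing.

TIFF_SHORT <- 3L
TIFF_LONG <- 4L

#' Write a grayscale image stack as multi-page TIFF
#'
#' Baseline TIFF 6.0: little-endian, 8 bits per sample, no compression, one
#' strip per page. Intensities are rounded and clamped to `[0, 255]`.
#'
#' @param frames an `H x W` matrix or `H x W x T` array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path) {
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  d <- dim(frames)
  h <- d[1L]; w <- d[2L]; n <- d[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header; first IFD sits right after all pixel data
  writeBin(charToRaw("II"), con)
  wr16(42L)
  pixel_bytes <- h * w
  first_ifd <- 8L + n * pixel_bytes
  wr32(first_ifd)
  for (i in seq_len(n)) {
    # TIFF strips are row-major; R matrices are column-major
    px <- as.integer(round(clamp255(frames[, , i])))
    writeBin(as.raw(t(matrix(px, h, w))), con)
  }
  ifd_size <- 2L + 9L * 12L + 4L
  entry <- function(tag, type, value) {
    wr16(tag); wr16(type); wr32(1L)
    if (type == TIFF_SHORT) { wr16(value); wr16(0L) } else wr32(value)
  }
  for (i in seq_len(n)) {
    wr16(9L)                                       # entry count
    entry(256L, TIFF_LONG, w)                      # ImageWidth
    entry(257L, TIFF_LONG, h)                      # ImageLength
    entry(258L, TIFF_SHORT, 8L)                    # BitsPerSample
    entry(259L, TIFF_SHORT, 1L)                    # Compression: none
    entry(262L, TIFF_SHORT, 1L)                    # Photometric: BlackIsZero
    entry(273L, TIFF_LONG, 8L + (i - 1L) * pixel_bytes)  # StripOffsets
    entry(277L, TIFF_SHORT, 1L)                    # SamplesPerPixel
    entry(278L, TIFF_LONG, h)                      # RowsPerStrip
    entry(279L, TIFF_LONG, pixel_bytes)            # StripByteCounts
    wr32(if (i < n) first_ifd + i * ifd_size else 0L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Accepts little-endian baseline TIFF with 8 bits per sample, one sample per
#' pixel and no compression (possibly several strips per page), i.e. the
#' format produced by [write_tiff_stack()].
#'
#' @param path file path.
#' @return numeric array `H x W x T`.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(p) as.integer(raw[p + 1L]) + 256L * as.integer(raw[p + 2L])
  u32 <- function(p) as.numeric(as.integer(raw[p + 1L]) +
    256 * as.integer(raw[p + 2L]) + 65536 * as.integer(raw[p + 3L]) +
    16777216 * as.integer(raw[p + 4L]))
  if (rawToChar(raw[1:2]) != "II")
    stop_musecho("only little-endian TIFF is supported", "musecho_tiff_error")
  if (u16(2L) != 42L) stop_musecho("not a TIFF file", "musecho_tiff_error")
  ifd <- u32(4L)
  pages <- list()
  while (ifd != 0) {
    n_ent <- u16(ifd)
    tags <- list()
    for (k in seq_len(n_ent)) {
      base <- ifd + 2L + (k - 1L) * 12L
      tag <- u16(base); type <- u16(base + 2L); count <- u32(base + 4L)
      unit <- if (type == TIFF_SHORT) 2L else if (type == TIFF_LONG) 4L else NA_integer_
      if (is.na(unit)) { tags[[as.character(tag)]] <- NULL; next }
      vals <- numeric(count)
      vpos <- if (unit * count <= 4) base + 8L else u32(base + 8L)
      for (j in seq_len(count)) {
        vals[j] <- if (unit == 2L) u16(vpos + (j - 1L) * 2L) else u32(vpos + (j - 1L) * 4L)
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    if ((g(259L, 1)[1L]) != 1)
      stop_musecho("compressed TIFF is not supported", "musecho_tiff_error")
    if ((g(258L, 8)[1L]) != 8 || (g(277L, 1)[1L]) != 1)
      stop_musecho("only 8-bit single-sample TIFF is supported", "musecho_tiff_error")
    w <- g(256L)[1L]; h <- g(257L)[1L]
    offs <- g(273L); cnts <- g(279L, rep(h * w, length(offs)))
    bytes <- raw(0)
    for (j in seq_along(offs)) {
      bytes <- c(bytes, raw[(offs[j] + 1L):(offs[j] + cnts[j])])
    }
    pages[[length(pages) + 1L]] <- t(matrix(as.integer(bytes), w, h))
    ifd <- u32(ifd + 2L + n_ent * 12L)
  }
  arr <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' Write a cine loop as TIFF + JSON sidecar (+ ECG CSV)
#'
#' @param loop a [cine_loop()].
#' @param dir output directory (created if missing).
#' @param stem file name stem; writes `<stem>.tif`, `<stem>.json` and, when an
#'   ECG is attached, `<stem>_ecg.csv`.
#' @param truth optional list of ground-truth parameters recorded in the
#'   sidecar (phantom provenance).
#' @return the sidecar path, invisibly.
#' @export
write_cine_loop <- function(loop, dir, stem, truth = NULL) {
  stopifnot(inherits(loop, "cine_loop"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tiff_stack(loop$frames, file.path(dir, paste0(stem, ".tif")))
  meta <- list(format = "musecho-cine", pixel_spacing = loop$pixel_spacing,
               frame_rate = loop$frame_rate, view = loop$view,
               n_frames = dim(loop$frames)[3L])
  if (!is.null(loop$ecg)) {
    meta$ecg_fs <- loop$ecg$fs
    utils::write.csv(data.frame(sample = seq_along(loop$ecg$signal) - 1L,
                                ecg = loop$ecg$signal),
                     file.path(dir, paste0(stem, "_ecg.csv")), row.names = FALSE)
  }
  if (!is.null(truth)) meta$truth <- truth
  sidecar <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a cine loop written by [write_cine_loop()]
#'
#' @inheritParams write_cine_loop
#' @return a [cine_loop()]; any recorded truth is attached as attribute
#'   `"truth"`.
#' @export
read_cine_loop <- function(dir, stem) {
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  frames <- read_tiff_stack(file.path(dir, paste0(stem, ".tif")))
  ecg <- NULL
  ecg_path <- file.path(dir, paste0(stem, "_ecg.csv"))
  if (!is.null(meta$ecg_fs) && file.exists(ecg_path)) {
    ecg <- list(signal = utils::read.csv(ecg_path)$ecg, fs = meta$ecg_fs)
  }
  loop <- cine_loop(frames, meta$pixel_spacing, meta$frame_rate, ecg, meta$view)
  attr(loop, "truth") <- meta$truth
  loop
}

#' Write a spectrogram as TIFF + JSON sidecar
#'
#' Power is scaled to 8-bit for the TIFF page; the scale factor and both axes
#' live in the sidecar so the round trip recovers power up to quantisation.
#'
#' @param spec a [spectrogram()].
#' @inheritParams write_cine_loop
#' @return the sidecar path, invisibly.
#' @export
write_spectrogram <- function(spec, dir, stem, truth = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pmax_ <- max(spec$power, .Machine$double.eps)
  write_tiff_stack(spec$power / pmax_ * 255, file.path(dir, paste0(stem, ".tif")))
  meta <- list(format = "musecho-spectrogram", power_max = pmax_,
               time_axis = spec$time_axis, velocity_axis = spec$velocity_axis,
               prf = spec$prf, angle_correction = spec$angle_correction)
  if (!is.null(truth)) meta$truth <- truth
  sidecar <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a spectrogram written by [write_spectrogram()]
#'
#' @inheritParams read_cine_loop
#' @return a [spectrogram()] with any recorded truth attached as attribute
#'   `"truth"`.
#' @export
read_spectrogram <- function(dir, stem) {
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  img <- read_tiff_stack(file.path(dir, paste0(stem, ".tif")))[, , 1L]
  spec <- spectrogram(img / 255 * meta$power_max, meta$time_axis,
                      meta$velocity_axis, meta$prf, meta$angle_correction)
  attr(spec, "truth") <- meta$truth
  spec
}

#' Write / read a diameter or velocity trace as CSV
#'
#' @param trace a [diameter_trace()] or [velocity_trace()].
#' @param path CSV path.
#' @return `path` invisibly (writers); the reconstructed trace (readers).
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "diameter_trace")) {
    utils::write.csv(data.frame(time_s = trace$time,
                                diameter_mm = trace$diameter_mm,
                                quality = trace$quality),
                     path, row.names = FALSE)
  } else if (inherits(trace, "velocity_trace")) {
    utils::write.csv(data.frame(time_s = trace$time,
                                velocity_mm_s = trace$velocity),
                     path, row.names = FALSE)
  } else stop_musecho("unsupported trace class", "musecho_io_error")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_diameter_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  diameter_trace(d$time_s, d$diameter_mm, d$quality %||% rep(1, nrow(d)))
}

#' @rdname write_trace_csv
#' @export
read_velocity_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  velocity_trace(d$time_s, d$velocity_mm_s)
}

#' Write / read an LV contour trace as CSV
#'
#' Long format: one row per contour point per frame with columns `frame`,
#' `time_s`, `set` (`endo`/`epi`), `point`, `x_mm`, `y_mm`, `laxis_mm`
#' (repeated per frame, `NA` when absent) and `view`.
#'
#' @param trace an [lv_trace()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the reconstructed [lv_trace()]
#'   (reader).
#' @export
write_lv_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "lv_trace"))
  rows <- list()
  for (i in seq_along(trace$time)) {
    for (set in c("endo", "epi")) {
      pts <- trace[[set]]
      if (is.null(pts)) next
      p <- pts[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = i, time_s = trace$time[i], set = set,
        point = seq_len(nrow(p)), x_mm = p[, 1L], y_mm = p[, 2L],
        laxis_mm = if (is.null(trace$laxis)) NA_real_ else trace$laxis[i],
        view = trace$view)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lv_trace_csv
#' @export
read_lv_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  frames <- sort(unique(d$frame))
  grab_set <- function(set) {
    if (!any(d$set == set)) return(NULL)
    lapply(frames, function(f) {
      s <- d[d$frame == f & d$set == set, ]
      s <- s[order(s$point), ]
      cbind(s$x_mm, s$y_mm)
    })
  }
  time <- vapply(frames, function(f) d$time_s[d$frame == f][1L], numeric(1))
  laxis <- vapply(frames, function(f) d$laxis_mm[d$frame == f][1L], numeric(1))
  if (all(is.na(laxis))) laxis <- NULL
  lv_trace(time, grab_set("endo"), grab_set("epi"), laxis,
           view = as.character(d$view[1L]))
}
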