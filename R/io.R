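# Minimal baseline TIFF writer (little-endian, uncompressed, one strip per
# frame). Needed because the installed tiff writer only stores values in
# [0, 1]; microscopy photon counts and masks need uint16 / float32 with
# their physical values intact. Reading goes through tiff::readTIFF, which
# handles both sample formats.
write_tiff_raw <- function(frames, path, format = c("float", "uint16")) {
  format <- match.arg(format)
  if (is.matrix(frames)) frames <- list(frames)
  bps <- if (format == "float") 32L else 16L
  sfmt <- if (format == "float") 3L else 1L
  bytes_px <- bps / 8L
  n <- length(frames)
  sizes <- vapply(frames, function(f) length(f) * bytes_px, numeric(1))
  data_off <- 8 + c(0, cumsum(sizes))[seq_len(n)]
  ifd_size <- 2 + 10 * 12 + 4
  ifd_off <- 8 + sum(sizes) + (seq_len(n) - 1) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (f in frames) {
    v <- as.vector(t(f))                     # TIFF is row-major
    if (format == "uint16") {
      if (any(v < 0 | v > 65535 | v != round(v)))
        stop("uint16 TIFF requires integers in [0, 65535]")
      writeBin(as.integer(v), con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    }
  }
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {                        # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    f <- frames[[i]]
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, ncol(f))                   # ImageWidth
    entry(257, 4, nrow(f))                   # ImageLength
    entry(258, 3, bps)                       # BitsPerSample
    entry(259, 3, 1)                         # Compression: none
    entry(262, 3, 1)                         # Photometric: BlackIsZero
    entry(273, 4, data_off[i])               # StripOffsets
    entry(277, 3, 1)                         # SamplesPerPixel
    entry(278, 4, nrow(f))                   # RowsPerStrip
    entry(279, 4, sizes[i])                  # StripByteCounts
    entry(339, 3, sfmt)                      # SampleFormat
    writeBin(as.integer(if (i < n) ifd_off[i + 1] else 0), con,
             size = 4, endian = "little")
  }
  invisible(path)
}

#' Write an image or stack as TIFF
#'
#' Integer-valued images (labelled masks, binaries) are stored as 16-bit
#' unsigned TIFF, everything else as 32-bit float, in both cases with
#' physical values preserved.
#'
#' @param img Matrix or list of matrices (a stack).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  frames <- if (is.matrix(img)) list(img) else img
  frames <- lapply(frames, as_pixels)
  int_ok <- all(vapply(frames, function(f)
    all(f >= 0 & f <= 65535 & f == round(f)), logical(1)))
  write_tiff_raw(frames, path, if (int_ok) "uint16" else "float")
}

#' Read a TIFF image or stack
#'
#' Single frames and stacks, 8/16-bit integer (read losslessly at their
#' original integer values) or 32-bit float.
#'
#' @param path TIFF file.
#' @param role Role assigned to the returned elements. Labelled masks carry
#'   values beyond 0/1, so they are read with a non-binary role and
#'   binarized downstream.
#' @return List of [image_element] objects, one per frame, in frame order.
#' @export
read_image_stack <- function(path, role = "fluorescence") {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  frames <- tryCatch({
    x <- try(tiff::readTIFF(path, all = TRUE, as.is = TRUE), silent = TRUE)
    if (inherits(x, "try-error"))
      x <- tiff::readTIFF(path, all = TRUE)   # float TIFFs reject as.is
    x
  }, error = function(e)
    stop(sprintf("cannot read TIFF %s: %s", path, conditionMessage(e))))
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3L) {
      if (dim(f)[3] == 1L) f <- f[, , 1]
      else stop(sprintf("%s: multi-sample images are not supported", path))
    }
    if (length(dim(f)) != 2L)
      stop(sprintf("%s: expected a 2-D frame", path))
    image_element(matrix(as.numeric(f), nrow(f), ncol(f)), role)
  })
}

normalize_loc_header <- function(nms) {
  x <- tolower(nms)
  x <- gsub("\\[.*\\]", "", x)          # strip unit brackets: "x [nm]"
  x <- gsub("[^a-z0-9]+", "", x)        # strip separators
  x <- sub("nm$", "", x)                # strip unit suffix: "x_nm"
  x[x == ""] <- "col"
  x
}

#' Read an SMLM localization table
#'
#' Delimited text with a header naming at least x and y columns
#' (ThunderSTORM-style dialects understood: `x [nm]`, `x_nm`, `x`;
#' comma/semicolon/tab delimiters sniffed from the header line). Coordinates
#' in nm are converted to px by the pixel size.
#'
#' @param path Localization file.
#' @param pixel_size nm per px (default 80), used for nm input.
#' @param units `"auto"` (nm if the header carries nm units), `"px"` or
#'   `"nm"`.
#' @return A [loc_table] in px.
#' @export
read_localizations <- function(path, pixel_size = 80,
                               units = c("auto", "px", "nm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("localization file not found: %s", path))
  header <- readLines(path, n = 1L)
  seps <- c("," = lengths(regmatches(header, gregexpr(",", header))),
            ";" = lengths(regmatches(header, gregexpr(";", header))),
            "\t" = lengths(regmatches(header, gregexpr("\t", header))))
  sep <- names(seps)[which.max(seps)]
  d <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  raw_names <- names(d)
  names(d) <- normalize_loc_header(raw_names)
  if (!all(c("x", "y") %in% names(d)))
    stop(sprintf("no x/y columns found; headers were: %s",
                 paste(raw_names, collapse = ", ")))
  if (units == "auto")
    units <- if (any(grepl("nm", tolower(raw_names[normalize_loc_header(raw_names)
                                                   %in% c("x", "y")]))))
      "nm" else "px"
  scale <- if (units == "nm") pixel_size else 1
  loc_table(x = d$x / scale, y = d$y / scale,
            frame = if ("frame" %in% names(d)) d$frame else 1L,
            intensity = if ("intensity" %in% names(d)) d$intensity else 1)
}

#' Write a localization table as CSV
#'
#' @param locs A [loc_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  utils::write.table(locs, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML run configuration: paths, pixel size, optimization and analysis
#' options, seed. Referenced input paths are checked at load time.
#'
#' @param path YAML file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$pixel_size) && cfg$pixel_size <= 0)
    stop("pixel_size must be positive")
  for (key in c("mask", "channels", "localizations")) {
    for (p in cfg[[key]])
      if (!file.exists(p))
        stop(sprintf("config references a missing path (%s): %s", key, p))
  }
  structure(cfg, class = c("run_config", class(cfg)))
}
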