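# Image and table I/O.
#
# The package reads and writes plain single-plane grayscale TIFF (8/16-bit,
# uncompressed) with an internal codec, and PNG label maps through the `png`
# package.  Loading never rescales intensities; any standardization happens
# explicitly downstream.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL

read_uint <- function(con, size, endian) {
  v <- readBin(con, "integer", n = 1L, size = size, signed = size >= 4,
               endian = endian)
  if (size == 4 && v < 0) v <- v + 2^32
  if (size < 4 && v < 0) v <- v + 2^(8 * size)
  v
}

# Read one IFD entry's value vector (SHORT or LONG), following offsets.
tiff_entry_values <- function(raw_entry, con, endian) {
  typ <- readBin(raw_entry[3:4], "integer", size = 2, signed = FALSE, endian = endian)
  cnt <- readBin(raw_entry[5:8], "integer", size = 4, endian = endian)
  if (cnt < 0) cnt <- cnt + 2^32
  size <- if (typ >= 1 && typ <= 5) TIFF_TYPE_SIZES[typ] else 1L
  if (!typ %in% c(1L, 3L, 4L)) return(NULL)  # only integer types needed
  total <- size * cnt
  if (total <= 4) {
    raw_val <- raw_entry[9:(8 + total)]
    vals <- readBin(raw_val, "integer", n = cnt, size = size,
                    signed = size >= 4, endian = endian)
    if (size < 4) vals[vals < 0] <- vals[vals < 0] + 2^(8 * size)
  } else {
    off <- readBin(raw_entry[9:12], "integer", size = 4, endian = endian)
    if (off < 0) off <- off + 2^32
    seek(con, off)
    vals <- readBin(con, "integer", n = cnt, size = size,
                    signed = size >= 4, endian = endian)
    if (size < 4) vals[vals < 0] <- vals[vals < 0] + 2^(8 * size)
  }
  vals
}

# Internal: read a single-plane grayscale uncompressed TIFF.
# Returns an integer-valued numeric matrix (rows = image rows).
read_tiff_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4L)
  endian <- if (rawToChar(hdr[1:2]) == "II") "little"
            else if (rawToChar(hdr[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  magic <- readBin(hdr[3:4], "integer", size = 2, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd_off <- read_uint(con, 4, endian)
  seek(con, ifd_off)
  n_entries <- read_uint(con, 2, endian)
  entries <- lapply(seq_len(n_entries), function(i) readBin(con, "raw", 12L))
  next_ifd <- read_uint(con, 4, endian)
  if (!is.na(next_ifd) && next_ifd != 0)
    stop("multi-plane TIFF not supported; expected single-channel image: ", path)
  tags <- vapply(entries, function(e)
    readBin(e[1:2], "integer", size = 2, signed = FALSE, endian = endian), 0L)
  getv <- function(tag, default = NULL) {
    i <- match(tag, tags)
    if (is.na(i)) return(default)
    tiff_entry_values(entries[[i]], con, endian)
  }
  if (!is.na(match(322L, tags))) stop("tiled TIFF not supported: ", path)
  width <- getv(256L); height <- getv(257L)
  if (is.null(width) || is.null(height)) stop("malformed TIFF: ", path)
  bits <- getv(258L, 1L)
  spp <- getv(277L, 1L)
  if (length(bits) > 1 || spp > 1)
    stop("expected single-channel image (got ", spp, " samples/pixel): ", path)
  comp <- getv(259L, 1L)
  if (comp != 1L) stop("compressed TIFF not supported: ", path)
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  offsets <- getv(273L)
  counts <- getv(279L, width * height * bits / 8)
  vals <- integer(0)
  size <- bits / 8
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    n <- counts[min(i, length(counts))] / size
    v <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                 endian = endian)
    vals <- c(vals, v)
  }
  if (length(vals) != width * height) stop("truncated TIFF data: ", path)
  m <- matrix(as.numeric(vals), nrow = height, ncol = width, byrow = TRUE)
  attr(m, "bits") <- as.integer(bits)
  m
}

# Internal: write an integer-valued matrix as uncompressed grayscale TIFF
# (little-endian, single strip).
write_tiff_gray <- function(m, path, bits = 16L) {
  bits <- as.integer(bits)
  stopifnot(bits %in% c(8L, 16L))
  vals <- round(as.vector(t(m)))
  if (any(vals < 0) || any(vals > 2^bits - 1))
    stop("pixel values out of range for ", bits, "-bit TIFF")
  h <- nrow(m); w <- ncol(m)
  size <- bits / 8L
  data_off <- 8L
  nbytes <- as.integer(h * w * size)
  ifd_off <- data_off + nbytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(data_off + nbytes), con, size = 4, endian = "little")
  writeBin(as.integer(vals), con, size = size, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  n_tags <- 9L
  writeBin(n_tags, con, size = 2, endian = "little")
  entry(256L, 4L, 1L, w)            # ImageWidth
  entry(257L, 4L, 1L, h)            # ImageLength
  entry(258L, 3L, 1L, bits)         # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression: none
  entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)     # StripOffsets
  entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
  entry(278L, 4L, 1L, h)            # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)       # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' Construct a single-channel image
#'
#' A `channel_image` wraps a 2-D matrix of nonnegative finite intensities
#' together with the channel tag and the (purely informational) pixel size.
#'
#' @param pixels numeric matrix of intensities, at least 64 x 64.
#' @param channel one of `"actin"`, `"alpha_actinin"`, `"nuclei"`.
#' @param pixel_size_um micrometres per pixel; metadata only, never used in
#'   any computation.
#' @param bits original bit depth if known.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = c("actin", "alpha_actinin", "nuclei"),
                          pixel_size_um = NA_real_, bits = NA_integer_) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("channel image must be at least 64 x 64 pixels")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and nonnegative")
  structure(list(pixels = pixels, channel = channel,
                 pixel_size_um = pixel_size_um, bits = bits),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, range [%g, %g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Load a grayscale channel image
#'
#' Reads a single-plane grayscale TIFF (or grayscale PNG) and returns the
#' intensities as floats in their original range: no rescaling is performed.
#' Multi-channel (RGB) or multi-plane inputs are rejected.
#'
#' @param path file path (.tif/.tiff or .png).
#' @param channel_tag channel name recorded on the image.
#' @param pixel_size_um optional pixel size metadata.
#' @return A [channel_image].
#' @export
load_channel <- function(path, channel_tag, pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- read_tiff_gray(path)
    bits <- attr(m, "bits")
    attr(m, "bits") <- NULL
  } else if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      if (dim(a)[3] > 1) stop("expected single-channel image, got RGB PNG: ", path)
      a <- a[, , 1]
    }
    m <- a * 255  # png package normalizes to [0,1]; 8-bit assumed
    bits <- 8L
  } else stop("unsupported image format: ", ext)
  channel_image(m, channel_tag, pixel_size_um = pixel_size_um, bits = bits)
}

#' Save a channel image as grayscale TIFF
#'
#' @param img a [channel_image] or numeric matrix with integer-valued
#'   intensities in `[0, 2^bits - 1]`.
#' @param path output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
save_channel <- function(img, path, bits = 16L) {
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  write_tiff_gray(m, path, bits = bits)
}

#' Save / load semantic class label maps
#'
#' Class maps hold the codes of [class_codes()] and are serialized as 8-bit
#' grayscale images (TIFF or PNG by file extension).  `load_class_map()`
#' inverts `save_class_map()` pixel for pixel.
#'
#' @param map integer matrix of class codes.
#' @param path file path ending in .tif/.tiff or .png.
#' @return `save_class_map()` returns `path` invisibly; `load_class_map()`
#'   returns the integer matrix of codes.
#' @export
save_class_map <- function(map, path) {
  map <- as.matrix(map)
  codes <- unique(as.vector(map))
  bad <- setdiff(codes, class_codes())
  if (length(bad) || anyNA(codes))
    stop("unknown class code(s): ", paste(bad, collapse = ", "))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(map / 255, path)
  } else {
    write_tiff_gray(map, path, bits = 8L)
  }
  invisible(path)
}

#' @param semantic if `TRUE` (default) validate codes against [class_codes()];
#'   use `FALSE` for instance label maps (e.g. nuclei).
#' @rdname save_class_map
#' @export
load_class_map <- function(path, semantic = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    m <- round(a * 255)
  } else {
    m <- read_tiff_gray(path)
    attr(m, "bits") <- NULL
  }
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  if (semantic && !all(unique(as.vector(m)) %in% class_codes()))
    stop("file contains codes outside the semantic class set")
  m
}

#' Save an instance label map (e.g. nuclei)
#'
#' Instance labels (0 = none) serialized as 8-bit or 16-bit grayscale TIFF
#' depending on the largest label.
#'
#' @param labels integer matrix, values >= 0.
#' @param path output TIFF path.
#' @export
save_label_map <- function(labels, path) {
  bits <- if (max(labels) > 255) 16L else 8L
  write_tiff_gray(as.matrix(labels), path, bits = bits)
}

WELL_SUMMARY_COLUMNS <- c("well", "group", "cell_type", "oop", "director_deg",
                          "angle_to_stretch_deg", "n_vectors", "actin_fraction")

#' Write / read a well summary table
#'
#' One row per well (or field of view) and cell type, comma-separated with a
#' fixed header; floats written at 6 significant digits.
#'
#' @param records data frame carrying at least the columns
#'   `r paste(WELL_SUMMARY_COLUMNS, collapse = ", ")`.
#' @param path output CSV path.
#' @return `write_well_summary()` returns `path` invisibly;
#'   `read_well_summary()` returns the data frame.
#' @export
write_well_summary <- function(records, path) {
  if (nrow(records) > 0) {
    missing <- setdiff(WELL_SUMMARY_COLUMNS, names(records))
    if (length(missing))
      stop("missing summary column(s): ", paste(missing, collapse = ", "))
    records <- records[, WELL_SUMMARY_COLUMNS, drop = FALSE]
    for (col in c("oop", "director_deg", "angle_to_stretch_deg", "actin_fraction"))
      records[[col]] <- signif(records[[col]], 6)
  } else {
    records <- as.data.frame(setNames(
      replicate(length(WELL_SUMMARY_COLUMNS), character(0), simplify = FALSE),
      WELL_SUMMARY_COLUMNS))
  }
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_well_summary
#' @export
read_well_summary <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
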