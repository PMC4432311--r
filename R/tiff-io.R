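#' TIFF input/output for phase maps and masks
#'
#' Phase maps are written as uncompressed little-endian baseline TIFF,
#' grayscale, 32-bit IEEE float samples in radians.  Masks are 8-bit (0/255).
#' The physical pixel size (um/px) and center wavelength (nm) travel in the
#' ImageDescription tag as a JSON object, e.g.
#' `{"pixel_size_um":0.05,"wavelength_nm":552}` — these are the documented
#' metadata keys.  The reader accepts any uncompressed single-plane grayscale
#' TIFF (8/16-bit unsigned or 32-bit float, single or multiple strips).
#'
#' No compression, tiling, palettes or multi-page files: the codec exists
#' because the deployment environment ships no TIFF-capable R package, and it
#' intentionally covers only what the pipeline emits.
#'
#' @name tiff-io
NULL

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L)

.tiff_entry <- function(tag, type, count, value_raw) {
  list(tag = tag, type = type, count = count, value_raw = value_raw)
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

## core writer: `data_raw` is the strip payload, row-major
.write_tiff <- function(path, data_raw, width, height, bits, sample_format,
                        description) {
  desc <- c(charToRaw(description), as.raw(0))  # NUL-terminated ASCII
  data_off <- 8L
  n_data <- length(data_raw)
  desc_off <- data_off + n_data
  if (desc_off %% 2L == 1L) { data_raw <- c(data_raw, as.raw(0)); desc_off <- desc_off + 1L }
  ifd_off <- desc_off + length(desc)
  if (ifd_off %% 2L == 1L) { desc <- c(desc, as.raw(0)); ifd_off <- ifd_off + 1L }

  inline <- function(x, type) {
    v <- if (type == .tiff_types[["SHORT"]]) .u16(x) else .u32(x)
    c(v, raw(4L - length(v)))
  }
  ent <- list(
    .tiff_entry(256L, 4L, 1L, inline(width, 4L)),          # ImageWidth
    .tiff_entry(257L, 4L, 1L, inline(height, 4L)),         # ImageLength
    .tiff_entry(258L, 3L, 1L, inline(bits, 3L)),           # BitsPerSample
    .tiff_entry(259L, 3L, 1L, inline(1L, 3L)),             # Compression: none
    .tiff_entry(262L, 3L, 1L, inline(1L, 3L)),             # Photometric: BlackIsZero
    .tiff_entry(270L, 2L, length(desc), inline(desc_off, 4L)),  # ImageDescription
    .tiff_entry(273L, 4L, 1L, inline(data_off, 4L)),       # StripOffsets
    .tiff_entry(277L, 3L, 1L, inline(1L, 3L)),             # SamplesPerPixel
    .tiff_entry(278L, 4L, 1L, inline(height, 4L)),         # RowsPerStrip
    .tiff_entry(279L, 4L, 1L, inline(n_data, 4L)),         # StripByteCounts
    .tiff_entry(339L, 3L, 1L, inline(sample_format, 3L))   # SampleFormat
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16(42L), .u32(ifd_off)), con)
  writeBin(data_raw, con)
  writeBin(desc, con)
  writeBin(.u16(length(ent)), con)
  for (e in ent)
    writeBin(c(.u16(e$tag), .u16(e$type), .u32(e$count), e$value_raw), con)
  writeBin(.u32(0L), con)  # no next IFD
  invisible(path)
}

#' @describeIn tiff-io Write a [phase_image()] as 32-bit float TIFF.
#' @param img a [phase_image()].
#' @param path file path.
#' @export
write_phase_tiff <- function(img, path) {
  if (!is_phase_image(img)) stop_parameter("`img` must be a phase_image")
  desc <- jsonlite::toJSON(
    list(pixel_size_um = img$pixel_size, wavelength_nm = img$wavelength),
    auto_unbox = TRUE, digits = NA)
  data_raw <- writeBin(as.numeric(t(img$values)), raw(), size = 4,
                       endian = "little")
  .write_tiff(path, data_raw, width = ncol(img$values),
              height = nrow(img$values), bits = 32L, sample_format = 3L,
              description = as.character(desc))
}

#' @describeIn tiff-io Write an [roi_mask()] as 8-bit TIFF (0/255).
#' @param mask an [roi_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  if (!is_roi_mask(mask)) stop_parameter("`mask` must be a roi_mask")
  data_raw <- as.raw(ifelse(as.vector(t(mask$mask)), 255L, 0L))
  .write_tiff(path, data_raw, width = ncol(mask$mask),
              height = nrow(mask$mask), bits = 8L, sample_format = 1L,
              description = "{\"mask\":true}")
}

.read_tiff_raw <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("TIFF file not found: %s", path))
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 8L) stop_io(sprintf("not a TIFF file: %s", path))
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop_io(sprintf("not a TIFF file (bad byte order mark): %s", path))
  ## size-4 reads are signed (R limitation); fine below 2 GiB files
  rd_int <- function(off, size, n = 1L)
    readBin(raw_all[(off + 1L):(off + size * n)], "integer", n = n,
            size = size, signed = size >= 4L, endian = endian)
  if (rd_int(2L, 2L) != 42L) stop_io(sprintf("not a TIFF file: %s", path))
  ifd_off <- rd_int(4L, 4L)
  n_ent <- rd_int(ifd_off, 2L)
  tags <- list()
  for (i in seq_len(n_ent)) {
    e_off <- ifd_off + 2L + (i - 1L) * 12L
    tag <- rd_int(e_off, 2L); type <- rd_int(e_off + 2L, 2L)
    count <- rd_int(e_off + 4L, 4L)
    tsz <- .tiff_type_size[type]
    nbytes <- tsz * count
    val_off <- if (nbytes <= 4L) e_off + 8L else rd_int(e_off + 8L, 4L)
    value <- switch(as.character(type),
      "2" = {
        bytes <- raw_all[(val_off + 1L):(val_off + count)]
        rawToChar(bytes[bytes != as.raw(0)])
      },
      "1" = as.integer(raw_all[(val_off + 1L):(val_off + count)]),
      "3" = rd_int(val_off, 2L, count),
      "4" = rd_int(val_off, 4L, count),
      "5" = rd_int(val_off, 4L, 2L * count),
      NULL)
    tags[[as.character(tag)]] <- value
  }
  list(raw = raw_all, endian = endian, tags = tags)
}

.read_tiff_matrix <- function(path) {
  tf <- .read_tiff_raw(path)
  tg <- tf$tags
  need <- function(tag) tg[[as.character(tag)]] %||%
    stop_io(sprintf("TIFF missing required tag %d: %s", tag, path))
  width <- need(256L); height <- need(257L)
  bits <- tg[["258"]] %||% 1L
  if ((tg[["259"]] %||% 1L) != 1L)
    stop_io(sprintf("compressed TIFF not supported: %s", path))
  if ((tg[["277"]] %||% 1L) != 1L)
    stop_io(sprintf("multi-sample TIFF not supported: %s", path))
  fmt <- tg[["339"]] %||% 1L
  offs <- need(273L); counts <- need(279L)
  payload <- unlist(lapply(seq_along(offs), function(i)
    tf$raw[(offs[i] + 1L):(offs[i] + counts[i])]))
  vals <- if (fmt == 3L && bits == 32L) {
    readBin(payload, "double", n = width * height, size = 4, endian = tf$endian)
  } else if (fmt == 1L && bits == 8L) {
    as.numeric(payload[seq_len(width * height)])
  } else if (fmt == 1L && bits == 16L) {
    as.numeric(readBin(payload, "integer", n = width * height, size = 2,
                       signed = FALSE, endian = tf$endian))
  } else {
    stop_io(sprintf("unsupported TIFF sample layout (bits=%s, format=%s): %s",
                    bits, fmt, path))
  }
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  list(matrix = m, description = tg[["270"]])
}

#' @describeIn tiff-io Read a phase map written by [write_phase_tiff()].
#'   Pixel size / wavelength fall back to the arguments when the file
#'   carries no metadata.
#' @param pixel_size,wavelength fallback metadata for files without the
#'   JSON ImageDescription.
#' @export
read_phase_tiff <- function(path, pixel_size = NULL, wavelength = NULL) {
  r <- .read_tiff_matrix(path)
  meta <- list()
  if (!is.null(r$description)) {
    meta <- tryCatch(jsonlite::fromJSON(r$description),
                     error = function(e) list())
  }
  ps <- meta$pixel_size_um %||% pixel_size
  wl <- meta$wavelength_nm %||% wavelength %||% 552
  if (is.null(ps))
    stop_io(sprintf(
      "no pixel size in TIFF metadata and none supplied: %s", path))
  phase_image(r$matrix, pixel_size = ps, wavelength = wl)
}

#' @describeIn tiff-io Read a mask written by [write_mask_tiff()] (any
#'   nonzero pixel is selected).
#' @export
read_mask_tiff <- function(path) {
  r <- .read_tiff_matrix(path)
  roi_mask(r$matrix != 0)
}
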