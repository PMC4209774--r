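#' Read an image stack from disk
#'
#' Accepts either a directory of single-slice images (PNG, plain or binary
#' PGM, or single-page TIFF; lexicographic filename order defines the z
#' order) or a single multi-page TIFF file.  All slices must share one
#' shape.  Intensities are returned on the 0--255 scale regardless of the
#' on-disk encoding.
#'
#' Only baseline uncompressed TIFF (8-bit grayscale, little- or big-endian)
#' is understood; PNG is read via the \pkg{png} package and may be RGB.
#'
#' @param path directory of slice images, or one multi-page TIFF file.
#' @param voxel_size physical voxel size `(x, y, z)` in micrometres.
#' @return a [slice_stack()].
#' @export
load_slice_stack <- function(path, voxel_size = c(0.34, 0.34, 0.5)) {
  if (!file.exists(path))
    stop_voxtex(sprintf("path does not exist: %s", path),
                "voxtex_error_missing_path")
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|pgm|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files, method = "radix")
    if (length(files) < 2L)
      stop_voxtex(sprintf("directory %s holds %d readable slices; need >= 2",
                          path, length(files)),
                  "voxtex_error_too_few_slices")
    slices <- lapply(files, read_slice_image)
  } else {
    slices <- read_tiff_pages(path)
    if (length(slices) < 2L)
      stop_voxtex("multi-page TIFF holds fewer than 2 pages",
                  "voxtex_error_too_few_slices")
  }
  slice_stack(slices, voxel_size = voxel_size, source_id = path)
}

# Dispatch a single slice file to the right decoder; 0-255 scale out.
read_slice_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    img <- png::readPNG(file)
    if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
    return(img * 255)
  }
  if (ext == "pgm") return(read_pgm(file))
  if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff_pages(file)
    if (length(pages) != 1L)
      stop_voxtex(sprintf("%s: expected a single-page TIFF inside a slice directory",
                          file), "voxtex_error_bad_tiff")
    return(pages[[1]])
  }
  stop_voxtex(sprintf("unsupported slice format: %s", file),
              "voxtex_error_bad_format")
}

#' Write a volume as a multi-page 8-bit grayscale TIFF
#'
#' Writes one uncompressed little-endian baseline TIFF page per z-slice,
#' rounding intensities to 8-bit integers.  The result round-trips through
#' [load_slice_stack()] voxel-exactly for integer-valued volumes.
#'
#' @param vol a [gray_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "gray_volume"))
  d <- dim(vol$data)
  nz <- d[1]; h <- d[2]; w <- d[3]
  pix <- round(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)  # header; first IFD at 8
  n_tags <- 9L
  ifd_size <- 2L + 12L * n_tags + 4L
  # Each page: IFD then pixel strip, laid out back to back after the header.
  page_bytes <- ifd_size + w * h
  tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
  for (k in seq_len(nz)) {
    base <- 8L + (k - 1L) * page_bytes
    strip_off <- base + ifd_size
    w2(n_tags)
    tag(256L, 4L, 1L, w)                 # ImageWidth
    tag(257L, 4L, 1L, h)                 # ImageLength
    tag(258L, 3L, 1L, 8L)                # BitsPerSample
    tag(259L, 3L, 1L, 1L)                # Compression: none
    tag(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    tag(273L, 4L, 1L, strip_off)         # StripOffsets
    tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
    tag(278L, 4L, 1L, h)                 # RowsPerStrip
    tag(279L, 4L, 1L, w * h)             # StripByteCounts
    w4(if (k < nz) base + page_bytes else 0L)  # next IFD
    writeBin(as.raw(t(pix[k, , ])), con)       # row-major pixel order
  }
  invisible(path)
}

# Parse a baseline TIFF into a list of numeric matrices (one per page).
# Supports: uncompressed, 8 bits/sample, 1 sample/pixel, either endianness,
# one or more strips.  Anything else raises voxtex_error_bad_tiff.
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L)
    stop_voxtex(sprintf("%s: not a TIFF file", path), "voxtex_error_bad_tiff")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop_voxtex(sprintf("%s: not a TIFF file", path), "voxtex_error_bad_tiff")
  int_at <- function(off, size, n = 1L)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4L, endian = endian)
  if (int_at(2L, 2L) != 42L)
    stop_voxtex(sprintf("%s: not a TIFF file", path), "voxtex_error_bad_tiff")
  ifd_off <- int_at(4L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n_tags <- int_at(ifd_off, 2L)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      id <- int_at(e, 2L); type <- int_at(e + 2L, 2L); count <- int_at(e + 4L, 4L)
      vsize <- c(1L, 1L, 2L, 4L)[type] %||% 4L
      if (is.na(vsize)) vsize <- 4L
      values <- if (count * vsize <= 4L) {
        int_at(e + 8L, vsize, count)
      } else {
        int_at(int_at(e + 8L, 4L), vsize, count)
      }
      tags[[as.character(id)]] <- values
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    if ((g(259L, 1L))[1] != 1L)
      stop_voxtex(sprintf("%s: compressed TIFF not supported", path),
                  "voxtex_error_bad_tiff")
    if ((g(258L, 8L))[1] != 8L || (g(277L, 1L))[1] != 1L)
      stop_voxtex(sprintf("%s: only 8-bit single-sample TIFF supported", path),
                  "voxtex_error_bad_tiff")
    w <- g(256L); h <- g(257L)
    offs <- g(273L); counts <- g(279L, w * h)
    bytes <- raw(0)
    for (s in seq_along(offs))
      bytes <- c(bytes, raw[(offs[s] + 1L):(offs[s] + counts[s])])
    m <- matrix(as.integer(bytes), nrow = h, ncol = w, byrow = TRUE)
    pages[[length(pages) + 1L]] <- m
    ifd_off <- int_at(ifd_off + 2L + n_tags * 12L, 4L)
  }
  pages
}

# Plain (P2) or binary (P5) 8-bit PGM reader; returns a numeric matrix.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # Header tokens: magic, width, height, maxval, with '#' comments allowed.
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L)
        stop_voxtex(sprintf("%s: truncated PGM header", path),
                    "voxtex_error_bad_format")
      if (grepl("\\s", ch)) next
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                if (length(c2) == 0L || c2 == "\n") break }; next }
      t <- ch
      repeat {
        c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || grepl("\\s", c2)) break
        t <- paste0(t, c2)
      }
      return(t)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5"))
    stop_voxtex(sprintf("%s: not a PGM file", path), "voxtex_error_bad_format")
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n)
    stop_voxtex(sprintf("%s: truncated PGM data", path), "voxtex_error_bad_format")
  matrix(vals * (255 / maxval), nrow = h, ncol = w, byrow = TRUE)
}

#' Write a volume as a directory of plain-text PGM slices
#'
#' One ASCII (P2) PGM file per z-slice, named `slice_000.pgm`,
#' `slice_001.pgm`, ... so that lexicographic order reproduces z order.
#' Useful for small human-readable fixtures.
#'
#' @param vol a [gray_volume()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_slices_pgm <- function(vol, dir) {
  stopifnot(inherits(vol, "gray_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$data)
  for (k in seq_len(d[1])) {
    sl <- round(vol$data[k, , ])
    lines <- c("P2", sprintf("%d %d", d[3], d[2]), "255",
               apply(sl, 1, paste, collapse = " "))
    writeLines(lines, file.path(dir, sprintf("slice_%03d.pgm", k - 1L)))
  }
  invisible(dir)
}
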