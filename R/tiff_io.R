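# Minimal baseline TIFF 6.0 codec: little-endian, uncompressed, grayscale,
# 16-bit unsigned, one strip per page, physical pixel size in the
# XResolution/YResolution tags (ResolutionUnit = cm). No R TIFF package is
# assumed at run time; this codec covers exactly the files the package
# writes, plus any baseline TIFF with the same layout.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L
TIFF_TYPE_RATIONAL <- 5L

#' Write 16-bit grayscale TIFF pages
#'
#' Writes one or more single-channel images as pages of an uncompressed
#' little-endian 16-bit TIFF. Intensities are rounded and clamped to
#' \code{[0, 65535]}. The physical pixel size is stored in the resolution
#' tags as pixels per centimetre.
#'
#' @param path Output file path.
#' @param pages A matrix or list of numeric matrices (rows = image rows).
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @return \code{path}, invisibly.
#' @export
write_tiff16 <- function(path, pages, pixel_size_um) {
  if (is.matrix(pages)) pages <- list(pages)
  check_number(pixel_size_um, "pixel_size_um", 0, strict_min = TRUE)
  if (!length(pages)) stopf("no image pages to write")
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stopf("all pages must share dimensions")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  px_per_cm <- 1e4 / pixel_size_um
  res_num <- round(px_per_cm * 100); res_den <- 100

  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con), add = TRUE)
    w2 <- function(x) writeBin(as.integer(ifelse(x > 32767L, x - 65536L, x)),
                               con, size = 2L, endian = "little")
    w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
    # header: "II", magic 42, offset of first IFD filled in as we go
    writeChar("II", con, nchars = 2, eos = NULL)
    w2(42L)
    strip_bytes <- 2L * w * h
    # layout per page: [strip][xres 8B][yres 8B][IFD]; first IFD offset
    page_block <- strip_bytes + 16L + ifd_size()
    w4(8L + strip_bytes + 16L)
    for (p in seq_along(pages)) {
      m <- pages[[p]]
      v <- round(as.vector(t(m)))
      v[v < 0] <- 0; v[v > 65535] <- 65535
      base <- 8L + (p - 1L) * page_block
      w2(v)
      w4(c(res_num, res_den)); w4(c(res_num, res_den))
      entries <- list(
        c(256L, TIFF_TYPE_LONG, 1L, w),
        c(257L, TIFF_TYPE_LONG, 1L, h),
        c(258L, TIFF_TYPE_SHORT, 1L, 16L),
        c(259L, TIFF_TYPE_SHORT, 1L, 1L),          # no compression
        c(262L, TIFF_TYPE_SHORT, 1L, 1L),          # BlackIsZero
        c(273L, TIFF_TYPE_LONG, 1L, base),         # strip offset
        c(277L, TIFF_TYPE_SHORT, 1L, 1L),          # samples per pixel
        c(278L, TIFF_TYPE_LONG, 1L, h),            # rows per strip
        c(279L, TIFF_TYPE_LONG, 1L, strip_bytes),
        c(282L, TIFF_TYPE_RATIONAL, 1L, base + strip_bytes),
        c(283L, TIFF_TYPE_RATIONAL, 1L, base + strip_bytes + 8L),
        c(296L, TIFF_TYPE_SHORT, 1L, 3L),          # resolution unit: cm
        c(339L, TIFF_TYPE_SHORT, 1L, 1L)           # unsigned integer data
      )
      w2(length(entries))
      for (e in entries) {
        w2(e[1]); w2(e[2]); w4(e[3])
        if (e[2] == TIFF_TYPE_SHORT) { w2(e[4]); w2(0L) } else w4(e[4])
      }
      # next IFD sits after the next page's strip and rational block
      w4(if (p < length(pages)) base + page_block + strip_bytes + 16L else 0L)
    }
  })
}

ifd_size <- function() 2L + 13L * 12L + 4L

#' Read 16-bit grayscale TIFF pages
#'
#' Reads an uncompressed grayscale TIFF (8 or 16 bits per sample, either
#' byte order) and returns its pages as numeric matrices along with the
#' physical pixel size decoded from the resolution tags.
#'
#' @param path TIFF file path.
#' @return List with \code{pages} (list of matrices) and \code{pixel_size_um}
#'   (\code{NA} if the file carries no resolution tags).
#' @export
read_tiff16 <- function(path) {
  if (!file.exists(path)) stopf("TIFF file not found: '%s'", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stopf("'%s' is not a TIFF file", path)
  endian <- if (raw[1] == as.raw(0x49)) "little" else "big"
  rd <- function(off, size, n = 1L) {
    # signed=FALSE is only legal for 1- and 2-byte reads; 4-byte offsets in
    # files this codec handles stay below 2^31 so signed is safe there
    readBin(raw[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, signed = size > 2L, endian = endian)
  }
  if (rd(2L, 2L) != 42L) stopf("'%s' is not a TIFF file", path)
  ifd_off <- rd(4L, 4L)
  pages <- list(); pixel_size <- NA_real_
  while (ifd_off > 0L) {
    n_entries <- rd(ifd_off, 2L)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd(e, 2L); type <- rd(e + 2L, 2L); count <- rd(e + 4L, 4L)
      val <- if (type == TIFF_TYPE_SHORT && count <= 2L) {
        rd(e + 8L, 2L, count)
      } else if (type %in% c(TIFF_TYPE_LONG, TIFF_TYPE_SHORT)) {
        off <- if (type == TIFF_TYPE_LONG && count <= 1L) e + 8L else rd(e + 8L, 4L)
        rd(off, if (type == TIFF_TYPE_LONG) 4L else 2L, count)
      } else if (type == TIFF_TYPE_RATIONAL) {
        off <- rd(e + 8L, 4L)
        rd(off, 4L, 2L * count)
      } else NULL
      if (!is.null(val)) tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stopf("TIFF tag %d missing in '%s'", tag, path)
        default
      } else v
    }
    if (need(259L, 1L)[1] != 1L) stopf("only uncompressed TIFF supported ('%s')", path)
    w <- need(256L); h <- need(257L); bits <- need(258L, 16L)[1]
    offs <- need(273L); counts <- need(279L)
    bytes <- bits %/% 8L
    vals <- unlist(lapply(seq_along(offs), function(s) {
      rd(offs[s], bytes, counts[s] %/% bytes)
    }))
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = h,
                                          ncol = w, byrow = TRUE)
    xres <- tags[["282"]]
    if (!is.null(xres) && xres[1] > 0) {
      unit <- need(296L, 2L)[1]
      per <- xres[1] / xres[2]
      pixel_size <- switch(as.character(unit),
                           "2" = 25400 / per,   # inch
                           "3" = 1e4 / per,     # cm
                           NA_real_)
    }
    ifd_off <- rd(ifd_off + 2L + n_entries * 12L, 4L)
  }
  list(pages = pages, pixel_size_um = pixel_size)
}
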