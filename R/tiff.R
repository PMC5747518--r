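#' Write an image stack as a multi-page two-channel TIFF
#'
#' A minimal baseline TIFF writer (little-endian, uncompressed, 16-bit
#' grayscale, one strip per page): pages are channel-interleaved
#' (green frame 1, red frame 1, green frame 2, ...), and the pixel size
#' and frame interval are recorded in each page's ImageDescription tag as
#' `pixel_um=<..>;dt_s=<..>;channels=GR`. Only files produced by this
#' writer (or equally plain baseline TIFFs) are meant to be read back with
#' [read_image_tiff()]; no compression, tiling or palette support.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @export
write_image_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$green)
  ny <- d[1L]; nx <- d[2L]; nt <- d[3L]
  desc <- sprintf("pixel_um=%.10g;dt_s=%.10g;channels=GR", stack$pixel_um, stack$dt_s)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)  # header; first IFD at 8
  n_pages <- 2L * nt
  strip_bytes <- 2L * nx * ny
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  meta_size <- ifd_size + length(desc_raw)
  data_start <- 8L + n_pages * meta_size
  for (p in seq_len(n_pages)) {
    ifd_off <- 8L + (p - 1L) * meta_size
    desc_off <- ifd_off + ifd_size
    strip_off <- data_start + (p - 1L) * strip_bytes
    next_ifd <- if (p < n_pages) 8L + p * meta_size else 0L
    tag <- function(id, type, count, value) {  # value fits in 4 bytes
      w2(id); w2(type); w4(count)
      if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
    }
    w2(n_tags)
    tag(256L, 3L, 1L, nx)                   # ImageWidth
    tag(257L, 3L, 1L, ny)                   # ImageLength
    tag(258L, 3L, 1L, 16L)                  # BitsPerSample
    tag(259L, 3L, 1L, 1L)                   # Compression: none
    tag(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    tag(270L, 2L, length(desc_raw), desc_off)  # ImageDescription
    tag(273L, 4L, 1L, strip_off)            # StripOffsets
    tag(278L, 3L, 1L, ny)                   # RowsPerStrip
    tag(279L, 4L, 1L, strip_bytes)          # StripByteCounts
    w4(next_ifd)
    writeBin(desc_raw, con)
  }
  for (k in seq_len(nt)) {
    for (ch in c("green", "red")) {
      # TIFF stores row-major (rows of the image): transpose our [y, x]
      writeBin(as.integer(t(stack[[ch]][, , k])), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a multi-page two-channel TIFF written by [write_image_tiff()]
#'
#' @param path TIFF file path.
#' @param pixel_um,dt_s Optional overrides for the metadata recorded in
#'   the file (required if the file has no ImageDescription metadata).
#' @return An [image_stack()].
#' @export
read_image_tiff <- function(path, pixel_um = NULL, dt_s = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L) {
    stop("not a little-endian baseline TIFF: ", path)
  }
  pages <- list(); desc <- NULL
  ifd <- u32(4L)
  while (ifd != 0) {
    n_tags <- u16(ifd)
    tags <- list()
    for (i in seq_len(n_tags)) {
      off <- ifd + 2L + (i - 1L) * 12L
      id <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
      val <- if (type == 3L && count == 1L) u16(off + 8L) else u32(off + 8L)
      tags[[as.character(id)]] <- list(type = type, count = count, value = val)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("unsupported TIFF layout in ", path)
    if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1L) {
      stop("compressed TIFF not supported: ", path)
    }
    if (is.null(desc) && !is.null(tags[["270"]])) {
      doff <- tags[["270"]]$value; dlen <- tags[["270"]]$count
      desc <- rawToChar(raw[(doff + 1L):(doff + dlen)][raw[(doff + 1L):(doff + dlen)] != as.raw(0L)])
    }
    pages[[length(pages) + 1L]] <- list(nx = tags[["256"]]$value,
                                        ny = tags[["257"]]$value,
                                        off = tags[["273"]]$value,
                                        bytes = tags[["279"]]$value)
    ifd <- u32(ifd + 2L + n_tags * 12L)
  }
  if (length(pages) %% 2L) stop("odd page count; expected channel-interleaved G,R pages")
  meta <- list()
  if (!is.null(desc)) {
    for (kv in strsplit(desc, ";")[[1L]]) {
      p <- strsplit(kv, "=")[[1L]]
      if (length(p) == 2L) meta[[p[1L]]] <- p[2L]
    }
  }
  pixel_um <- pixel_um %||% as.numeric(meta$pixel_um)
  dt_s <- dt_s %||% as.numeric(meta$dt_s)
  if (is.null(pixel_um) || is.na(pixel_um) || is.null(dt_s) || is.na(dt_s)) {
    stop("no pixel size / frame interval metadata; pass pixel_um and dt_s")
  }
  nx <- pages[[1L]]$nx; ny <- pages[[1L]]$ny
  nt <- length(pages) %/% 2L
  green <- array(0L, c(ny, nx, nt)); red <- array(0L, c(ny, nx, nt))
  for (k in seq_len(nt)) {
    for (ci in 1:2) {
      pg <- pages[[(k - 1L) * 2L + ci]]
      con <- rawConnection(raw[(pg$off + 1L):(pg$off + pg$bytes)])
      vals <- readBin(con, "integer", n = pg$nx * pg$ny, size = 2L,
                      endian = "little", signed = FALSE)
      close(con)
      m <- t(matrix(vals, nrow = pg$nx, ncol = pg$ny))  # undo row-major
      if (ci == 1L) green[, , k] <- m else red[, , k] <- m
    }
  }
  image_stack(green, red, pixel_um, dt_s)
}
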