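# Portable anymap (PGM/PPM) I/O.
#
# The package's image artifacts use the netpbm formats: a trivial
# header-plus-raster layout readable by every scientific image stack. No R
# package for PNG/JPEG is assumed; PGM/PPM keeps artifacts portable and
# (in ASCII form) diffable.

#' Write a grayscale image as PGM
#'
#' @param image Numeric matrix in `[0, 1]` (quantized to 8-bit) or a
#'   logical matrix (written as 0/255).
#' @param path Output path.
#' @param ascii Write ASCII (`P2`) instead of binary (`P5`).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, ascii = FALSE) {
  if (is.logical(image)) image <- image * 1.0
  if (!is.matrix(image)) stop_invalid("'image' must be a matrix")
  px <- round(pmin(pmax(image, 0), 1) * 255)
  # raster order: row by row, top to bottom
  flat <- as.integer(t(px))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con, eos = NULL)
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

#' Write an RGB image as PPM
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param path Output path.
#' @param ascii Write ASCII (`P3`) instead of binary (`P6`).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(image, path, ascii = FALSE) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop_invalid("'image' must be an H x W x 3 array")
  px <- round(pmin(pmax(image, 0), 1) * 255)
  h <- dim(px)[1L]; w <- dim(px)[2L]
  # interleave channels pixel by pixel in raster order
  flat <- integer(3L * h * w)
  for (ch in 1:3) flat[seq(ch, by = 3L, length.out = h * w)] <- as.integer(t(px[, , ch]))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

.pnm_tokens <- function(raw_bytes, n_tokens) {
  # scan header tokens (magic, dims, maxval), skipping '#' comments
  toks <- character(0)
  i <- 1L
  n <- length(raw_bytes)
  while (length(toks) < n_tokens && i <= n) {
    ch <- rawToChar(raw_bytes[i])
    if (ch == "#") {
      while (i <= n && rawToChar(raw_bytes[i]) != "\n") i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[[:space:]]", rawToChar(raw_bytes[j]))) j <- j + 1L
      toks <- c(toks, rawToChar(raw_bytes[i:(j - 1L)]))
      i <- j
    }
  }
  list(tokens = toks, next_byte = i + 1L)  # single whitespace after maxval
}

#' Read a PGM image
#'
#' Supports ASCII (`P2`) and binary (`P5`) variants with 8-bit depth.
#'
#' @param path Path to a PGM file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  hdr <- .pnm_tokens(bytes, 4L)
  magic <- hdr$tokens[1L]
  if (!magic %in% c("P2", "P5")) stop_invalid("not a PGM file")
  w <- as.integer(hdr$tokens[2L]); h <- as.integer(hdr$tokens[3L])
  maxval <- as.integer(hdr$tokens[4L])
  if (magic == "P5") {
    px <- as.integer(bytes[hdr$next_byte:(hdr$next_byte + w * h - 1L)])
  } else {
    txt <- rawToChar(bytes[(hdr$next_byte - 1L):length(bytes)])
    px <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1L]])[seq_len(w * h)]
  }
  t(matrix(px, nrow = w, ncol = h)) / maxval
}
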