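# Grayscale image container, file I/O, histogram equalization.
#
# Images are plain numeric matrices carrying class "gray_image". Pixel (r, c)
# addresses row r (top-down) and column c (left-right); the x axis is the
# column axis and the y axis is the row axis. Intensities are floats in the
# nominal 8-bit range [0, 255]; quantization to 8 bits happens only when an
# image is written to disk, so repeated filtering passes do not accumulate
# rounding error.

#' Construct a grayscale image
#'
#' Wraps a numeric matrix as a `gray_image`: a 2D scalar intensity field in
#' the nominal range \[0, 255\], addressed as (row, column) with row 1 at the
#' top. Values are carried as floats; they are quantized to 8 bits only by
#' [write_gray()].
#'
#' @param pixels Numeric matrix of intensities. All values must be finite and
#'   within \[0, 255\].
#' @return A `gray_image` (numeric matrix with class attribute).
#' @examples
#' img <- gray_image(matrix(c(0, 85, 170, 255), 2, 2))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(pixels, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, range [%.1f, %.1f], mean %.1f\n",
              nrow(x), ncol(x), min(x), max(x), mean(x)))
  invisible(x)
}

# Strip the class so internal arithmetic works on a bare matrix.
as_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}

assert_gray <- function(img, arg = "img") {
  if (!inherits(img, "gray_image"))
    stop(sprintf("`%s` must be a gray_image (see gray_image())", arg),
         call. = FALSE)
  invisible(img)
}

clip255 <- function(m) pmin(pmax(m, 0), 255)

#' Read a grayscale image from file
#'
#' Reads PNG, PGM (both the ASCII `P2` and binary `P5` flavors) or
#' single-image TIFF into a [gray_image()]. Multi-channel inputs are reduced
#' to luminance with the Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); an
#' alpha channel, if present, is ignored. Output intensities are floats in
#' \[0, 255\].
#'
#' @param path Path to a `.png`, `.pgm`, `.tif`/`.tiff` file.
#' @return A [gray_image()].
#' @seealso [write_gray()]
#' @export
read_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path) * 255,
    pgm  = read_pgm(path),
    tif  = ,
    tiff = tiff::readTIFF(path) * 255,
    stop(sprintf("unsupported image format '.%s' (PNG/PGM/TIFF only)", ext),
         call. = FALSE)
  )
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3L]
    if (nch >= 3L) {
      a <- 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    } else {
      a <- a[, , 1L]
    }
  }
  if (is.null(dim(a)) || any(dim(a) < 1L))
    stop(sprintf("zero-size image: %s", path), call. = FALSE)
  gray_image(clip255(a))
}

#' Write a grayscale image to file
#'
#' Quantizes intensities to 8 bits (`round`, then clip to \[0, 255\]) and
#' writes PNG (default), ASCII PGM (`P2`) or TIFF according to the file
#' extension.
#'
#' @param img A [gray_image()].
#' @param path Output path ending in `.png`, `.pgm`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  assert_gray(img)
  q <- round(clip255(as_matrix(img)))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(q / 255, path),
    pgm  = write_pgm(q, path),
    tif  = ,
    tiff = tiff::writeTIFF(q / 255, path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format '.%s' (PNG/PGM/TIFF only)", ext),
         call. = FALSE)
  )
  invisible(path)
}

# Minimal PGM reader: P2 (ASCII) and P5 (8-bit binary), '#' comments allowed
# in the header. Returns a numeric matrix scaled to [0, 255].
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || !nzchar(ch))
        stop(sprintf("truncated PGM header: %s", path), call. = FALSE)
      if (ch == "#") {       # comment runs to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || !nzchar(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
        next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("not a PGM file (magic '%s'): %s", magic, path),
         call. = FALSE)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (any(is.na(c(w, h, maxval))) || w < 1L || h < 1L || maxval < 1L)
    stop(sprintf("invalid PGM header: %s", path), call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    if (maxval > 255L)
      stop("16-bit binary PGM is not supported", call. = FALSE)
    v <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  } else {
    v <- integer(0)
    while (length(v) < n) {
      chunk <- scan(con, what = integer(), n = n - length(v), quiet = TRUE)
      if (!length(chunk)) break
      v <- c(v, chunk)
    }
  }
  if (length(v) < n)
    stop(sprintf("truncated PGM pixel data: %s", path), call. = FALSE)
  m <- matrix(as.numeric(v[seq_len(n)]), nrow = h, ncol = w, byrow = TRUE)
  if (maxval != 255L) m <- m * (255 / maxval)
  m
}

write_pgm <- function(q, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "255"), con)
  # one image row per line keeps files diffable
  apply(q, 1L, function(row) writeLines(paste(as.integer(row), collapse = " "), con))
  invisible(path)
}

#' Histogram equalization
#'
#' Classical 256-bin cumulative-distribution histogram equalization, the
#' pipeline's first stage. Intensities are binned to the nearest integer
#' level, the empirical CDF is computed, and each level `v` is remapped to
#' `round(255 * (cdf(v) - cdf_min) / (1 - cdf_min))` where `cdf_min` is the
#' CDF at the lowest occupied level. The mapping is monotone non-decreasing.
#' A single-valued image (where `1 - cdf_min = 0`) is returned unchanged.
#'
#' @param img A [gray_image()].
#' @return The equalized [gray_image()].
#' @export
equalize <- function(img) {
  assert_gray(img)
  m <- as_matrix(img)
  bins <- pmin(pmax(as.integer(round(m)), 0L), 255L)
  counts <- tabulate(bins + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(bins)
  cdf_min <- cdf[which(counts > 0L)[1L]]
  if (1 - cdf_min <= 0) return(img)   # constant image: degenerate mapping
  lut <- round(255 * (cdf - cdf_min) / (1 - cdf_min))
  gray_image(matrix(lut[bins + 1L], nrow = nrow(m), ncol = ncol(m)))
}
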