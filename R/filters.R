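# The filter pool — oriented 1D Gaussian "stick", 2D median, 2D Gaussian —
# and the structure-driven dispatch that applies one despeckling pass.
#
# Every filter reads only the pass-input image (out-of-place), so the result
# is independent of pixel visiting order; borders are mirror-reflected
# everywhere.

#' Filter-pool parameters
#'
#' @param stick_len Number of samples on the oriented 1D Gaussian stick
#'   (odd, >= 3). Default 9.
#' @param stick_sigma Standard deviation of the stick's Gaussian weights, in
#'   pixels. Default 1.
#' @param median_size Side of the square median window (odd, >= 3). Default
#'   9.
#' @param gauss2d_sigma Standard deviation of the isotropic 2D Gaussian used
#'   on spot pixels, in pixels. Default 1.
#' @return A `filter_params` list.
#' @export
filter_params <- function(stick_len = 9L, stick_sigma = 1,
                          median_size = 9L, gauss2d_sigma = 1) {
  stick_len <- as.integer(stick_len)
  median_size <- as.integer(median_size)
  if (is.na(stick_len) || stick_len < 3L || stick_len %% 2L == 0L)
    stop("`stick_len` must be odd and >= 3", call. = FALSE)
  if (is.na(median_size) || median_size < 3L || median_size %% 2L == 0L)
    stop("`median_size` must be odd and >= 3", call. = FALSE)
  if (!is.numeric(stick_sigma) || stick_sigma <= 0 ||
      !is.numeric(gauss2d_sigma) || gauss2d_sigma <= 0)
    stop("sigmas must be > 0", call. = FALSE)
  structure(list(stick_len = stick_len, stick_sigma = stick_sigma,
                 median_size = median_size, gauss2d_sigma = gauss2d_sigma),
            class = "filter_params")
}

assert_filter_params <- function(params) {
  if (!inherits(params, "filter_params"))
    stop("`params` must come from filter_params()", call. = FALSE)
  invisible(params)
}

stick_weights <- function(len, sigma) {
  k <- seq.int(-(len %/% 2L), len %/% 2L)
  w <- exp(-k^2 / (2 * sigma^2))
  list(offsets = k, weights = w / sum(w))
}

# Bilinear sampling at continuous (rows, cols), coordinates mirror-reflected
# into the image. Vectorized over sample positions.
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  y <- reflect_coord(rows, nr)
  x <- reflect_coord(cols, nc)
  y0 <- pmax(pmin(floor(y), nr - 1L), 1)
  x0 <- pmax(pmin(floor(x), nc - 1L), 1)
  fy <- pmax(y - y0, 0)   # 0 for single-row/col images
  fx <- pmax(x - x0, 0)
  y1 <- pmin(y0 + 1, nr)
  x1 <- pmin(x0 + 1, nc)
  v00 <- m[(x0 - 1) * nr + y0]; v10 <- m[(x0 - 1) * nr + y1]
  v01 <- m[(x1 - 1) * nr + y0]; v11 <- m[(x1 - 1) * nr + y1]
  (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
    (1 - fy) * fx * v01 + fy * fx * v11
}

#' Oriented 1D Gaussian stick filter at one pixel
#'
#' Averages `stick_len` bilinear samples taken at offsets `k * dir`,
#' `k = -(len-1)/2 .. (len-1)/2`, from pixel `(r, c)`, with Gaussian weights
#' `exp(-k^2 / (2 sigma^2))` normalized to sum 1. In the despeckling
#' dispatch the direction is the minor eigenvector, so smoothing runs along
#' a curvilinear structure and never across it — intensity along the curve
#' becomes coherent while the cross-curve contrast is retained or enhanced.
#'
#' @param img A [gray_image()].
#' @param r,c Pixel row and column (1-based).
#' @param dir Unit direction as `c(x, y)` = (column, row) components.
#' @param params A [filter_params()].
#' @return The filtered intensity at `(r, c)`.
#' @export
stick_gaussian <- function(img, r, c, dir, params = filter_params()) {
  assert_gray(img)
  assert_filter_params(params)
  if (length(dir) != 2L || !all(is.finite(dir)) || all(dir == 0))
    stop("`dir` must be a nonzero 2-vector c(x, y)", call. = FALSE)
  if (r < 1L || r > nrow(img) || c < 1L || c > ncol(img))
    stop("pixel out of bounds", call. = FALSE)
  nrm <- sqrt(sum(dir^2))
  dir <- dir / nrm
  sw <- stick_weights(params$stick_len, params$stick_sigma)
  samp <- bilinear_sample(as_matrix(img),
                          r + sw$offsets * dir[2L],
                          c + sw$offsets * dir[1L])
  sum(sw$weights * samp)
}

# Stick filtering of many pixels at once: rows/cols/dirx/diry are parallel
# vectors (directions already unit length).
stick_filter_at <- function(m, rows, cols, dirx, diry, params) {
  sw <- stick_weights(params$stick_len, params$stick_sigma)
  out <- numeric(length(rows))
  for (i in seq_along(sw$offsets)) {
    k <- sw$offsets[i]
    out <- out + sw$weights[i] *
      bilinear_sample(m, rows + k * diry, cols + k * dirx)
  }
  out
}

# Full-image exact median filter (mirror borders); used by the dispatch and
# the baseline. Returns a bare matrix.
median_filter_full <- function(m, size) {
  half <- size %/% 2L
  median_filter_padded(pad_reflect(m, half, half), nrow(m), ncol(m), half)
}

#' 2D median filter at one pixel
#'
#' Exact median of the `size x size` neighborhood centered at `(r, c)`,
#' mirror-reflected at the borders. The odd window guarantees an odd sample
#' count, so the median is always an observed intensity.
#'
#' @param img A [gray_image()].
#' @param r,c Pixel row and column (1-based).
#' @param size Odd window side, >= 3.
#' @return The neighborhood median.
#' @export
median2d <- function(img, r, c, size = 9L) {
  assert_gray(img)
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    stop("`size` must be odd and >= 3", call. = FALSE)
  if (r < 1L || r > nrow(img) || c < 1L || c > ncol(img))
    stop("pixel out of bounds", call. = FALSE)
  m <- as_matrix(img)
  half <- size %/% 2L
  ri <- reflect_index(seq.int(r - half, r + half), nrow(m))
  ci <- reflect_index(seq.int(c - half, c + half), ncol(m))
  median(m[ri, ci])
}

#' Isotropic 2D Gaussian filter
#'
#' Separable Gaussian convolution with kernel truncated at 4 sigma and
#' mirror-reflected borders. With the default sigma = 1 the support is
#' 9 x 9.
#'
#' @param img A [gray_image()].
#' @param sigma Standard deviation in pixels (> 0).
#' @return The filtered [gray_image()].
#' @export
gaussian2d <- function(img, sigma = 1) {
  assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  g <- gauss_kernel(sigma)
  gray_image(clip255(correlate_sep(as_matrix(img), g, g)))
}

#' Structure-driven filtering pass
#'
#' Applies the filter pool according to the structure map, out-of-place
#' (every filter reads only `img`): linear and boundary pixels get the
#' oriented stick filter along the minor eigenvector, uniform and unknown
#' pixels the `median_size` x `median_size` median, spot pixels the value of
#' the sigma = `gauss2d_sigma` 2D Gaussian at that pixel. The output is
#' clipped to \[0, 255\].
#'
#' @param img A [gray_image()] (the pass input).
#' @param map The `structure_map` for `img`.
#' @param tf The `tensor_field` carrying the minor eigenvectors.
#' @param params A [filter_params()].
#' @return The filtered [gray_image()].
#' @export
apply_structure_filtering <- function(img, map, tf,
                                      params = filter_params()) {
  assert_gray(img)
  assert_filter_params(params)
  if (!inherits(map, "structure_map"))
    stop("`map` must be a structure_map", call. = FALSE)
  if (!inherits(tf, "tensor_field") || !isTRUE(tf$has_eigen))
    stop("`tf` must be a tensor_field with the eigensystem computed",
         call. = FALSE)
  if (!all(dim(img) == dim(map)) || !all(dim(img) == tf$dim))
    stop("`img`, `map` and `tf` must have the same shape", call. = FALSE)

  m <- as_matrix(img)
  lab <- unclass(map)
  out <- m

  sel <- lab == TYPE_UNIFORM | lab == TYPE_UNKNOWN
  if (any(sel)) {
    med <- median_filter_full(m, params$median_size)
    out[sel] <- med[sel]
  }
  sel <- lab == TYPE_SPOT
  if (any(sel)) {
    g <- gauss_kernel(params$gauss2d_sigma)
    sm <- correlate_sep(m, g, g)
    out[sel] <- sm[sel]
  }
  sel <- which(lab == TYPE_LINEAR | lab == TYPE_BOUNDARY)
  if (length(sel)) {
    rows <- (sel - 1L) %% nrow(m) + 1L
    cols <- (sel - 1L) %/% nrow(m) + 1L
    out[sel] <- stick_filter_at(m, rows, cols, tf$v2x[sel], tf$v2y[sel],
                                params)
  }
  gray_image(clip255(out))
}
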