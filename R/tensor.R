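# Per-pixel diffusion tensor (intensity Hessian) at a Gaussian scale, its
# closed-form eigensystem, and global eigenvalue normalization.
#
# The Hessian H = [[Ixx, Ixy], [Ixy, Iyy]] is obtained by correlating the
# image with sampled Gaussian-derivative kernels (x = column axis, y = row
# axis). Kernels are separable; borders are handled by mirror reflection
# about the edge pixel centers. The discrete kernels are moment-corrected so
# that the second-derivative kernel responds exactly 2 to I = x^2 and the
# first-derivative kernel exactly 1 to I = x, matching their continuous
# counterparts on polynomials.

# ---- mirror-reflected indexing and separable correlation -------------------

# Reflect integer indices into 1..n about the edge pixel centers
# (..., 3, 2 | 1, 2, ..., n | n-1, n-2, ...). Handles arbitrarily far
# excursions via the period-2(n-1) fold.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# Reflect continuous coordinates into [1, n] with the same fold; used by
# bilinear sampling in the stick filter.
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  j <- (x - 1) %% p
  j <- ifelse(j < 0, j + p, j)
  ifelse(j > (n - 1), p - j, j) + 1
}

pad_reflect <- function(m, pr, pc) {
  ri <- reflect_index(seq.int(1L - pr, nrow(m) + pr), nrow(m))
  ci <- reflect_index(seq.int(1L - pc, ncol(m) + pc), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Separable correlation: kx runs along the column (x) axis, ky along the
# row (y) axis. out[r, c] = sum_{i,j} ky[j] kx[i] m[r + j, c + i].
correlate_sep <- function(m, kx, ky) {
  nr <- nrow(m); nc <- ncol(m)
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  p <- pad_reflect(m, ry, rx)
  # pass 1: along x (columns)
  tmp <- matrix(0, nrow(p), nc)
  for (i in seq_along(kx))
    tmp <- tmp + kx[i] * p[, (i - 1L) + seq_len(nc), drop = FALSE]
  # pass 2: along y (rows)
  out <- matrix(0, nr, nc)
  for (j in seq_along(ky))
    out <- out + ky[j] * tmp[(j - 1L) + seq_len(nr), , drop = FALSE]
  out
}

# ---- sampled, moment-corrected Gaussian-derivative kernels -----------------

kernel_radius <- function(sigma) max(1L, as.integer(floor(4 * sigma)))

gauss_kernel <- function(sigma, radius = kernel_radius(sigma)) {
  t <- seq.int(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2))
  g / sum(g)
}

# First derivative: antisymmetric, scaled so sum(k * d[k]) = 1
# (correlation with I = x yields exactly 1).
dgauss_kernel <- function(sigma, radius = kernel_radius(sigma)) {
  t <- seq.int(-radius, radius)
  d <- t * exp(-t^2 / (2 * sigma^2))
  d / sum(t * d)
}

# Second derivative: mean-subtracted so a constant maps to 0, scaled so
# sum(k^2 * h[k]) = 2 (correlation with I = x^2 yields exactly 2).
ddgauss_kernel <- function(sigma, radius = kernel_radius(sigma)) {
  t <- seq.int(-radius, radius)
  h <- (t^2 / sigma^4 - 1 / sigma^2) * exp(-t^2 / (2 * sigma^2))
  h <- h - mean(h)
  h * (2 / sum(t^2 * h))
}

# ---- tensor field ----------------------------------------------------------

#' Hessian (diffusion tensor) field of an image
#'
#' Computes the per-pixel second-derivative responses Ixx, Ixy, Iyy by
#' correlation with separable Gaussian-derivative kernels at scale `sigma`
#' (truncated at 4 sigma, mirror-reflected borders). The eigensystem is not
#' yet computed; see [compute_eigensystem()] and [normalize_field()].
#'
#' @param img A [gray_image()].
#' @param sigma Gaussian scale in pixels (> 0). The default 1.4 is the
#'   operating scale of the despeckling pipeline.
#' @return A `tensor_field`: list with matrices `ixx`, `ixy`, `iyy`, the
#'   image dimensions, and bookkeeping fields (`has_eigen`, `normalized`,
#'   `norm_const`).
#' @export
hessian_field <- function(img, sigma = 1.4) {
  assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  m <- as_matrix(img)
  g <- gauss_kernel(sigma)
  d <- dgauss_kernel(sigma)
  h <- ddgauss_kernel(sigma)
  # floating-point summation leaves O(eps * intensity) residue where the
  # true derivative is 0; snap it out so the later global eigenvalue
  # normalization cannot amplify pure round-off into apparent structure
  floor_tol <- 1e-11 * max(1, max(abs(m)))
  snap <- function(x) { x[abs(x) < floor_tol] <- 0; x }
  tf <- list(
    ixx = snap(correlate_sep(m, kx = h, ky = g)),
    ixy = snap(correlate_sep(m, kx = d, ky = d)),
    iyy = snap(correlate_sep(m, kx = g, ky = h)),
    dim = dim(m), sigma = sigma,
    has_eigen = FALSE, normalized = FALSE, norm_const = NA_real_
  )
  class(tf) <- "tensor_field"
  tf
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d x %d, sigma = %g, eigen: %s, normalized: %s\n",
              x$dim[1L], x$dim[2L], x$sigma,
              if (x$has_eigen) "yes" else "no",
              if (x$normalized) sprintf("yes (norm_const = %g)", x$norm_const)
              else "no"))
  invisible(x)
}

#' Closed-form eigensystem of symmetric 2x2 matrices
#'
#' Eigendecomposition of `[[ixx, ixy], [ixy, iyy]]`, vectorized over the
#' inputs. Eigenvalues are ordered by magnitude, `|lam1| >= |lam2|` (the
#' major/minor convention of Hessian structure analysis); when the two
#' magnitudes are equal but the values differ (trace zero), the negative
#' eigenvalue is taken as `lam1`. Eigenvectors are unit length, mutually
#' orthogonal, and sign-canonicalized so that the x component is >= 0 (and
#' the y component >= 0 when x = 0). The zero (or isotropic) matrix yields
#' `v1 = (1, 0)`, `v2 = (0, 1)` by convention.
#'
#' @param ixx,ixy,iyy Numeric vectors (recycled to common length) of the
#'   symmetric matrix entries; must be finite.
#' @return List of numeric vectors `lam1`, `lam2`, `v1x`, `v1y`, `v2x`,
#'   `v2y`. Vector components are in (x, y) = (column, row) axes.
#' @examples
#' eig2x2_symmetric(2, 0, 1)   # lam1 = 2 along x, lam2 = 1 along y
#' @export
eig2x2_symmetric <- function(ixx, ixy, iyy) {
  n <- max(length(ixx), length(ixy), length(iyy))
  a <- rep_len(as.numeric(ixx), n)
  b <- rep_len(as.numeric(ixy), n)
  c_ <- rep_len(as.numeric(iyy), n)
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(c_)))
    stop("tensor entries must be finite", call. = FALSE)

  half_tr <- (a + c_) / 2
  disc <- sqrt(((a - c_) / 2)^2 + b^2)
  lp <- half_tr + disc   # lp >= lm always
  lm <- half_tr - disc

  # order by magnitude; tie |lp| == |lm| with lp != lm -> negative first
  take_p <- abs(lp) > abs(lm) | (abs(lp) == abs(lm) & lp == lm)
  lam1 <- ifelse(take_p, lp, lm)
  lam2 <- ifelse(take_p, lm, lp)

  # eigenvector for lam2 from the larger of the two candidate rows of
  # (H - lam2 I); degenerate (isotropic) pixels fall back to the axes
  u1x <- b;         u1y <- lam2 - a
  u2x <- lam2 - c_; u2y <- b
  n1 <- u1x^2 + u1y^2
  n2 <- u2x^2 + u2y^2
  use1 <- n1 >= n2
  vx <- ifelse(use1, u1x, u2x)
  vy <- ifelse(use1, u1y, u2y)
  nv <- sqrt(vx^2 + vy^2)
  degen <- nv < .Machine$double.eps * (abs(a) + abs(c_) + abs(b) + 1)
  vx <- ifelse(degen, 0, vx / ifelse(nv > 0, nv, 1))
  vy <- ifelse(degen, 1, vy / ifelse(nv > 0, nv, 1))

  # canonical sign: x >= 0, and y >= 0 when x == 0
  flip <- vx < 0 | (vx == 0 & vy < 0)
  v2x <- ifelse(flip, -vx, vx)
  v2y <- ifelse(flip, -vy, vy)

  # v1 is the perpendicular, canonicalized the same way
  w1x <- -v2y; w1y <- v2x
  flip <- w1x < 0 | (w1x == 0 & w1y < 0)
  v1x <- ifelse(flip, -w1x, w1x)
  v1y <- ifelse(flip, -w1y, w1y)

  list(lam1 = lam1, lam2 = lam2, v1x = v1x, v1y = v1y, v2x = v2x, v2y = v2y)
}

#' Compute the eigensystem of every pixel of a tensor field
#'
#' @param tf A `tensor_field` from [hessian_field()].
#' @return `tf` with matrices `lam1`, `lam2`, `v1x`, `v1y`, `v2x`, `v2y`
#'   added and `has_eigen = TRUE`.
#' @export
compute_eigensystem <- function(tf) {
  if (!inherits(tf, "tensor_field"))
    stop("`tf` must be a tensor_field", call. = FALSE)
  e <- eig2x2_symmetric(tf$ixx, tf$ixy, tf$iyy)
  d <- tf$dim
  for (f in names(e)) tf[[f]] <- matrix(e[[f]], d[1L], d[2L])
  tf$has_eigen <- TRUE
  tf
}

#' Globally normalize the eigenvalues of a tensor field
#'
#' Divides every eigenvalue by the maximum eigenvalue magnitude over the
#' whole field, so that all eigenvalues lie in \[-1, 1\]; the divisor is
#' recorded as `norm_const`. A field whose eigenvalues are all zero is
#' returned unchanged with `norm_const = 0`. Normalization makes the
#' downstream structure classification invariant to a global rescaling of
#' image contrast.
#'
#' @param tf A `tensor_field` with the eigensystem computed.
#' @return The normalized `tensor_field`.
#' @export
normalize_field <- function(tf) {
  if (!inherits(tf, "tensor_field") || !isTRUE(tf$has_eigen))
    stop("`tf` must be a tensor_field with the eigensystem computed",
         call. = FALSE)
  if (isTRUE(tf$normalized)) return(tf)
  k <- max(abs(tf$lam1))    # |lam1| >= |lam2| pointwise
  if (k > 0) {
    tf$lam1 <- tf$lam1 / k
    tf$lam2 <- tf$lam2 / k
  }
  tf$norm_const <- k
  tf$normalized <- TRUE
  tf
}
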