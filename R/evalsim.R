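# Evaluation machinery: multiplicative Rayleigh-type speckle, a labeled
# synthetic phantom generator, PSNR and SSIM, the baseline filters, and a
# benchmark harness that runs the full corrupt -> filter -> score protocol.

#' Multiplicative Rayleigh speckle
#'
#' Corrupts an image as `I* = clip(I * n, 0, 255)` with a unit-mean
#' multiplicative field `n = max(0, 1 + sigma * Z)`, where `Z` is a
#' standardized (zero-mean, unit-variance) Rayleigh variate. `sigma` is thus
#' the standard deviation (and, on a constant image, the coefficient of
#' variation) of the noise field. The Rayleigh shape gives the positive skew
#' characteristic of speckle; anchoring the mean at 1 keeps overall image
#' brightness, so fidelity changes measured by PSNR reflect noise alone.
#'
#' @param img A [gray_image()].
#' @param sigma Noise level >= 0 (typical speckle studies use 0.1-0.5).
#' @param seed Optional integer seed for reproducibility.
#' @return The noisy [gray_image()].
#' @export
multiplicative_rayleigh <- function(img, sigma, seed = NULL) {
  assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("`sigma` must be a single number >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- as_matrix(img)
  # Rayleigh(1): mean sqrt(pi/2), variance 2 - pi/2
  r <- sqrt(-2 * log(runif(length(m))))
  z <- (r - sqrt(pi / 2)) / sqrt(2 - pi / 2)
  n <- pmax(0, 1 + sigma * z)
  gray_image(clip255(m * matrix(n, nrow(m), ncol(m))))
}

# ---- phantom ----------------------------------------------------------------

#' Phantom specification
#'
#' Describes a synthetic test scene that emulates the structures the
#' despeckler targets: piecewise-uniform tissue regions (vertical bands),
#' bright/dark curvilinear boundaries with Gaussian cross-section (expected
#' linear / boundary structures), and isolated Gaussian spots.
#'
#' @param size `c(rows, cols)`, each >= 64.
#' @param background Numeric vector of band intensities; the image is split
#'   into `length(background)` equal-width vertical bands.
#' @param ridges List of ridges, each `list(points = , amplitude = ,
#'   width = )` where `points` is an n x 2 matrix of (row, col) polyline
#'   vertices, `amplitude` the signed peak offset (positive = bright ridge,
#'   negative = dark curve) and `width` the Gaussian cross-section standard
#'   deviation in pixels (> 0).
#' @param spots List of spots, each `list(center = c(row, col),
#'   amplitude = , radius = )` with `radius` the Gaussian standard deviation
#'   (> 0).
#' @param seed Integer seed; jitters structure placement so distinct seeds
#'   give distinct (but statistically identical) scenes.
#' @return A `phantom_spec` list.
#' @seealso [make_phantom()], [default_phantom_spec()]
#' @export
phantom_spec <- function(size = c(256L, 256L),
                         background = c(70, 120, 170),
                         ridges = list(), spots = list(), seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(is.na(size)) || any(size < 64L))
    stop("`size` must be c(rows, cols) with both >= 64", call. = FALSE)
  if (!is.numeric(background) || !length(background) ||
      any(background < 0 | background > 255))
    stop("`background` must be intensities in [0, 255]", call. = FALSE)
  for (rg in ridges)
    if (!is.matrix(rg$points) || ncol(rg$points) != 2L || rg$width <= 0)
      stop("each ridge needs an n x 2 `points` matrix and `width` > 0",
           call. = FALSE)
  for (sp in spots)
    if (length(sp$center) != 2L || sp$radius <= 0)
      stop("each spot needs `center = c(row, col)` and `radius` > 0",
           call. = FALSE)
  structure(list(size = size, background = background, ridges = ridges,
                 spots = spots, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' The reference phantom scene
#'
#' A 256 x 256 scene with three flat vertical bands (intensities 70, 120,
#' 170), two bright ridges (amplitudes +70 and +60, cross-section width 2),
#' one dark curve (amplitude -60, width 2) and four Gaussian spots
#' (amplitudes +80/-80, radius 3), placed with a small seed-driven jitter.
#'
#' @param seed Integer seed for the placement jitter.
#' @param size `c(rows, cols)`.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1L, size = c(256L, 256L)) {
  set.seed(as.integer(seed))
  nr <- size[1L]; nc <- size[2L]
  jit <- function(k) runif(k, -2, 2)
  # ridge 1: gently sloping near-horizontal polyline in the upper third
  xs <- seq(1, nc, length.out = 7L)
  r1 <- cbind(nr * 0.22 + 8 * sin(seq(0, pi, length.out = 7L)) + jit(7L), xs)
  # ridge 2: diagonal across the lower half
  r2 <- cbind(seq(nr * 0.55, nr * 0.92, length.out = 7L) + jit(7L),
              seq(1, nc, length.out = 7L))
  # dark curve: arc through the middle third
  r3 <- cbind(nr * 0.45 + 14 * sin(seq(0, pi, length.out = 9L)) + jit(9L),
              seq(1, nc, length.out = 9L))
  spots <- list(
    list(center = c(nr * 0.12, nc * 0.18) + jit(2L), amplitude = 80,
         radius = 3),
    list(center = c(nr * 0.70, nc * 0.15) + jit(2L), amplitude = 80,
         radius = 3),
    list(center = c(nr * 0.32, nc * 0.80) + jit(2L), amplitude = -80,
         radius = 3),
    list(center = c(nr * 0.85, nc * 0.60) + jit(2L), amplitude = 80,
         radius = 3))
  phantom_spec(size = size, background = c(70, 120, 170),
               ridges = list(list(points = r1, amplitude = 70, width = 2),
                             list(points = r2, amplitude = 60, width = 2),
                             list(points = r3, amplitude = -60, width = 2)),
               spots = spots, seed = seed)
}

# distance from every pixel to a polyline (minimum over segments)
polyline_distance <- function(nr, nc, points) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- pmin(d2, (rr - a[1L])^2 + (cc - a[2L])^2)
      next
    }
    t <- ((rr - a[1L]) * ab[1L] + (cc - a[2L]) * ab[2L]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- pmin(d2, (rr - (a[1L] + t * ab[1L]))^2 +
                   (cc - (a[2L] + t * ab[2L]))^2)
  }
  sqrt(d2)
}

#' Ground-truth codes used by [make_phantom()]
#'
#' `dontcare` = 0 (near structure borders or overlaps; excluded from
#' scoring), `flat` = 1 (flat-region interior), `crest_linear` = 2 (crest of
#' a bright ridge), `crest_boundary` = 3 (trough of a dark curve),
#' `spot_center` = 4.
#'
#' @return Named integer vector of truth codes.
#' @export
truth_types <- function() {
  c(dontcare = 0L, flat = 1L, crest_linear = 2L, crest_boundary = 3L,
    spot_center = 4L)
}

#' Render a phantom and its ground truth
#'
#' Flat vertical bands are drawn at the background intensities, ridges are
#' added as polylines with Gaussian cross-section, spots as isotropic
#' Gaussian bumps; the sum is clipped to \[0, 255\]. The truth mask marks
#' ridge-crest pixels (distance to the polyline <= 0.5 px), spot centers,
#' and flat interiors; pixels under the influence of any structure (within
#' 4 cross-section widths / radii), near band borders, or claimed by two
#' structures at once are marked don't-care.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [gray_image()]) and `truth` (integer matrix
#'   of [truth_types()] codes).
#' @export
make_phantom <- function(spec = default_phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must come from phantom_spec()", call. = FALSE)
  nr <- spec$size[1L]; nc <- spec$size[2L]
  nb <- length(spec$background)
  band <- pmin(((seq_len(nc) - 1L) * nb) %/% nc + 1L, nb)
  m <- matrix(spec$background[band], nr, nc, byrow = TRUE)

  tt <- truth_types()
  truth <- matrix(tt[["flat"]], nr, nc)
  # band borders: an 8 px margin on either side is don't-care
  if (nb > 1L) {
    edges <- which(diff(band) != 0L)
    for (e in edges) {
      cols <- pmax(1L, e - 7L):pmin(nc, e + 8L)
      truth[, cols] <- tt[["dontcare"]]
    }
  }
  claims <- matrix(0L, nr, nc)   # structures claiming each crest pixel

  for (rg in spec$ridges) {
    d <- polyline_distance(nr, nc, rg$points)
    m <- m + rg$amplitude * exp(-d^2 / (2 * rg$width^2))
    infl <- d <= 4 * rg$width
    crest <- d <= 0.5
    truth[infl & !crest] <- tt[["dontcare"]]
    code <- if (rg$amplitude >= 0) tt[["crest_linear"]] else
      tt[["crest_boundary"]]
    truth[crest & truth != tt[["dontcare"]]] <- code
    truth[crest & claims > 0L] <- tt[["dontcare"]]  # overlap -> don't-care
    claims[crest] <- claims[crest] + 1L
  }
  for (sp in spec$spots) {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    d <- sqrt((rr - sp$center[1L])^2 + (cc - sp$center[2L])^2)
    m <- m + sp$amplitude * exp(-d^2 / (2 * sp$radius^2))
    infl <- d <= 4 * sp$radius
    ctr <- round(sp$center)
    overlap <- truth[ctr[1L], ctr[2L]] != tt[["flat"]] &&
      truth[ctr[1L], ctr[2L]] != tt[["dontcare"]]
    truth[infl] <- tt[["dontcare"]]
    truth[ctr[1L], ctr[2L]] <- if (overlap) tt[["dontcare"]] else
      tt[["spot_center"]]
  }
  list(image = gray_image(clip255(m)), truth = truth)
}

#' Load a phantom specification from YAML
#'
#' The YAML mirrors [phantom_spec()]: scalar `seed`, `size` (2 ints),
#' `background` (list of intensities), `ridges` (each with `points` as a
#' flat list of row,col pairs, `amplitude`, `width`) and `spots` (each with
#' `center`, `amplitude`, `radius`).
#'
#' @param path YAML file path.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  ridges <- lapply(y$ridges %||% list(), function(rg) {
    list(points = matrix(unlist(rg$points), ncol = 2L, byrow = TRUE),
         amplitude = rg$amplitude, width = rg$width)
  })
  spots <- lapply(y$spots %||% list(), function(sp) {
    list(center = unlist(sp$center), amplitude = sp$amplitude,
         radius = sp$radius)
  })
  phantom_spec(size = unlist(y$size %||% c(256L, 256L)),
               background = unlist(y$background %||% c(70, 120, 170)),
               ridges = ridges, spots = spots, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- quality metrics --------------------------------------------------------

#' Peak signal-to-noise ratio
#'
#' `10 log10(255^2 / MSE)` in dB for 8-bit-range images; identical images
#' (zero MSE) are reported as the 100 dB cap.
#'
#' @param a,b [gray_image()]s of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b) {
  assert_gray(a, "a"); assert_gray(b, "b")
  if (!all(dim(a) == dim(b)))
    stop("images must have the same shape", call. = FALSE)
  mse <- mean((as_matrix(a) - as_matrix(b))^2)
  if (mse == 0) return(100)
  min(10 * log10(255^2 / mse), 100)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the reference formulation: 11 x 11 Gaussian window
#' (sigma 1.5, normalized to sum 1), K1 = 0.01, K2 = 0.03, dynamic range
#' L = 255, local statistics from valid (fully interior) windows only.
#'
#' @param a,b [gray_image()]s of the same shape; both dimensions must be at
#'   least 11.
#' @return Mean SSIM in \[-1, 1\].
#' @export
ssim <- function(a, b) {
  assert_gray(a, "a"); assert_gray(b, "b")
  if (!all(dim(a) == dim(b)))
    stop("images must have the same shape", call. = FALSE)
  if (any(dim(a) < 11L))
    stop("images must be at least 11 x 11 for SSIM", call. = FALSE)
  x <- as_matrix(a); y <- as_matrix(b)
  w <- gauss_kernel(1.5, radius = 5L)   # 11-tap, sums to 1
  conv_valid <- function(m) {
    nr <- nrow(m) - 10L; nc <- ncol(m) - 10L
    tmp <- matrix(0, nrow(m), nc)
    for (i in 1:11) tmp <- tmp + w[i] * m[, (i - 1L) + seq_len(nc)]
    out <- matrix(0, nr, nc)
    for (j in 1:11) out <- out + w[j] * tmp[(j - 1L) + seq_len(nr), ]
    out
  }
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  mx <- conv_valid(x); my <- conv_valid(y)
  sxx <- conv_valid(x * x) - mx^2
  syy <- conv_valid(y * y) - my^2
  sxy <- conv_valid(x * y) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(smap)
}

# ---- baselines and benchmark ------------------------------------------------

#' Baseline full-image Gaussian filter
#'
#' The plain isotropic Gaussian comparator (default sigma 1.0).
#'
#' @param img A [gray_image()].
#' @param sigma Standard deviation in pixels.
#' @return The filtered [gray_image()].
#' @export
baseline_gaussian <- function(img, sigma = 1.0) gaussian2d(img, sigma)

#' Baseline full-image median filter
#'
#' The plain square-window median comparator (default 7 x 7).
#'
#' @param img A [gray_image()].
#' @param size Odd window side.
#' @return The filtered [gray_image()].
#' @export
baseline_median <- function(img, size = 7L) {
  assert_gray(img)
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    stop("`size` must be odd and >= 3", call. = FALSE)
  gray_image(median_filter_full(as_matrix(img), size))
}

#' Run the corrupt / filter / score benchmark
#'
#' For every (image, sigma, method) combination: corrupt the clean image
#' with [multiplicative_rayleigh()], filter it, and score PSNR and SSIM
#' against the clean image. The method `"proposed"` is the despeckling
#' pipeline scored after each of `passes` passes (one row per pass, with
#' equalization off so scores are comparable to the unequalized reference);
#' `"identity"` scores the noisy image itself; `"gaussian"` and `"median"`
#' are the baselines. A named function in `methods` is applied as-is
#' (`function(gray_image) gray_image`), so external comparators can be
#' plugged in.
#'
#' @param images Named list of clean [gray_image()]s (a bare `gray_image`
#'   is accepted).
#' @param sigmas Numeric vector of noise levels.
#' @param methods Character names among `identity`, `gaussian`, `median`,
#'   `proposed`, and/or named filter functions.
#' @param passes Passes scored for the proposed method.
#' @param seed Integer seed; each (image, sigma) cell gets a distinct noise
#'   realization derived from it.
#' @param csv_path Optional path; when given the report is also written as
#'   CSV.
#' @return Data frame with columns `image`, `sigma`, `method`, `pass`,
#'   `psnr_db`, `ssim`.
#' @export
run_benchmark <- function(images, sigmas, methods = c("identity", "gaussian",
                                                      "median", "proposed"),
                          passes = 3L, seed = 1L, csv_path = NULL) {
  if (inherits(images, "gray_image")) images <- list(image = images)
  if (is.null(names(images)) || any(!nzchar(names(images))))
    names(images) <- paste0("image", seq_along(images))
  passes <- as.integer(passes)
  method_names <- if (is.character(methods)) methods else names(methods)
  if (is.null(method_names) || any(!nzchar(method_names)))
    stop("`methods` must be method names or a named list of functions",
         call. = FALSE)

  rows <- list()
  cell <- 0L
  for (im in names(images)) {
    clean <- images[[im]]
    assert_gray(clean, im)
    for (sg in sigmas) {
      cell <- cell + 1L
      noisy <- multiplicative_rayleigh(clean, sg,
                                       seed = (seed + 7919L * cell) %% .Machine$integer.max)
      for (k in seq_along(method_names)) {
        mn <- method_names[k]
        fun <- if (is.list(methods)) methods[[k]] else NULL
        if (!is.null(fun) && is.function(fun)) {
          scored <- list(list(pass = 1L, img = fun(noisy)))
        } else {
          scored <- switch(mn,
            identity = list(list(pass = 1L, img = noisy)),
            gaussian = list(list(pass = 1L, img = baseline_gaussian(noisy))),
            median   = list(list(pass = 1L, img = baseline_median(noisy))),
            proposed = {
              cfg <- pipeline_config(passes = 1L,
                                     equalize_each_pass = FALSE)
              cur <- noisy
              lapply(seq_len(passes), function(p) {
                cur <<- despeckle(cur, cfg)$image
                list(pass = p, img = cur)
              })
            },
            stop(sprintf("unknown method '%s'", mn), call. = FALSE))
        }
        for (s in scored) {
          rows[[length(rows) + 1L]] <- data.frame(
            image = im, sigma = sg, method = mn, pass = s$pass,
            psnr_db = psnr(clean, s$img), ssim = ssim(clean, s$img))
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(csv_path)) write.csv(report, csv_path, row.names = FALSE)
  report
}
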