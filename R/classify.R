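# Structure classification: turn the normalized tensor field into per-pixel
# feature responses and a five-type structure map, then refine the map so
# that broken curvilinear structures are reconnected.
#
# Label semantics (from the sign of the major eigenvalue): a LINEAR pixel
# sits on a bright ridge (local intensity maximum across the structure,
# lam1 <= 0), a BOUNDARY pixel on a dark valley (lam1 > 0), a SPOT pixel on
# an isotropic intensity concentration, a UNIFORM pixel in a featureless
# region; UNKNOWN collects everything the rules cannot decide.

#' Structure type codes
#'
#' Integer codes used in a `structure_map`: uniform = 1, linear = 2,
#' boundary = 3, spot = 4, unknown = 5.
#'
#' @return Named integer vector of the five codes.
#' @export
structure_types <- function() {
  c(uniform = 1L, linear = 2L, boundary = 3L, spot = 4L, unknown = 5L)
}

TYPE_UNIFORM  <- 1L
TYPE_LINEAR   <- 2L
TYPE_BOUNDARY <- 3L
TYPE_SPOT     <- 4L
TYPE_UNKNOWN  <- 5L

#' Classifier parameters
#'
#' @param beta Feature-strength threshold: pixels with `T1 <= beta` are
#'   uniform. Default 0.12.
#' @param alpha Spot-strength threshold guarding against labeling noisy
#'   regions as spots: a spot additionally requires `T1 >= alpha`. Default
#'   0.45. Must satisfy `0 < beta < alpha < 2`.
#' @param epsilon Guard constant added to numerator and denominator of the
#'   eigenvalue-ratio response `T2`; keeps `T2 = 1` (isotropy) when both
#'   eigenvalues vanish. Default 1e-6.
#' @param refine_iters Number of refinement sweeps over the spot/unknown
#'   queue. Default 3.
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(beta = 0.12, alpha = 0.45, epsilon = 1e-6,
                              refine_iters = 3L) {
  if (!(is.numeric(beta) && is.numeric(alpha) && beta > 0 && beta < alpha &&
        alpha < 2))
    stop("need 0 < beta < alpha < 2", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("`epsilon` must be > 0", call. = FALSE)
  refine_iters <- as.integer(refine_iters)
  if (is.na(refine_iters) || refine_iters < 0L)
    stop("`refine_iters` must be >= 0", call. = FALSE)
  structure(list(beta = beta, alpha = alpha, epsilon = epsilon,
                 refine_iters = refine_iters),
            class = "classifier_params")
}

assert_classifier_params <- function(params) {
  if (!inherits(params, "classifier_params"))
    stop("`params` must come from classifier_params()", call. = FALSE)
  invisible(params)
}

#' Feature responses from normalized eigenvalues
#'
#' Computes, per pixel, the feature strength `T1 = lam1^2 + lam2^2`, the
#' isotropy ratio `T2 = (|lam2| + eps) / (|lam1| + eps)`, and the linearity
#' and spot responses `Cl = T1 (1 - T2)`, `Cs = T1 T2`. With eigenvalues
#' normalized to \[-1, 1\], `T1` lies in \[0, 2\] and `Cl + Cs = T1`
#' identically.
#'
#' @param lam1n,lam2n Normalized major/minor eigenvalues (vectors or
#'   matrices, `|lam1n| >= |lam2n|`, both in \[-1, 1\]).
#' @param epsilon Guard constant (> 0), see [classifier_params()].
#' @return List with components `t1`, `t2`, `cl`, `cs` shaped like the
#'   input.
#' @export
responses <- function(lam1n, lam2n, epsilon = 1e-6) {
  t1 <- lam1n^2 + lam2n^2
  t2 <- (abs(lam2n) + epsilon) / (abs(lam1n) + epsilon)
  list(t1 = t1, t2 = t2, cl = t1 * (1 - t2), cs = t1 * t2)
}

#' Classify one pixel (vectorized)
#'
#' Applies the decision rules in their printed order: (i) `T1 <= beta` is
#' uniform; (ii) `T1 > beta`, `Cl > Cs`, `lam1 <= 0` is linear (bright
#' ridge); (iii) `T1 > beta`, `Cl > Cs`, `lam1 > 0` is boundary (dark
#' valley); (iv) `T1 >= alpha`, `Cs > Cl` is spot; (v) anything else is
#' unknown. A tie `Cl = Cs` falls through to rules (iv)/(v).
#'
#' @param t1,cl,cs Responses from [responses()].
#' @param lam1n Normalized major eigenvalue.
#' @param params A [classifier_params()].
#' @return Integer type codes (see [structure_types()]), shaped like `t1`.
#' @export
classify_pixel <- function(t1, cl, cs, lam1n, params = classifier_params()) {
  assert_classifier_params(params)
  lab <- rep.int(TYPE_UNKNOWN, length(t1))
  lab[t1 >= params$alpha & cs > cl] <- TYPE_SPOT
  lin <- t1 > params$beta & cl > cs
  lab[lin & lam1n <= 0] <- TYPE_LINEAR
  lab[lin & lam1n > 0] <- TYPE_BOUNDARY
  lab[t1 <= params$beta] <- TYPE_UNIFORM
  if (is.matrix(t1)) lab <- matrix(lab, nrow(t1), ncol(t1))
  lab
}

new_structure_map <- function(labels) {
  structure(labels, class = c("structure_map", "matrix", "array"))
}

#' @export
print.structure_map <- function(x, ...) {
  tab <- tabulate(unclass(x), nbins = 5L)
  cat(sprintf("<structure_map> %d x %d\n", nrow(x), ncol(x)))
  print(stats::setNames(tab, names(structure_types())))
  invisible(x)
}

#' Classify every pixel of a normalized tensor field
#'
#' @param tf A normalized `tensor_field` (see [normalize_field()]).
#' @param params A [classifier_params()].
#' @return List with `responses` (list of matrices `t1`, `t2`, `cl`, `cs`)
#'   and `map` (a `structure_map` of integer type codes).
#' @export
classify_field <- function(tf, params = classifier_params()) {
  if (!inherits(tf, "tensor_field") || !isTRUE(tf$normalized))
    stop("`tf` must be a normalized tensor_field (see normalize_field())",
         call. = FALSE)
  assert_classifier_params(params)
  resp <- responses(tf$lam1, tf$lam2, params$epsilon)
  lab <- classify_pixel(resp$t1, resp$cl, resp$cs, tf$lam1, params)
  list(responses = resp, map = new_structure_map(lab))
}

#' Refine a structure map along the minor eigenvector
#'
#' Tissue boundary segments with high curvature echo weakly and come out of
#' the initial classification as isolated spot or unknown pixels, breaking
#' otherwise continuous curves. The refinement queues all spot and unknown
#' pixels in raster (row-major) order and, for each, inspects the two
#' neighbors at `round(p +/- v2)` — one step along each direction of the
#' minor eigenvector, i.e. along the putative curve. If either neighbor is
#' linear the pixel becomes linear; otherwise if either is boundary it
#' becomes boundary; otherwise it is left for the next sweep. Relabeling
#' takes effect immediately, so a repaired pixel can propagate within the
#' same sweep. The queue is rebuilt and swept `refine_iters` times.
#' Uniform, linear and boundary pixels are never altered. Off-image
#' neighbors are ignored; a pixel with a zero minor eigenvector is kept
#' unchanged.
#'
#' @param map A `structure_map`.
#' @param tf The `tensor_field` (with eigensystem) the map came from.
#' @param params A [classifier_params()]; `refine_iters` controls the number
#'   of sweeps.
#' @return The refined `structure_map`.
#' @export
refine <- function(map, tf, params = classifier_params()) {
  if (!inherits(map, "structure_map"))
    stop("`map` must be a structure_map", call. = FALSE)
  if (!inherits(tf, "tensor_field") || !isTRUE(tf$has_eigen))
    stop("`tf` must be a tensor_field with the eigensystem computed",
         call. = FALSE)
  if (!all(dim(map) == tf$dim))
    stop("`map` and `tf` must have the same shape", call. = FALSE)
  assert_classifier_params(params)

  lab <- unclass(map)
  nr <- nrow(lab); nc <- ncol(lab)
  v2x <- tf$v2x; v2y <- tf$v2y

  for (sweep in seq_len(params$refine_iters)) {
    # raster order: row by row, left to right
    idx <- which(t(lab == TYPE_SPOT | lab == TYPE_UNKNOWN))
    if (!length(idx)) break
    cs <- (idx - 1L) %/% nc + 1L   # row of t() index = image row
    rs <- cs
    cs <- (idx - 1L) %% nc + 1L
    changed <- FALSE
    for (q in seq_along(rs)) {
      r <- rs[q]; cc <- cs[q]
      dx <- v2x[r, cc]; dy <- v2y[r, cc]
      if (dx == 0 && dy == 0) next
      new_lab <- 0L
      for (s in c(1, -1)) {
        rn <- as.integer(round(r + s * dy))
        cn <- as.integer(round(cc + s * dx))
        if (rn < 1L || rn > nr || cn < 1L || cn > nc) next
        nb <- lab[rn, cn]
        if (nb == TYPE_LINEAR) { new_lab <- TYPE_LINEAR; break }
        if (nb == TYPE_BOUNDARY && new_lab == 0L) new_lab <- TYPE_BOUNDARY
      }
      if (new_lab != 0L) {
        lab[r, cc] <- new_lab   # immediate update, visible to later pixels
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  new_structure_map(lab)
}

#' Export a structure map as a color PNG
#'
#' Renders the map with the conventional debugging palette: grey = uniform,
#' green = linear, dark green = boundary, red = spot, blue = unknown.
#'
#' @param map A `structure_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_typemap <- function(map, path) {
  if (!inherits(map, "structure_map"))
    stop("`map` must be a structure_map", call. = FALSE)
  pal <- matrix(c(0.62, 0.62, 0.62,   # uniform: grey
                  0.00, 0.80, 0.00,   # linear: green
                  0.00, 0.39, 0.00,   # boundary: dark green
                  1.00, 0.00, 0.00,   # spot: red
                  0.00, 0.00, 1.00),  # unknown: blue
                nrow = 5L, byrow = TRUE)
  lab <- unclass(map)
  rgb <- array(0, c(nrow(lab), ncol(lab), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[lab, ch], nrow(lab), ncol(lab))
  png::writePNG(rgb, path)
  invisible(path)
}
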