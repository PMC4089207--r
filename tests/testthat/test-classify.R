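test_that("feature responses match hand-computed values and identities", {
  r <- responses(-1, 0, 1e-6)
  expect_equal(r$t1, 1)
  expect_equal(r$t2, 1e-6 / (1 + 1e-6))
  expect_equal(r$cl, 1 - r$t2)
  # both eigenvalues zero: epsilon/epsilon keeps the ratio at 1 (isotropy)
  r <- responses(0, 0, 1e-6)
  expect_equal(unlist(r), c(t1 = 0, t2 = 1, cl = 0, cs = 0))
  r <- responses(0.9, 0.85, 1e-6)
  expect_equal(r$t1, 1.5325)
  expect_equal(r$t2, (0.85 + 1e-6) / (0.9 + 1e-6), tolerance = 1e-12)
  expect_equal(r$cl, 0.0851, tolerance = 1e-3)
  expect_equal(r$cs, 1.4473, tolerance = 1e-4)

  # Cl + Cs = T1 identically; T1 in [0, 2] for normalized eigenvalues
  set.seed(4)
  l1 <- runif(5000, -1, 1)
  l2 <- runif(5000, -1, 1)
  swap <- abs(l2) > abs(l1)
  tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
  r <- responses(l1, l2, 1e-6)
  expect_lt(max(abs(r$cl + r$cs - r$t1)), 1e-12)
  expect_true(all(r$t1 >= 0 & r$t1 <= 2))
  expect_true(all(r$t2 >= 0))
})

test_that("pixel rules reproduce the decision table", {
  p <- classifier_params()
  lab1 <- function(l1, l2) {
    r <- responses(l1, l2, p$epsilon)
    classify_pixel(r$t1, r$cl, r$cs, l1, p)
  }
  expect_equal(lab1(0.3, 0), ST[["uniform"]])      # T1 = 0.09 <= 0.12
  expect_equal(lab1(-0.8, 0.1), ST[["linear"]])    # Cl > Cs, lam1 < 0
  expect_equal(lab1(0.8, 0.1), ST[["boundary"]])   # Cl > Cs, lam1 > 0
  expect_equal(lab1(-0.9, -0.85), ST[["spot"]])    # T1 = 1.53 >= alpha
  expect_equal(lab1(0.45, 0.40), ST[["unknown"]])  # spot-ish but T1 < alpha
  expect_error(classify_pixel(1, 0.5, 0.5, 1, list()), "classifier_params")
})

test_that("classification is invariant to eigenvalue rescaling", {
  set.seed(9)
  p <- classifier_params()
  l1 <- runif(400, -1, 1)
  l2 <- runif(400) * abs(l1) * sign(runif(400, -1, 1))
  lab <- function(a, b) {
    m <- max(abs(a))          # renormalize to [-1, 1]
    r <- responses(a / m, b / m, p$epsilon)
    classify_pixel(r$t1, r$cl, r$cs, a / m, p)
  }
  base <- lab(l1, l2)
  for (k in c(0.25, 3, 17)) expect_identical(lab(k * l1, k * l2), base)
})

test_that("field classification finds uniform regions, ridges and blobs", {
  # constant image: every pixel uniform
  tf <- normalize_field(compute_eigensystem(
    hessian_field(gray_image(matrix(90, 64, 64)), 1.4)))
  cls <- classify_field(tf)
  expect_true(all(cls$map == ST[["uniform"]]))
  expect_equal(dim(cls$responses$t1), c(64L, 64L))

  # un-normalized field is rejected
  expect_error(classify_field(compute_eigensystem(
    hessian_field(gray_image(matrix(90, 64, 64)), 1.4))), "normalized")

  # bright ridge: crest pixels (away from the frame) are linear
  img <- ridge_image(64, 64, row = 32)
  tf <- normalize_field(compute_eigensystem(hessian_field(img, 1.4)))
  cls <- classify_field(tf)
  expect_true(all(cls$map[32, 8:56] == ST[["linear"]]))

  # bright Gaussian blob: center pixel is a spot
  d2 <- (matrix(seq_len(64), 64, 64) - 32)^2 +
    (matrix(rep(seq_len(64), each = 64), 64, 64) - 32)^2
  blob <- gray_image(100 + 80 * exp(-d2 / (2 * 3^2)))
  tf <- normalize_field(compute_eigensystem(hessian_field(blob, 1.4)))
  cls <- classify_field(tf)
  expect_equal(cls$map[32, 32], ST[["spot"]], ignore_attr = TRUE)
})

test_that("refinement follows the minor eigenvector with linear precedence", {
  nr <- 7L; nc <- 7L
  v2x <- matrix(1, nr, nc); v2y <- matrix(0, nr, nc)   # v2 along x
  tf <- fake_tensor_field(nr, nc, v2x, v2y)

  # a map with no spot/unknown pixels is untouched
  lab <- matrix(ST[["uniform"]], nr, nc)
  lab[4, ] <- ST[["linear"]]
  expect_identical(unclass(refine(label_map(lab), tf)), lab)

  # single spot with linear pixels at both horizontal neighbors -> linear
  lab <- matrix(ST[["uniform"]], nr, nc)
  lab[4, c(3, 5)] <- ST[["linear"]]
  lab[4, 4] <- ST[["spot"]]
  out <- refine(label_map(lab), tf)
  expect_equal(out[4, 4], ST[["linear"]], ignore_attr = TRUE)

  # one boundary and one linear neighbor: linear wins
  lab[4, 3] <- ST[["boundary"]]
  out <- refine(label_map(lab), tf)
  expect_equal(out[4, 4], ST[["linear"]], ignore_attr = TRUE)

  # boundary-only neighborhood relabels to boundary
  lab[4, c(3, 5)] <- ST[["boundary"]]
  out <- refine(label_map(lab), tf)
  expect_equal(out[4, 4], ST[["boundary"]], ignore_attr = TRUE)

  # refine_iters = 0 is a no-op
  lab[4, 4] <- ST[["spot"]]
  p0 <- classifier_params(refine_iters = 0L)
  expect_identical(unclass(refine(label_map(lab), tf, p0)), lab)

  # neighbors off the image edge are ignored, not an error
  lab <- matrix(ST[["unknown"]], nr, nc)
  expect_no_error(refine(label_map(lab), tf))
})

test_that("refinement only ever shrinks the spot/unknown set", {
  ph <- make_phantom(default_phantom_spec(seed = 2, size = c(96L, 96L)))
  noisy <- multiplicative_rayleigh(ph$image, 0.3, seed = 8)
  tf <- normalize_field(compute_eigensystem(hessian_field(noisy, 1.4)))
  cls <- classify_field(tf)
  prev <- cls$map
  n_prev <- sum(prev == ST[["spot"]] | prev == ST[["unknown"]])
  p1 <- classifier_params(refine_iters = 1L)
  for (sweep in 1:3) {
    cur <- refine(prev, tf, p1)
    # uniform / linear / boundary pixels are never altered
    keep <- prev == ST[["uniform"]] | prev == ST[["linear"]] |
      prev == ST[["boundary"]]
    expect_true(all(cur[keep] == prev[keep]))
    # changed pixels only ever become linear or boundary
    ch <- cur != prev
    expect_true(all(cur[ch] %in% c(ST[["linear"]], ST[["boundary"]])))
    n_cur <- sum(cur == ST[["spot"]] | cur == ST[["unknown"]])
    expect_lte(n_cur, n_prev)
    prev <- cur
    n_prev <- n_cur
  }
})

test_that("a one-pixel gap punched into a ridge is healed to linear", {
  img <- ridge_image(64, 64, row = 32)
  tf <- normalize_field(compute_eigensystem(hessian_field(img, 1.4)))
  cls <- classify_field(tf)
  lab <- unclass(cls$map)
  expect_equal(lab[32, 30], ST[["linear"]])
  lab[32, 30] <- ST[["spot"]]      # deliberate break in the crest
  out <- refine(label_map(lab), tf)
  expect_equal(out[32, 30], ST[["linear"]], ignore_attr = TRUE)
})

test_that("structure maps export as a paletted PNG", {
  lab <- matrix(rep(1:5, length.out = 30), 5, 6)
  p <- withr::local_tempfile(fileext = ".png")
  write_typemap(label_map(lab), p)
  a <- png::readPNG(p)
  expect_equal(dim(a), c(5, 6, 3))
  expect_equal(a[1, 1, ], c(0.62, 0.62, 0.62), tolerance = 0.01)
})
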