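test_that("multiplicative Rayleigh noise has the designed moments", {
  img <- gray_image(matrix(128, 512, 512))
  expect_identical(unclass(multiplicative_rayleigh(img, 0)), unclass(img))

  noisy <- multiplicative_rayleigh(img, 0.3, seed = 1)
  n <- unclass(noisy) / 128
  expect_equal(mean(n), 1, tolerance = 0.01)
  expect_equal(sd(n), 0.3, tolerance = 0.01)

  # reproducibility: same seed bit-identical, different seeds different
  a <- multiplicative_rayleigh(img, 0.2, seed = 11)
  b <- multiplicative_rayleigh(img, 0.2, seed = 11)
  cc <- multiplicative_rayleigh(img, 0.2, seed = 12)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(cc)))
  expect_equal(sd(unclass(cc) / 128), 0.2, tolerance = 0.01)

  expect_error(multiplicative_rayleigh(img, -0.1), ">= 0")
})

test_that("noise PSNR on a constant image matches the closed form", {
  img <- gray_image(matrix(128, 512, 512))
  noisy <- multiplicative_rayleigh(img, 0.1, seed = 2)
  # E[(I - I n)^2] = I^2 sigma^2 -> 10 log10(255^2 / 12.8^2)
  expect_equal(psnr(img, noisy), 10 * log10(255^2 / (128 * 0.1)^2),
               tolerance = 0.1)
})

test_that("PSNR definition, symmetry and caps", {
  a <- random_image(24, 24, seed = 3)
  b <- random_image(24, 24, seed = 4)
  expect_equal(psnr(a, b), psnr(b, a))
  expect_equal(psnr(a, a), 100)   # zero-MSE cap
  expect_equal(psnr(gray_image(matrix(0, 8, 8)),
                    gray_image(matrix(255, 8, 8))), 0)
  expect_equal(psnr(gray_image(matrix(100, 8, 8)),
                    gray_image(matrix(101, 8, 8))), 48.1308,
               tolerance = 1e-4)
  expect_error(psnr(a, gray_image(matrix(1, 3, 3))), "shape")
})

test_that("SSIM matches its reference behavior and the brute-force oracle", {
  a <- random_image(24, 24, seed = 5)
  expect_equal(ssim(a, a), 1)
  inv <- gray_image(255 - unclass(a))
  expect_lt(ssim(a, inv), 0.5)
  off <- gray_image(pmin(unclass(a) + 4, 255))
  s <- ssim(a, off)
  expect_gt(s, 0.9); expect_lt(s, 1)

  for (seed in c(6, 7)) {
    x <- random_image(20, 23, seed = seed)
    y <- multiplicative_rayleigh(x, 0.2, seed = seed + 50)
    expect_equal(ssim(x, y), ssim_bruteforce(x, y), tolerance = 1e-6)
  }
  expect_error(ssim(gray_image(matrix(1, 8, 8)),
                    gray_image(matrix(1, 8, 8))), "11")
})

test_that("phantom renders the declared structures with coherent truth", {
  # no structures: constant image, all-flat truth
  sp <- phantom_spec(size = c(64L, 64L), background = 90, seed = 1)
  ph <- make_phantom(sp)
  expect_true(all(unclass(ph$image) == 90))
  expect_true(all(ph$truth == TT[["flat"]]))

  # one horizontal bright ridge: crest row marked linear-truth
  pts <- cbind(rep(32, 2), c(1, 64))
  sp <- phantom_spec(size = c(64L, 64L), background = 90,
                     ridges = list(list(points = pts, amplitude = 70,
                                        width = 2)), seed = 1)
  ph <- make_phantom(sp)
  expect_true(all(ph$truth[32, ] == TT[["crest_linear"]]))
  expect_equal(max(unclass(ph$image)), 160, tolerance = 0.01)
  # dark ridge gets boundary-truth
  spd <- phantom_spec(size = c(64L, 64L), background = 90,
                      ridges = list(list(points = pts, amplitude = -60,
                                         width = 2)), seed = 1)
  expect_true(all(make_phantom(spd)$truth[32, ] == TT[["crest_boundary"]]))

  # one blob: center marked spot-truth, surroundings don't-care
  sp <- phantom_spec(size = c(64L, 64L), background = 90,
                     spots = list(list(center = c(20, 40), amplitude = 80,
                                       radius = 3)), seed = 1)
  ph <- make_phantom(sp)
  expect_equal(ph$truth[20, 40], TT[["spot_center"]])
  expect_equal(ph$truth[20, 42], TT[["dontcare"]])
  expect_equal(unclass(ph$image)[20, 40], 170, tolerance = 0.01)

  # phantom specs round-trip through YAML
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "size: [64, 64]",
    "background: [90]",
    "seed: 1",
    "ridges:",
    "  - points: [[32, 1], [32, 64]]",
    "    amplitude: 70",
    "    width: 2",
    "spots:",
    "  - center: [20, 40]",
    "    amplitude: 80",
    "    radius: 3"), p)
  spy <- read_phantom_spec(p)
  expect_s3_class(spy, "phantom_spec")
  phy <- make_phantom(spy)
  expect_true(all(phy$truth[32, 10] == TT[["crest_linear"]]))
})

test_that("baseline filters behave like their textbook versions", {
  const <- gray_image(matrix(44, 16, 16))
  expect_equal(unclass(baseline_gaussian(const)), unclass(const),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(baseline_median(const)), unclass(const),
               ignore_attr = TRUE)
  # impulse through the 7x7 median: 1 of 49 samples, removed
  imp <- matrix(0, 15, 15); imp[8, 8] <- 255
  expect_equal(unclass(baseline_median(gray_image(imp)))[8, 8], 0)
  # ramp through the sigma-1 Gaussian: interior unchanged
  ramp <- gray_image(matrix(rep(seq(5, 95, length.out = 16), each = 16),
                            16, 16, byrow = TRUE))
  expect_equal(unclass(baseline_gaussian(ramp))[6:11, 6:11],
               unclass(ramp)[6:11, 6:11], tolerance = 1e-9)
})

test_that("benchmark report has the protocol's shape and semantics", {
  ph <- make_phantom(default_phantom_spec(seed = 6, size = c(96L, 96L)))
  p <- withr::local_tempfile(fileext = ".csv")
  rep <- run_benchmark(list(phantom = ph$image), sigmas = c(0.1, 0.3),
                       methods = c("identity", "gaussian", "median",
                                   "proposed"),
                       passes = 2L, seed = 10, csv_path = p)
  # rows = |images| * |sigmas| * (1 + 1 + 1 + passes)
  expect_equal(nrow(rep), 1L * 2L * (3L + 2L))
  expect_named(rep, c("image", "sigma", "method", "pass", "psnr_db", "ssim"))
  expect_true(all(is.finite(rep$psnr_db)) && all(is.finite(rep$ssim)))
  expect_true(all(rep$ssim >= -1 & rep$ssim <= 1))
  expect_true(file.exists(p))
  expect_equal(nrow(read.csv(p)), nrow(rep))

  # identity rows score the noisy image itself
  ident <- rep[rep$method == "identity" & rep$sigma == 0.3, ]
  noisy <- multiplicative_rayleigh(ph$image, 0.3,
                                   seed = (10 + 7919 * 2) %% .Machine$integer.max)
  expect_equal(ident$psnr_db, psnr(ph$image, noisy))

  # a plugged-in external filter callable is accepted
  rep2 <- run_benchmark(list(phantom = ph$image), sigmas = 0.1,
                        methods = list(identity = "identity",
                                       blur3 = function(im) gaussian2d(im, 3)),
                        passes = 1L, seed = 10)
  expect_equal(nrow(rep2), 2L)
  expect_error(run_benchmark(ph$image, 0.1, methods = "frobnicate",
                             seed = 1), "unknown method")
})
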