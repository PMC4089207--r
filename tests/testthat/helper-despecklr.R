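# Shared fixtures and independent oracles, built in code at test time.

# Independent SSIM oracle: direct per-window evaluation with an explicit
# 11 x 11 Gaussian weight matrix (no separable convolution, no shared code
# with ssim()).
ssim_bruteforce <- function(a, b) {
  x <- unclass(a); y <- unclass(b)
  g <- exp(-(-5:5)^2 / (2 * 1.5^2))
  w <- outer(g, g)
  w <- w / sum(w)
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  vals <- c()
  for (r in 6:(nrow(x) - 5)) {
    for (cc in 6:(ncol(x) - 5)) {
      wx <- x[(r - 5):(r + 5), (cc - 5):(cc + 5)]
      wy <- y[(r - 5):(r + 5), (cc - 5):(cc + 5)]
      mx <- sum(w * wx); my <- sum(w * wy)
      vx <- sum(w * wx^2) - mx^2
      vy <- sum(w * wy^2) - my^2
      cxy <- sum(w * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                        ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# Random test image with mixed smooth + rough content.
random_image <- function(nr = 32L, nc = nr, seed = 1L) {
  set.seed(seed)
  base <- outer(seq_len(nr), seq_len(nc),
                function(r, c) 120 + 60 * sin(r / 7) * cos(c / 9))
  gray_image(pmin(pmax(base + matrix(rnorm(nr * nc, sd = 20), nr, nc),
                       0), 255))
}

# Single straight horizontal bright ridge with Gaussian cross-section.
ridge_image <- function(nr = 64L, nc = 64L, row = nr %/% 2L,
                        amplitude = 70, width = 2, background = 100) {
  d <- abs(matrix(seq_len(nr), nr, nc) - row)
  gray_image(pmin(background + amplitude * exp(-d^2 / (2 * width^2)), 255))
}

# Hand-built tensor field carrying only what refine() needs: eigenvector
# fields on a lattice (lam values are placeholders).
fake_tensor_field <- function(nr, nc, v2x, v2y) {
  structure(list(dim = c(nr, nc), sigma = 1.4, has_eigen = TRUE,
                 normalized = TRUE, norm_const = 1,
                 lam1 = matrix(0, nr, nc), lam2 = matrix(0, nr, nc),
                 v1x = -v2y, v1y = v2x, v2x = v2x, v2y = v2y),
            class = "tensor_field")
}

label_map <- function(codes_matrix) {
  despecklr:::new_structure_map(codes_matrix)
}

ST <- structure_types()
TT <- truth_types()
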