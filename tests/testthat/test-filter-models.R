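## High-pass and ODOG-family filtering: brute-force convolution oracle,
## bank construction invariants, and the normalization properties.

## direct O(n^2 k^2) sliding-window box mean with edge renormalization:
## the independent oracle for the high-pass blur
naive_boxblur <- function(x, k) {
  half <- (k - 1) / 2
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      ri <- max(1, i - half):min(nrow(x), i + half)
      rj <- max(1, j - half):min(ncol(x), j + half)
      out[i, j] <- mean(x[ri, rj])
    }
  }
  out
}

test_that("highpass equals the brute-force subtract-blur oracle", {
  toy <- matrix(0, 5, 5); toy[3, 3] <- 1
  got <- highpass(toy, 3)$response
  expect_equal(got, toy - naive_boxblur(toy, 3), tolerance = 1e-12)
  set.seed(8)
  r <- matrix(runif(49), 7, 7)
  for (k in c(1, 3, 5, 7)) {
    expect_equal(highpass(r, k)$response, r - naive_boxblur(r, k),
                 tolerance = 1e-12, info = paste("k =", k))
  }
})

test_that("highpass of a uniform image is exactly zero", {
  u <- matrix(42, 32, 32)
  expect_true(all(highpass(u, 9)$response == 0))
})

test_that("highpass validates its filter size", {
  expect_error(highpass(matrix(1, 8, 8), 4), "odd")
  expect_error(highpass(matrix(1, 8, 8), 9), "larger")
  expect_error(highpass(matrix(1, 8, 8)), "filter_px")
})

test_that("the ODOG bank has 42 zero-sum kernels over 180 degrees", {
  bank <- make_odog_bank(ppd = 8)
  expect_equal(length(bank$kernels), 42)
  expect_equal(sort(unique(bank$meta$angle_deg)), seq(0, 150, by = 30))
  for (i in seq_along(bank$kernels)) {
    k <- bank$kernels[[i]]
    expect_lt(abs(sum(k)), 1e-6 * sum(abs(k)))
  }
  ## scale weights increase with centre frequency (shallow power law)
  w <- bank$meta$weight[bank$meta$orientation == 1]
  expect_true(all(diff(w) > 0))
  expect_equal(w[7] / w[1], 64^0.1, tolerance = 1e-9)
  expect_error(make_odog_bank(ppd = 0.5), "too small")
})

test_that("rotating a kernel by the orientation spacing maps it onto the
          next orientation", {
  bank <- make_odog_bank(ppd = 16)
  i0 <- which(bank$meta$orientation == 1 & bank$meta$scale == 3)
  i1 <- which(bank$meta$orientation == 2 & bank$meta$scale == 3)
  k0 <- bank$kernels[[i0]]; k1 <- bank$kernels[[i1]]
  ## rotate k0 by 30 deg via bilinear resampling (independent of the
  ## analytic construction)
  n <- nrow(k0); c0 <- (n + 1) / 2
  th <- 30 * pi / 180
  rot <- matrix(0, n, n)
  for (i in seq_len(n)) {
    y <- i - c0
    x <- seq_len(n) - c0
    xs <- x * cos(th) - y * sin(th) + c0
    ys <- x * sin(th) + y * cos(th) + c0
    x0 <- floor(xs); y0 <- floor(ys)
    wx <- xs - x0; wy <- ys - y0
    ok <- x0 >= 1 & x0 < n & y0 >= 1 & y0 < n
    v <- numeric(n)
    idx <- function(r, cc) k0[cbind(pmin(pmax(r, 1), n), pmin(pmax(cc, 1), n))]
    v[ok] <- ((idx(y0, x0) * (1 - wx) + idx(y0, x0 + 1) * wx) * (1 - wy) +
              (idx(y0 + 1, x0) * (1 - wx) + idx(y0 + 1, x0 + 1) * wx) * wy)[ok]
    rot[i, ] <- v
  }
  rel <- sqrt(sum((rot - k1)^2)) / sqrt(sum(k1^2))
  expect_lt(rel, 0.01)
})

test_that("uniform input raises the degenerate-output signal", {
  u <- matrix(50, 64, 64)
  bank <- make_odog_bank(ppd = 8)
  expect_error(odog(u, "odog", bank),
               class = "lightbench_degenerate_error")
})

test_that("global ODOG output is invariant to input gain", {
  b <- build_display("slc", resolution = 128, ppd = 8)
  bank <- make_odog_bank(8)
  r1 <- odog(b$image, "odog", bank)$response
  r2 <- odog(3.7 * b$image, "odog", bank)$response
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("each orientation's RMS is 1 after global ODOG normalization", {
  b <- build_display("whites", resolution = 128, ppd = 8)
  bank <- make_odog_bank(8)
  img <- b$image; n <- nrow(img); gf <- lightbench:::fft2(img)
  total <- matrix(0, n, n)
  for (o in 1:6) {
    tr <- lightbench:::orientation_transfer(bank, o, n)
    resp <- lightbench:::conv_transfer(gf, tr)
    rms <- sqrt(mean(resp^2))
    expect_equal(sqrt(mean((resp / rms)^2)), 1, tolerance = 1e-9)
    total <- total + resp / rms
  }
  ## and the summed map equals the model output
  expect_equal(total, odog(img, "odog", bank)$response, tolerance = 1e-9)
})

test_that("mirroring the image mirrors the response (all variants)", {
  b <- build_display("slc", resolution = 96, ppd = 6)
  bank <- make_odog_bank(6)
  mir <- function(m) m[, ncol(m):1]
  for (v in c("odog", "odog2", "lodog", "flodog")) {
    r1 <- odog(b$image, v, bank)$response
    r2 <- odog(mir(b$image), v, bank)$response
    expect_lt(sqrt(mean((mir(r2) - r1)^2)) / sqrt(mean(r1^2)), 1e-6)
  }
})

test_that("LODOG converges to gray-padded ODOG for huge windows", {
  b <- build_display("slc", resolution = 96, ppd = 6)
  bank <- make_odog_bank(6)
  r_odog2 <- odog(b$image, "odog2", bank)$response
  r_lodog <- odog(b$image, "lodog", bank, window_sigma_deg = 1000)$response
  rel <- sqrt(sum((r_lodog - r_odog2)^2)) / sqrt(sum(r_odog2^2))
  expect_lt(rel, 0.01)
})

test_that("tiled-boundary filtering is translation-equivariant", {
  ## circular convolution commutes with cyclic shifts exactly; check the
  ## full pipeline response follows a shifted stimulus
  set.seed(5)
  img <- matrix(runif(64^2, 10, 100), 64, 64)
  bank <- make_odog_bank(8)
  r1 <- odog(img, "odog", bank)$response
  sh <- function(m, k) m[c((k + 1):nrow(m), 1:k), ]
  r2 <- odog(sh(img, 7), "odog", bank)$response
  expect_equal(sh(r1, 7), r2, tolerance = 1e-9 * max(abs(r1)))
})
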