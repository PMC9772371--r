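## FFT helpers shared by the spatial-filtering models.  All convolutions
## are circular on the working grid; boundary policies (tiling vs mean-gray
## padding) are implemented by choosing the working grid, not the kernel.

fft2 <- function(x) stats::fft(x)
ifft2_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

## embed a spatial kernel (odd-sized, centred) into an n x n grid with its
## centre at element [1, 1] so that circular convolution does not shift
embed_kernel <- function(kernel, n) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ci <- (kh + 1L) %/% 2L; cj <- (kw + 1L) %/% 2L
  ri <- ((seq_len(kh) - ci) %% n) + 1L
  rj <- ((seq_len(kw) - cj) %% n) + 1L
  out <- matrix(0, n, n)
  if (kh <= n && kw <= n) {
    out[ri, rj] <- kernel
  } else {
    ## kernel larger than the grid: fold (alias) the tails, which is what
    ## circular convolution with the full kernel does; this also keeps
    ## the kernel sum exactly zero
    by_row <- rowsum(kernel, ri)                 # fold rows
    rows <- matrix(0, n, kw)
    rows[as.integer(rownames(by_row)), ] <- by_row
    by_col <- rowsum(t(rows), rj)                # fold columns
    out[, as.integer(rownames(by_col))] <- t(by_col)
  }
  out
}

## circular convolution of an image with a pre-computed kernel transfer
conv_transfer <- function(img_f, transfer) {
  ifft2_re(img_f * transfer)
}

## analytic transfer function of a unit-volume isotropic Gaussian
gauss_transfer <- function(n, sigma_px) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n   # cycles / pixel
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n)
  exp(-2 * pi^2 * sigma_px^2 * (fx^2 + fy^2))
}

## Gaussian-window smoothing renormalized to the frame (normalized
## convolution with the frame indicator), computed exactly as a
## separable pair of dense weight-matrix products; no padding, valid for
## arbitrarily wide windows
gauss_blur_norm <- function(x, sigma_px, cache = NULL) {
  wr <- gauss_weights(nrow(x), sigma_px, cache)
  wc <- gauss_weights(ncol(x), sigma_px, cache)
  num <- wr %*% x %*% wc
  den <- outer(rowSums(wr), rowSums(wc))
  num / den
}

## symmetric Toeplitz matrix of 1-D Gaussian weights exp(-d^2 / 2 sigma^2)
gauss_weights <- function(n, sigma_px, cache = NULL) {
  key <- sprintf("gw_%d_%g", n, sigma_px)
  w <- cache_get(cache, key)
  if (is.null(w)) {
    d <- outer(seq_len(n), seq_len(n), "-")
    w <- exp(-d^2 / (2 * sigma_px^2))
    cache_set(cache, key, w)
  }
  w
}

cache_get <- function(cache, key) {
  if (is.null(cache)) return(NULL)
  if (exists(key, envir = cache, inherits = FALSE)) get(key, envir = cache)
  else NULL
}
cache_set <- function(cache, key, value) {
  if (!is.null(cache)) assign(key, value, envir = cache)
  invisible(value)
}

## classed error used whenever a normalizer degenerates (e.g. a uniform
## input drives every zero-sum filter response to zero)
degenerate_error <- function(model_id, ...) {
  stop(structure(
    class = c("lightbench_degenerate_error", "error", "condition"),
    list(message = paste0("degenerate model output [", model_id, "]: ",
                          ...),
         call = sys.call(-1))
  ))
}
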