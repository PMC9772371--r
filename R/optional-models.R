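## Best-effort tier: two statistically motivated models implemented to a
## contract level.  Both mark their output with `optional_tier = TRUE`, a
## fidelity flag that every downstream report keeps visible; their
## constants are frozen here and are not fitted.

#' Dynamic-decorrelation model of brightness (best-effort tier)
#'
#' Three processing stages: (1) the image is decomposed by quadrature
#' Gabor pairs into a high-resolution contrast-only channel and a
#' low-resolution contrast-luminance channel, and the contrast-only
#' channel yields a local energy map; (2) the energy map is decorrelated
#' (redundancy reduced) by dividing out its own local average, so only
#' locally unpredictable energy survives; (3) the image is recovered from
#' the two channels with the band-pass content gain-modulated by the
#' decorrelated energy.
#'
#' This is a contract-level re-implementation; its output carries the
#' best-effort fidelity flag.
#'
#' @param image luminance matrix or `stimulus_bundle`.
#' @param wavelengths_px Gabor wavelengths of the contrast-only channel.
#' @param lowpass_sigma_px sd of the contrast-luminance lowpass.
#' @param pool_sigma_px sd of the energy pooling / decorrelation window.
#' @return a `model_output` with `optional_tier = TRUE`.
#' @export
dynamic_decorrelation <- function(image, wavelengths_px = c(4, 8, 16, 32),
                                  lowpass_sigma_px = 24,
                                  pool_sigma_px = 24) {
  if (inherits(image, "stimulus_bundle")) image <- image$image
  if (any(image <= 0)) stop("image luminances must be strictly positive")
  n <- nrow(image)
  stopifnot(n == ncol(image))
  pad <- n %/% 2L
  m <- n + 2L * pad
  grid <- matrix(mean(image), m, m)
  idx <- (pad + 1L):(pad + n)
  grid[idx, idx] <- image
  gf <- fft2(grid)

  angles <- c(0, 45, 90, 135) * pi / 180
  energy <- matrix(0, n, n)
  bandpass <- matrix(0, n, n)
  for (lam in wavelengths_px) {
    for (th in angles) {
      q <- gabor_pair_transfer(m, lam, th)
      ev <- conv_transfer(gf, q$even)[idx, idx]
      od <- ifft2_re(gf * q$odd)[idx, idx]
      energy <- energy + ev^2 + od^2
      bandpass <- bandpass + ev
    }
  }
  ## decorrelation: locally predictable energy is divided out
  pooled <- gauss_blur_norm(energy, pool_sigma_px)
  decorr <- energy / (pooled + 1e-12 * mean(energy) + 1e-300)
  gain <- decorr / (decorr + 1)
  low <- gauss_blur_norm(image, lowpass_sigma_px)
  out <- low + gain * bandpass
  model_output(out, "dyndec",
               list(wavelengths_px = wavelengths_px,
                    lowpass_sigma_px = lowpass_sigma_px,
                    pool_sigma_px = pool_sigma_px),
               optional_tier = TRUE)
}

## frequency-domain even (cosine, zero-DC) and odd (sine) Gabor transfer
## pair at one wavelength and orientation
gabor_pair_transfer <- function(m, wavelength_px, theta) {
  f0 <- 1 / wavelength_px
  sigma <- wavelength_px / 2
  f <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
  fx <- matrix(f, m, m, byrow = TRUE)
  fy <- matrix(f, m, m)
  fu <- fx * cos(theta) + fy * sin(theta)
  fv <- -fx * sin(theta) + fy * cos(theta)
  g <- function(cu) exp(-2 * pi^2 * sigma^2 * ((fu - cu)^2 + fv^2))
  gp <- g(f0); gm <- g(-f0); g0 <- g(0)
  dc <- exp(-2 * pi^2 * sigma^2 * f0^2)   # value of gp + gm at f = 0, halved
  even <- (gp + gm) / 2 - dc * g0          # cosine Gabor, DC removed
  odd_i <- (gp - gm) / 2                   # sine Gabor (imaginary transfer)
  list(even = even, odd = complex(real = 0, imaginary = 1) * odd_i)
}

#' Markov reflectance-illumination decomposition (best-effort tier)
#'
#' Decomposes a luminance image into reflectance and illumination by MAP
#' inference in a conditional random field.  Each pixel carries a
#' log-reflectance label from a log-spaced grid; illumination is the
#' luminance divided by the labelled reflectance, so the decomposition
#' reproduces the input exactly at label resolution.  Unary potentials
#' encode the statistical priors: reflectance is roughly uniform on
#' [3%, 90%] with a rapid (quadratic in log units) penalty outside, and
#' low illumination is more probable than high.  Pairwise potentials
#' charge truncated-linear costs to reflectance edges and (more heavily)
#' to illumination edges.  Inference is min-sum loopy belief propagation
#' with damping, run at a reduced resolution and upsampled.
#'
#' @param image luminance matrix or `stimulus_bundle` (cd/m2).
#' @param n_labels reflectance labels (default 32).
#' @param max_size decomposition grid size; larger inputs are area-averaged
#'   down to at most this many pixels per side (default 64).
#' @param max_sweeps belief-propagation sweeps (default 20).
#' @param lambda_r,lambda_i pairwise weights for reflectance and
#'   illumination edges (`lambda_i > lambda_r`).
#' @param prior_illum weight of the increasing log-illumination prior.
#' @return object of class `intrinsic_decomposition`: list with
#'   `reflectance` (in (0, 1]), `illumination` (cd/m2), `converged`,
#'   `model_id`, `optional_tier = TRUE`.  Use [mir_lightness()] to obtain
#'   the reflectance map as a `model_output`.
#' @export
mir_decompose <- function(image, n_labels = 32, max_size = 64,
                          max_sweeps = 20, lambda_r = 1, lambda_i = 3,
                          prior_illum = 0.05) {
  if (inherits(image, "stimulus_bundle")) image <- image$image
  if (any(image <= 0)) stop("image luminances must be strictly positive")
  full_dim <- dim(image)
  work <- image
  while (max(dim(work)) > max_size) work <- halve(work)

  logL <- log(work / max(work))          # max luminance = illumination 1
  rho <- seq(log(0.01), log(1), length.out = n_labels)  # log reflectance
  h <- rho[2] - rho[1]

  ## unary: reflectance plateau prior + illumination prior on L / r
  n1 <- nrow(work); n2 <- ncol(work); npix <- n1 * n2
  U <- matrix(0, npix, n_labels)
  lo <- log(0.03); hi <- log(0.90)
  for (l in seq_len(n_labels)) {
    pr <- 8 * (pmax(lo - rho[l], 0)^2 + pmax(rho[l] - hi, 0)^2)
    logi <- as.vector(logL) - rho[l]     # log illumination at this label
    pi_ <- prior_illum * (logi - min(logL))    # higher illumination costs
    pi_[logi > 0] <- 1e3                 # illumination cannot exceed max
    U[, l] <- pr + pi_
  }

  bp <- bp_minsum(U, logL, rho, h, n1, n2, n_labels, max_sweeps,
                  lambda_r, lambda_i)
  lab <- matrix(bp$labels, n1, n2)
  refl <- matrix(exp(rho[lab]), n1, n2)
  illum <- work / refl

  refl_full <- upsample_full(refl, full_dim)
  illum_full <- upsample_full(illum, full_dim)
  structure(list(reflectance = refl_full, illumination = illum_full,
                 converged = bp$converged, sweeps = bp$sweeps,
                 model_id = "mir", optional_tier = TRUE,
                 params = list(n_labels = n_labels, max_size = max_size,
                               lambda_r = lambda_r, lambda_i = lambda_i)),
            class = "intrinsic_decomposition")
}

#' Reflectance map of a MIR decomposition as a model output
#'
#' @param decomposition result of [mir_decompose()], or an image to
#'   decompose with default settings.
#' @param ... passed to [mir_decompose()] when an image is given.
#' @return a `model_output` carrying the best-effort fidelity flag.
#' @export
mir_lightness <- function(decomposition, ...) {
  if (!inherits(decomposition, "intrinsic_decomposition")) {
    decomposition <- mir_decompose(decomposition, ...)
  }
  model_output(decomposition$reflectance, "mir", decomposition$params,
               optional_tier = TRUE)
}

## min-sum loopy BP on the 4-connected grid; the pairwise cost between
## labels lp, lq on edge (p, q) is
##   lambda_r * min(h |lp - lq|, tau_r) +
##   lambda_i * min(|delta_pq - h (lp - lq)|, tau_i)
## with delta_pq the log-luminance step across the edge
bp_minsum <- function(U, logL, rho, h, n1, n2, L, max_sweeps,
                      lambda_r, lambda_i, damping = 0.5) {
  npix <- n1 * n2
  ## reflectance edges are cheap and heavily truncated (piecewise-constant
  ## reflectance); illumination edges cost more and are truncated late
  ## (illumination should be smooth)
  tau_r <- 2 * h; tau_i <- 30 * h
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  msg <- lapply(dirs, function(d) matrix(0, npix, L))
  pix_index <- matrix(seq_len(npix), n1, n2)
  shift_idx <- function(d) as.vector(shift_clamp(pix_index, d[1], d[2]))
  logLv <- as.vector(logL)
  converged <- FALSE
  sweeps <- 0
  for (sweep in seq_len(max_sweeps)) {
    sweeps <- sweep
    delta_msg <- 0
    belief_wo <- function(skip) {
      b <- U
      for (j in seq_along(dirs)) if (j != skip) b <- b + msg[[j]]
      b
    }
    new_msg <- msg
    for (j in seq_along(dirs)) {
      d <- dirs[[j]]
      src <- shift_idx(c(-d[1], -d[2]))   # message into q comes from p = q - d
      rev_j <- switch(j, 2L, 1L, 4L, 3L)
      H <- belief_wo(rev_j)[src, , drop = FALSE]
      H <- H - rowMins(H)                 # normalize
      delta <- logLv[src] - logLv        # log-luminance step p -> q
      acc <- matrix(Inf, npix, L)
      for (k in (-(L - 1)):(L - 1)) {
        ## lp = lq + k
        cols_q <- max(1, 1 - k):min(L, L - k)
        vk <- lambda_r * min(h * abs(k), tau_r) +
          lambda_i * pmin(abs(delta - h * k), tau_i)
        cand <- H[, cols_q + k, drop = FALSE] + vk
        acc[, cols_q] <- pmin(acc[, cols_q, drop = FALSE], cand)
      }
      edge_ok <- src != seq_len(npix)     # clamped border pixels: no edge
      acc[!edge_ok, ] <- 0
      new_msg[[j]] <- damping * msg[[j]] + (1 - damping) * acc
      delta_msg <- max(delta_msg, max(abs(new_msg[[j]] - msg[[j]])))
    }
    msg <- new_msg
    if (delta_msg < 1e-4) { converged <- TRUE; break }
  }
  b <- U
  for (j in seq_along(dirs)) b <- b + msg[[j]]
  list(labels = max.col(-b, ties.method = "first"),
       converged = converged, sweeps = sweeps)
}

rowMins <- function(m) {
  out <- m[, 1]
  for (j in 2:ncol(m)) out <- pmin(out, m[, j])
  out
}

upsample_full <- function(x, full_dim) {
  while (nrow(x) < full_dim[1] || ncol(x) < full_dim[2]) {
    x <- upsample_to(x, pmin(2L * dim(x), full_dim))
  }
  x
}
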