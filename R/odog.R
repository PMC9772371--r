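## Oriented difference-of-Gaussians model family (ODOG, ODOG-2, LODOG,
## FLODOG).  The first stage convolves the stimulus with a bank of 42
## anisotropic DoG filters (6 orientations x 7 scales); the variants differ
## only in boundary handling and in how the filter responses are
## normalized before the orientations are summed.

#' Build the 42-filter oriented DoG bank
#'
#' Six orientations evenly spaced over 180 degrees crossed with seven
#' scales spaced in octaves.  Each filter is the difference of a circular
#' centre Gaussian (space constant `sigma_c`) and a surround Gaussian with
#' twice the centre space constant along the filter's orientation axis and
#' the centre space constant across it, both unit volume.  The seven centre
#' space constants are `3 / 2^(0:6)` degrees (1/e-radius convention), placing the centre spatial
#' frequencies at roughly 0.1 to 6.5 cycles per degree.  Scales are
#' combined with weights that grow with centre frequency as a shallow
#' power law with exponent 0.1.
#'
#' Rasterized kernels are truncated at three surround space constants and
#' have their surround rescaled so every kernel sums to exactly zero.
#'
#' @param ppd pixels per degree at which the kernels are rasterized.
#' @return object of class `odog_bank`: list with `ppd`, `meta` (one row
#'   per kernel: orientation index/angle, scale index, centre/surround
#'   space constants in degrees, scale weight) and `kernels` (list of 42
#'   matrices in orientation-major order).
#' @export
#' @examples
#' bank <- make_odog_bank(ppd = 8)
#' length(bank$kernels)
make_odog_bank <- function(ppd) {
  stopifnot(is.numeric(ppd), ppd > 0)
  ## published space constants 3/2^(0:6) deg in the exp(-(x/s)^2)
  ## convention; divide by sqrt(2) for the standard-deviation form used
  ## here
  sigma_c <- 3 / sqrt(2) / 2^(0:6)       # degrees, coarse to fine
  if (6 * min(sigma_c) * ppd < 1) {
    stop("ppd ", ppd, " too small: the finest kernel would span < 1 px ",
         "and cannot be rasterized meaningfully")
  }
  angles <- seq(0, 150, by = 30)         # degrees, orientation of long axis
  weights <- (2^(0:6))^0.1
  weights <- weights / sum(weights)
  meta <- expand.grid(scale = 1:7, orientation = 1:6)[, c(2, 1)]
  meta$angle_deg <- angles[meta$orientation]
  meta$sigma_c_deg <- sigma_c[meta$scale]
  meta$sigma_s_deg <- 2 * sigma_c[meta$scale]
  meta$weight <- weights[meta$scale]
  kernels <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    kernels[[i]] <- odog_kernel(meta$sigma_c_deg[i], meta$angle_deg[i], ppd)
  }
  structure(list(ppd = ppd, meta = meta, kernels = kernels,
                 cache = new.env(parent = emptyenv())),
            class = "odog_bank")
}

## rasterize one oriented DoG kernel; u is the coordinate along the
## orientation axis (the elongated surround axis)
odog_kernel <- function(sigma_c_deg, angle_deg, ppd) {
  sc <- sigma_c_deg * ppd
  su <- 2 * sc                    # surround, along orientation
  sv <- sc                        # surround, across orientation
  half <- max(3L, ceiling(3 * su))
  xs <- (-half):half
  x <- matrix(xs, length(xs), length(xs), byrow = TRUE)
  y <- matrix(xs, length(xs), length(xs))
  th <- angle_deg * pi / 180
  u <- x * cos(th) - y * sin(th)
  v <- x * sin(th) + y * cos(th)
  g2 <- function(su_, sv_) {
    exp(-(u^2 / (2 * su_^2) + v^2 / (2 * sv_^2))) / (2 * pi * su_ * sv_)
  }
  centre <- g2(sc, sc)
  surround <- g2(su, sv)
  ## exact discrete zero sum: match the surround volume to the centre's
  surround <- surround * (sum(centre) / sum(surround))
  centre - surround
}

#' @export
print.odog_bank <- function(x, ...) {
  cat("<odog_bank> ", length(x$kernels), " kernels (",
      length(unique(x$meta$orientation)), " orientations x ",
      length(unique(x$meta$scale)), " scales) at ", x$ppd, " px/deg\n",
      sep = "")
  invisible(x)
}

#' Run an ODOG-family model
#'
#' All variants share the first stage: the image is convolved with the 42
#' oriented DoG kernels and, within each orientation, the seven scale
#' responses are combined with the bank's frequency weights.  They differ
#' in the second stage:
#' \describe{
#'   \item{`odog`}{each orientation's combined response is divided by its
#'     global RMS over the image, then the six orientations are summed;
#'     the boundary is handled by tiling the input pattern (circular
#'     convolution).}
#'   \item{`odog2`}{identical normalization, but the input is padded with
#'     its mean gray before filtering.}
#'   \item{`lodog`}{the global RMS is replaced by a local Gaussian-windowed
#'     RMS (window sd `window_sigma_deg`, default 4 degrees of visual
#'     angle), with a small floor to avoid division blow-up in blank
#'     regions; mean-gray padding.}
#'   \item{`flodog`}{normalization is computed separately for each
#'     (orientation, scale) channel; the normalizing energy pools scales
#'     with a Gaussian weight over octave distance (sd
#'     `flodog_octave_sd`) centred on the channel itself, in a window
#'     proportional to the channel's surround space constant
#'     (`flodog_window_mult` times it); mean-gray padding.}
#' }
#'
#' Normalization statistics are always computed over the un-padded frame.
#'
#' @param image luminance matrix (strictly positive) or `stimulus_bundle`.
#' @param variant one of `"odog"`, `"odog2"`, `"lodog"`, `"flodog"`.
#' @param bank an `odog_bank` built at the matching ppd; built on the fly
#'   when omitted and a bundle is given.
#' @param window_sigma_deg LODOG normalization window sd in degrees.
#' @param flodog_window_mult FLODOG window sd as a multiple of the
#'   channel's surround space constant.
#' @param flodog_octave_sd sd (in octaves) of the FLODOG cross-scale
#'   pooling weights.
#' @param floor_frac normalizer floor as a fraction of the global RMS.
#' @return a `model_output`.
#' @export
odog <- function(image, variant = c("odog", "odog2", "lodog", "flodog"),
                 bank = NULL, window_sigma_deg = 4,
                 flodog_window_mult = 2, flodog_octave_sd = 0.5,
                 floor_frac = 1e-6) {
  variant <- match.arg(variant)
  ppd <- NULL
  if (inherits(image, "stimulus_bundle")) {
    ppd <- image$ppd
    image <- image$image
  }
  if (any(image <= 0)) stop("image luminances must be strictly positive")
  if (is.null(bank)) {
    if (is.null(ppd)) stop("supply a bank or a stimulus_bundle (for ppd)")
    bank <- make_odog_bank(ppd)
  }
  if (!is.null(ppd) && abs(bank$ppd - ppd) > 1e-9) {
    stop("bank was built at ", bank$ppd, " px/deg but the stimulus is at ",
         ppd, " px/deg")
  }
  ppd <- bank$ppd
  n <- nrow(image)
  stopifnot(n == ncol(image))

  tiled <- variant == "odog"
  if (tiled) {
    grid <- image
    idx <- seq_len(n)
  } else {
    pad <- n %/% 2L
    m <- n + 2L * pad
    grid <- matrix(mean(image), m, m)
    idx <- (pad + 1L):(pad + n)
    grid[idx, idx] <- image
  }
  gf <- fft2(grid)
  gn <- nrow(grid)

  params <- list(variant = variant, ppd = ppd,
                 window_sigma_deg = window_sigma_deg,
                 flodog_window_mult = flodog_window_mult,
                 flodog_octave_sd = flodog_octave_sd,
                 floor_frac = floor_frac)

  if (variant %in% c("odog", "odog2", "lodog")) {
    out <- matrix(0, n, n)
    any_signal <- FALSE
    for (o in 1:6) {
      tr <- orientation_transfer(bank, o, gn)
      resp <- conv_transfer(gf, tr)[idx, idx]
      grms <- sqrt(mean(resp^2))
      if (grms < 1e-12 * mean(abs(image))) next
      any_signal <- TRUE
      if (variant == "lodog") {
        local_rms <- sqrt(pmax(gauss_blur_norm(resp^2,
                                               window_sigma_deg * ppd,
                                               bank$cache), 0))
        out <- out + resp / pmax(local_rms, floor_frac * grms)
      } else {
        out <- out + resp / grms
      }
    }
    if (!any_signal) {
      degenerate_error(variant, "all oriented filter responses are zero ",
                       "(uniform input?)")
    }
    return(model_output(out, variant, params))
  }

  ## FLODOG: per-channel responses and per-channel local normalization
  out <- matrix(0, n, n)
  any_signal <- FALSE
  octave_w <- outer(0:6, 0:6, function(a, b) {
    exp(-(a - b)^2 / (2 * flodog_octave_sd^2))
  })
  octave_w <- octave_w / rowSums(octave_w)
  for (o in 1:6) {
    resp <- vector("list", 7)
    rows <- which(bank$meta$orientation == o)
    for (s in 1:7) {
      i <- rows[bank$meta$scale[rows] == s]
      tr <- kernel_transfer(bank, i, gn)
      resp[[s]] <- bank$meta$weight[i] * conv_transfer(gf, tr)[idx, idx]
    }
    for (s in 1:7) {
      grms <- sqrt(mean(resp[[s]]^2))
      if (grms < 1e-15 * mean(abs(image))) next
      any_signal <- TRUE
      pooled <- matrix(0, n, n)
      for (s2 in 1:7) pooled <- pooled + octave_w[s, s2] * resp[[s2]]
      i <- rows[bank$meta$scale[rows] == s]
      win_px <- flodog_window_mult * bank$meta$sigma_s_deg[i] * ppd
      local_rms <- sqrt(pmax(gauss_blur_norm(pooled^2, win_px, bank$cache),
                             0))
      out <- out + resp[[s]] / pmax(local_rms, floor_frac * grms)
    }
  }
  if (!any_signal) {
    degenerate_error(variant, "all oriented filter responses are zero ",
                     "(uniform input?)")
  }
  model_output(out, variant, params)
}

## FFT of one rasterized kernel embedded in an m x m grid; only small
## grids are cached (a full set of large complex transfers would dominate
## memory)
kernel_transfer <- function(bank, i, m) {
  if (m > 640) return(fft2(embed_kernel(bank$kernels[[i]], m)))
  key <- sprintf("ker_%d_%d", i, m)
  tr <- cache_get(bank$cache, key)
  if (is.null(tr)) {
    tr <- fft2(embed_kernel(bank$kernels[[i]], m))
    cache_set(bank$cache, key, tr)
  }
  tr
}

## cached weighted sum across the 7 scales of one orientation
orientation_transfer <- function(bank, o, m) {
  key <- sprintf("ori_%d_%d", o, m)
  tr <- cache_get(bank$cache, key)
  if (is.null(tr)) {
    rows <- which(bank$meta$orientation == o)
    tr <- 0
    for (i in rows) {
      tr <- tr + bank$meta$weight[i] * fft2(embed_kernel(bank$kernels[[i]], m))
    }
    cache_set(bank$cache, key, tr)
  }
  tr
}
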