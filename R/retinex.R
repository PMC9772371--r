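#' McCann multiresolution RETINEX
#'
#' Lightness computation by the ratio-product-reset-average algorithm run
#' over a multiresolution pyramid.  The image is converted to log
#' luminance anchored at its global maximum; a pyramid is built by 2x2
#' area averaging down to the level whose smaller dimension is at most 8
#' pixels.  Starting from the coarsest level (with the working estimate
#' initialized at the anchor, i.e. "everything is white"), each level runs
#' `n_iterations` sweeps; in each sweep every pixel visits its eight
#' nearest neighbours in clockwise order starting at the top-left and
#' applies the four steps: ratio (log-luminance difference to the
#' neighbour), product (added to the neighbour's running estimate), reset
#' (estimates capped at the global maximum) and average (with the pixel's
#' previous estimate).  Finished estimates are propagated to the next
#' finer level by pixel replication, which keeps estimates constant
#' across uniform regions (smooth interpolation would drag region-border
#' gradients deep into uniform surfaces and break the model's ratio
#' conservation).
#'
#' The output is `exp` of the final estimate, a lightness map in (0, 1]
#' whose maximum is exactly 1 (the reset step anchors the highest
#' luminance to white).
#'
#' @param image strictly positive luminance matrix or `stimulus_bundle`.
#' @param n_iterations sweeps per pyramid level (default 4).
#' @return a `model_output` with response in (0, 1].
#' @export
#' @examples
#' img <- matrix(c(20, 20, 80, 80), 2, 4)
#' retinex_mccann(img, n_iterations = 32)$response
retinex_mccann <- function(image, n_iterations = 4) {
  if (inherits(image, "stimulus_bundle")) image <- image$image
  if (any(image <= 0)) {
    stop("luminances must be strictly positive (log undefined)")
  }
  stopifnot(n_iterations >= 1)
  logI <- log(image / max(image))

  ## pyramid, fine to coarse
  levels <- list(logI)
  while (min(dim(levels[[length(levels)]])) > 8) {
    levels[[length(levels) + 1L]] <- halve(levels[[length(levels)]])
  }

  ## neighbour offsets (drow, dcol), clockwise from top-left
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                 c(1, 1), c(1, 0), c(1, -1), c(0, -1))

  op <- matrix(0, nrow(levels[[length(levels)]]),
               ncol(levels[[length(levels)]]))
  for (lev in rev(seq_along(levels))) {
    li <- levels[[lev]]
    if (!all(dim(op) == dim(li))) {
      ## replication hands a child its parent's estimate, which can fall
      ## below the child's own veridical ratio when the parent mixed
      ## luminances; re-impose the model's lower bound (the ratio-product
      ## chain guarantees estimate >= log ratio to the global maximum),
      ## which also keeps the white anchor exact
      op <- pmax(upsample_to(op, dim(li)), li)
    }
    for (it in seq_len(n_iterations)) {
      for (s in shifts) {
        np <- shift_clamp(op, s[1], s[2]) +
          (li - shift_clamp(li, s[1], s[2]))
        np <- pmin(np, 0)              # reset: cap at the global maximum
        op <- (op + np) / 2            # average with the old product
      }
    }
  }
  model_output(exp(op), "retinex", list(n_iterations = n_iterations))
}

## 2x2 area averaging; odd trailing rows/columns are averaged over the
## available pixels, so level dims are ceil(previous / 2)
halve <- function(x) {
  n <- nrow(x); m <- ncol(x)
  ri <- (seq_len(n) + 1L) %/% 2L
  ci <- (seq_len(m) + 1L) %/% 2L
  num <- rowsum(t(rowsum(x, ri)), ci)
  cnt <- rowsum(t(rowsum(matrix(1, n, m), ri)), ci)
  t(num / cnt)
}

## pixel replication up to the exact target dims
upsample_to <- function(x, d) {
  ri <- pmin(rep(seq_len(nrow(x)), each = 2), nrow(x))[seq_len(d[1])]
  ci <- pmin(rep(seq_len(ncol(x)), each = 2), ncol(x))[seq_len(d[2])]
  x[ri, ci, drop = FALSE]
}

## neighbour lookup with edge clamping (border pixels compare with
## themselves in the out-of-range direction, a no-op for the update)
shift_clamp <- function(x, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(x)) + dr, 1L), nrow(x))
  ci <- pmin(pmax(seq_len(ncol(x)) + dc, 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}
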