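#' Screen calibration between 8-bit gray values and luminance
#'
#' The displays are defined by five measured anchor pairs between 8-bit
#' gray value and screen luminance: 0 -> 6, 64 -> 25, 127 -> 69,
#' 190 -> 105, 255 -> 145 cd/m2.  Intermediate gray levels are mapped by
#' monotone piecewise-power interpolation: within each anchor segment the
#' luminance follows \code{L1 * (L2/L1)^t} with \code{t} the normalized
#' position in the segment, which is exact at the anchors and strictly
#' increasing everywhere.
#'
#' @param gray numeric vector of gray values in \code{[0, 255]}.
#' @return numeric vector of luminances in cd/m2.
#' @export
#' @examples
#' gray_to_luminance(c(0, 127, 255))
gray_to_luminance <- function(gray) {
  stopifnot(is.numeric(gray))
  if (any(gray < 0 | gray > 255, na.rm = TRUE)) {
    stop("gray values must lie in [0, 255]")
  }
  a <- calibration_anchors()
  interp_piecewise_power(gray, a$gray, a$luminance)
}

#' @rdname gray_to_luminance
#' @param luminance numeric vector of luminances in \code{[6, 145]} cd/m2.
#' @return \code{luminance_to_gray}: continuous (non-integer) gray values;
#'   round to obtain displayable 8-bit levels.
#' @export
luminance_to_gray <- function(luminance) {
  stopifnot(is.numeric(luminance))
  if (any(luminance < 6 | luminance > 145, na.rm = TRUE)) {
    stop("luminance values must lie in [6, 145] cd/m2")
  }
  a <- calibration_anchors()
  ## exact inverse of the forward segment-wise map
  idx <- findInterval(luminance, a$luminance,
                      rightmost.closed = TRUE, all.inside = TRUE)
  L1 <- a$luminance[idx]; L2 <- a$luminance[idx + 1L]
  g1 <- a$gray[idx];      g2 <- a$gray[idx + 1L]
  g1 + (g2 - g1) * log(luminance / L1) / log(L2 / L1)
}

#' Calibration anchor table
#'
#' @return data.frame with columns \code{gray} and \code{luminance}.
#' @export
calibration_anchors <- function() {
  data.frame(
    gray      = c(0, 64, 127, 190, 255),
    luminance = c(6, 25, 69, 105, 145)
  )
}

## Segment-wise geometric interpolation: y follows a power of the segment
## ratio, exact at the anchors and strictly monotone (all y anchors > 0)
interp_piecewise_power <- function(x, xa, ya) {
  idx <- findInterval(x, xa, rightmost.closed = TRUE, all.inside = TRUE)
  x1 <- xa[idx]; x2 <- xa[idx + 1L]
  y1 <- ya[idx]; y2 <- ya[idx + 1L]
  t <- (x - x1) / (x2 - x1)
  y1 * (y2 / y1)^t
}
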