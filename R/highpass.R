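#' High-pass filtering model of brightness
#'
#' Subtract-the-blur high-pass filtering: the image is convolved with a
#' uniform (box) filter that averages luminance within its window, and the
#' blurred image is subtracted from the original.  Following the idea that
#' the visual system discards spatial content coarser than the attended
#' object, the box size defaults to the diameter of the test patch of the
#' display being processed (`bundle$target_diameter_px`).
#'
#' Near the image border the box window is renormalized to the part of the
#' window that falls inside the frame, so a uniform image maps to an
#' exactly zero response everywhere.
#'
#' @param image luminance matrix, or a `stimulus_bundle`.
#' @param filter_px odd box side length in pixels; defaults to the target
#'   diameter when a bundle is supplied.
#' @return a `model_output` object (list with `response`, `model_id`,
#'   `params`).
#' @export
#' @examples
#' b <- build_display("slc", resolution = 128)
#' r <- highpass(b)
#' range(r$response)
highpass <- function(image, filter_px = NULL) {
  if (inherits(image, "stimulus_bundle")) {
    if (is.null(filter_px)) filter_px <- image$target_diameter_px
    image <- image$image
  }
  if (is.null(filter_px)) {
    stop("filter_px must be given when image is a plain matrix")
  }
  filter_px <- as.integer(filter_px)
  if (filter_px < 1 || filter_px %% 2 == 0) {
    stop("filter_px must be a positive odd integer")
  }
  if (filter_px > min(dim(image))) {
    stop("box filter (", filter_px, " px) larger than the image")
  }
  blur <- box_blur(image, filter_px)
  model_output(image - blur, "highpass", list(filter_px = filter_px))
}

## separable box mean with border renormalization (mean over the
## intersection of the window with the image)
box_blur <- function(x, k) {
  half <- (k - 1L) %/% 2L
  sum1 <- function(m) {
    ## running sums along rows of a matrix, window k, edge-truncated
    n <- nrow(m)
    cs <- apply(m, 2, cumsum)
    cs <- rbind(0, cs)
    hi <- pmin(seq_len(n) + half, n) + 1L
    lo <- pmax(seq_len(n) - half, 1L)
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  counts <- function(n) {
    pmin(seq_len(n) + half, n) - pmax(seq_len(n) - half, 1L) + 1L
  }
  s <- sum1(t(sum1(x)))
  s <- t(s)
  cnt <- outer(counts(nrow(x)), counts(ncol(x)))
  s / cnt
}

#' Construct a raw model output record
#'
#' @param response numeric matrix of model responses (model-specific units).
#' @param model_id character identifier of the producing model.
#' @param params list of parameter values used.
#' @param optional_tier logical; TRUE marks a best-effort implementation
#'   whose results carry a fidelity flag through all reports.
#' @return object of class `model_output`.
#' @export
model_output <- function(response, model_id, params = list(),
                         optional_tier = FALSE) {
  stopifnot(is.matrix(response), all(is.finite(response)))
  structure(list(response = response, model_id = model_id, params = params,
                 optional_tier = isTRUE(optional_tier)),
            class = "model_output")
}

#' @export
print.model_output <- function(x, ...) {
  cat("<model_output> ", x$model_id,
      if (x$optional_tier) " [best-effort tier]" else "",
      ": ", nrow(x$response), "x", ncol(x$response),
      ", range [", signif(min(x$response), 4), ", ",
      signif(max(x$response), 4), "]\n", sep = "")
  invisible(x)
}
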