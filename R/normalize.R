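## Scale normalization and target readout: model responses arrive in
## model-specific units; they are rescaled to a common 0-1 lightness scale
## (an affine map of the raw range, in the spirit of the
## highest-luminance-as-white anchoring rule) and summarized per target.

#' Rescale a raw model response to the 0-1 lightness scale
#'
#' Affine map sending the raw minimum to 0 and the raw maximum to 1.  The
#' raw range is recorded for audit.
#'
#' @param raw a `model_output`, or a plain numeric matrix.
#' @return object of class `lightness_map`: list with `values` (matrix in
#'   `[0, 1]`), `model_id`, `raw_min`, `raw_max`, `optional_tier`.
#' @export
#' @examples
#' scale_normalize(matrix(c(2, 4, 6, 4), 2))$values
scale_normalize <- function(raw) {
  if (is.matrix(raw)) raw <- model_output(raw, "raw")
  stopifnot(inherits(raw, "model_output"))
  lo <- min(raw$response); hi <- max(raw$response)
  if (hi - lo <= 0) {
    degenerate_error(raw$model_id,
                     "constant response map cannot be normalized")
  }
  structure(list(values = (raw$response - lo) / (hi - lo),
                 model_id = raw$model_id, raw_min = lo, raw_max = hi,
                 params = raw$params,
                 optional_tier = isTRUE(raw$optional_tier)),
            class = "lightness_map")
}

#' Read out the predicted lightness of a target
#'
#' Mean of the normalized lightness map over the target mask.  Mode
#' `"center"` first erodes the mask to its central ~50% area, which
#' discounts edge ringing of filter models on thin targets.
#'
#' @param map a `lightness_map` (or matrix in `[0, 1]`).
#' @param mask logical matrix, same shape.
#' @param mode `"full"` (default) or `"center"`.
#' @return scalar unit lightness.
#' @export
target_readout <- function(map, mask, mode = c("full", "center")) {
  mode <- match.arg(mode)
  values <- if (inherits(map, "lightness_map")) map$values else map
  stopifnot(is.logical(mask), all(dim(values) == dim(mask)))
  if (!any(mask)) stop("empty target mask")
  if (mode == "center") mask <- erode_to_half(mask)
  mean(values[mask])
}

## binary erosion (4-neighbourhood) until the area first drops to <= 50%
## of the original; stops early rather than emptying the mask
erode_to_half <- function(mask) {
  target <- sum(mask) / 2
  repeat {
    er <- mask &
      shift_clamp(mask, 1, 0) & shift_clamp(mask, -1, 0) &
      shift_clamp(mask, 0, 1) & shift_clamp(mask, 0, -1)
    if (!any(er)) return(mask)
    mask <- er
    if (sum(mask) <= target) return(mask)
  }
}

#' Run one model on one display and read out the illusion
#'
#' Deterministic composition: run the model, scale-normalize its response,
#' read out both targets, and report the left-minus-right difference.
#'
#' @param bundle a `stimulus_bundle` with two targets.
#' @param model function taking the bundle and returning a `model_output`
#'   (or a plain response matrix).
#' @param mode readout mode passed to [target_readout()].
#' @return object of class `illusion_result`: list with `display`,
#'   `model_id`, `left`, `right`, `diff`, `raw_min`, `raw_max`, `params`,
#'   `optional_tier`.
#' @export
#' @examples
#' b <- build_display("slc", resolution = 128)
#' illusion_effect(b, highpass)$diff > 0
illusion_effect <- function(bundle, model, mode = "full") {
  stopifnot(inherits(bundle, "stimulus_bundle"))
  raw <- model(bundle)
  if (is.matrix(raw)) raw <- model_output(raw, "custom")
  map <- scale_normalize(raw)
  left <- target_readout(map, bundle$mask_left, mode)
  right <- target_readout(map, bundle$mask_right, mode)
  structure(list(display = bundle$name, model_id = raw$model_id,
                 left = left, right = right, diff = left - right,
                 raw_min = map$raw_min, raw_max = map$raw_max,
                 params = raw$params,
                 optional_tier = isTRUE(raw$optional_tier)),
            class = "illusion_result")
}

#' @export
print.illusion_result <- function(x, ...) {
  cat("<illusion_result> ", x$model_id, " on ", x$display,
      if (x$optional_tier) " [best-effort tier]" else "", ":\n",
      "  left ", round(x$left, 4), ", right ", round(x$right, 4),
      ", diff ", round(x$diff, 4), "\n", sep = "")
  invisible(x)
}
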