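## Scoring model predictions against the human directions of illusion and
## assembling the model scoreboard (matched / unmatched grid with row
## totals) plus the Mondrian lightness-constancy report.

#' Does a model match the human direction of an illusion?
#'
#' Matched when the predicted left-minus-right difference has the same
#' sign as the human mean difference *and* exceeds `epsilon` in magnitude;
#' a prediction of (effectively) no effect therefore counts as unmatched.
#' The default `epsilon` of 0.005 on the 0-1 scale is a third of the
#' smallest human effect in the embedded statistics (0.015).
#'
#' @param result an `illusion_result`, or a numeric left-minus-right
#'   difference.
#' @param human_sign +1 (left lighter) or -1 (left darker).
#' @param epsilon no-effect threshold on the unit lightness scale.
#' @return logical.
#' @export
#' @examples
#' direction_match(0.10, +1)
#' direction_match(0.002, +1)   # below epsilon: "predicts no effect"
direction_match <- function(result, human_sign, epsilon = 0.005) {
  diff <- if (inherits(result, "illusion_result")) result$diff else result
  stopifnot(is.numeric(diff), human_sign %in% c(-1, 1), epsilon >= 0)
  sign(diff) == human_sign && abs(diff) > epsilon
}

#' Absolute lightness constancy on the Mondrian displays
#'
#' The Mondrian targets are veridically mid-gray, i.e. 0.5 on the unit
#' lightness scale; a model shows constancy when its mean target readout
#' stays within `delta` of that reference on *both* Mondrians.
#'
#' @param results list of two `illusion_result`s (the 4- and 34-surface
#'   Mondrians).
#' @param reference veridical target lightness (default 0.5).
#' @param delta tolerance on the unit scale (default 0.05).
#' @return logical.
#' @export
mondrian_constancy <- function(results, reference = 0.5, delta = 0.05) {
  if (length(results) != 2) stop("results for both Mondrians are required")
  readouts <- vapply(results, function(r) {
    stopifnot(inherits(r, "illusion_result"))
    (r$left + r$right) / 2
  }, 0)
  all(abs(readouts - reference) <= delta)
}

#' Model registry for the benchmark
#'
#' Returns ready-to-run model closures, each taking a `stimulus_bundle`
#' and returning a `model_output`.  The core tier re-implements high-pass
#' filtering, McCann RETINEX and the four ODOG variants; `"all"` adds the
#' two best-effort tier models (dynamic decorrelation and MIR), whose
#' outputs carry a fidelity flag.
#'
#' @param ppd pixels per degree shared by the ODOG bank and the stimuli.
#' @param which `"core"` or `"all"`.
#' @param retinex_iterations iterations per RETINEX pyramid level.
#' @return named list of functions.
#' @export
benchmark_models <- function(ppd = 32, which = c("core", "all"),
                             retinex_iterations = 4) {
  which <- match.arg(which)
  bank <- make_odog_bank(ppd)
  models <- list(
    highpass = function(b) highpass(b),
    retinex = function(b) retinex_mccann(b, retinex_iterations),
    odog = function(b) odog(b, "odog", bank),
    odog2 = function(b) odog(b, "odog2", bank),
    lodog = function(b) odog(b, "lodog", bank),
    flodog = function(b) odog(b, "flodog", bank)
  )
  if (which == "all") {
    models$dyndec <- function(b) dynamic_decorrelation(b)
    models$mir <- function(b) mir_lightness(b)
  }
  models
}

#' Build the model scoreboard
#'
#' Runs every model over the 13 displays, normalizes and reads out target
#' lightness, and scores each model on the nine scoreboard categories: the
#' eight illusion categories (direction agreement with the human data, see
#' [direction_match()]) and the Mondrians (absolute constancy, see
#' [mondrian_constancy()]).  The SLC luminance variants and the
#' large-stripe White's are scored as a supplementary variants table and
#' excluded from the row totals.  Model failures (e.g. a degenerate
#' normalization) are recorded as unmatched with an error annotation.
#'
#' @param models named list of model closures, e.g. [benchmark_models()].
#' @param resolution,ppd stimulus rendering parameters.
#' @param eps no-effect threshold for [direction_match()].
#' @param seed integer seed for the Mondrian tessellations.
#' @param mondrian_reference,mondrian_delta constancy criterion.
#' @param mode readout mode (`"full"` or `"center"`).
#' @param bundles optional pre-built named list of `stimulus_bundle`s
#'   (overrides `resolution`/`ppd`/`seed`).
#' @param verbose print progress.
#' @return object of class `direction_table`: list with `grid` (logical
#'   model x category matrix), `totals` (per-model matched counts),
#'   `column_totals`, `results` (long per model x display data.frame),
#'   `variants` (matched flags for the variant displays), `optional_tier`
#'   (per-model fidelity flags) and the configuration used.
#' @export
table2 <- function(models, resolution = 512, ppd = 32, eps = 0.005,
                   seed = 1, mondrian_reference = 0.5,
                   mondrian_delta = 0.05, mode = "full", bundles = NULL,
                   verbose = FALSE) {
  cat13 <- list_displays()
  if (is.null(bundles)) {
    bundles <- lapply(seq_len(nrow(cat13)), function(i) {
      build_display(cat13$name[i], resolution, ppd,
                    seed = if (cat13$needs_seed[i]) {
                      seed + match(cat13$name[i],
                                   c("mondrian4", "mondrian34")) - 1L
                    } else NULL)
    })
    names(bundles) <- cat13$name
  }
  stopifnot(!is.null(names(models)), all(nzchar(names(models))))

  rows <- list()
  for (m in names(models)) {
    for (d in names(bundles)) {
      if (verbose) message("running ", m, " on ", d)
      res <- tryCatch(illusion_effect(bundles[[d]], models[[m]], mode),
                      lightbench_degenerate_error = function(e) e)
      if (inherits(res, "condition")) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, display = d, left = NA_real_, right = NA_real_,
          diff = NA_real_, raw_min = NA_real_, raw_max = NA_real_,
          optional_tier = NA, error = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, display = d, left = res$left, right = res$right,
          diff = res$diff, raw_min = res$raw_min, raw_max = res$raw_max,
          optional_tier = res$optional_tier, error = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)

  cats <- c(illusion_categories(), "mondrians")
  grid <- matrix(FALSE, length(models), length(cats),
                 dimnames = list(names(models), cats))
  for (m in names(models)) {
    for (cat_name in illusion_categories()) {
      r <- results[results$model == m & results$display == cat_name, ]
      sign_h <- cat13$human_sign[cat13$name == cat_name]
      grid[m, cat_name] <- is.na(r$error) &&
        direction_match(r$diff, sign_h, eps)
    }
    mres <- lapply(c("mondrian4", "mondrian34"), function(d) {
      r <- results[results$model == m & results$display == d, ]
      if (!is.na(r$error)) return(NULL)
      structure(list(display = d, model_id = m, left = r$left,
                     right = r$right, diff = r$diff, raw_min = r$raw_min,
                     raw_max = r$raw_max, params = list(),
                     optional_tier = isTRUE(r$optional_tier)),
                class = "illusion_result")
    })
    grid[m, "mondrians"] <- !any(vapply(mres, is.null, TRUE)) &&
      mondrian_constancy(mres, mondrian_reference, mondrian_delta)
  }

  variant_names <- cat13$name[!is.na(cat13$variant_of)]
  variants <- do.call(rbind, lapply(names(models), function(m) {
    do.call(rbind, lapply(variant_names, function(d) {
      r <- results[results$model == m & results$display == d, ]
      sign_h <- cat13$human_sign[cat13$name == d]
      data.frame(model = m, display = d, diff = r$diff,
                 matched = is.na(r$error) &&
                   direction_match(r$diff, sign_h, eps),
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(
    grid = grid,
    totals = rowSums(grid),
    column_totals = colSums(grid),
    results = results,
    variants = variants,
    optional_tier = vapply(names(models), function(m) {
      any(results$optional_tier[results$model == m], na.rm = TRUE)
    }, TRUE),
    eps = eps, resolution = if (is.null(bundles)) resolution else
      nrow(bundles[[1]]$image),
    ppd = ppd, mode = mode, seed = seed,
    mondrian_reference = mondrian_reference,
    mondrian_delta = mondrian_delta
  ), class = "direction_table")
}

#' @export
print.direction_table <- function(x, ...) {
  sym <- ifelse(x$grid, "o", "x")
  df <- as.data.frame(sym, stringsAsFactors = FALSE)
  df$total <- x$totals
  flagged <- names(x$optional_tier)[x$optional_tier]
  rownames(df) <- ifelse(rownames(df) %in% flagged,
                         paste0(rownames(df), "*"), rownames(df))
  cat("<direction_table> matched directions (o) at eps ", x$eps, "\n",
      sep = "")
  print(df)
  if (length(flagged)) cat("* best-effort tier (fidelity flag)\n")
  n_err <- sum(!is.na(x$results$error))
  if (n_err) cat(n_err, "model/display runs failed (scored unmatched)\n")
  invisible(x)
}
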