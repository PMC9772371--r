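## Writers for stimuli and model outputs.  All luminances in the palette
## and Mondrian draws sit exactly on 8-bit gray levels of the calibration
## map, so an 8-bit gray PNG plus the JSON calibration sidecar is a
## lossless representation of a stimulus.

#' Write a stimulus to disk
#'
#' Writes `<name>.png` (8-bit gray, calibrated), `<name>_mask_left.png`
#' and `<name>_mask_right.png` (binary), and `<name>.json` (name, ppd,
#' px_per_cm, calibration anchors and the luminance palette).
#'
#' @param bundle a `stimulus_bundle`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_stimulus <- function(bundle, dir) {
  stopifnot(inherits(bundle, "stimulus_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, bundle$name)
  gray <- round(luminance_to_gray(bundle$image)) / 255
  png::writePNG(gray, paste0(base, ".png"))
  png::writePNG(bundle$mask_left * 1, paste0(base, "_mask_left.png"))
  png::writePNG(bundle$mask_right * 1, paste0(base, "_mask_right.png"))
  sidecar <- list(
    name = bundle$name, ppd = bundle$ppd, px_per_cm = bundle$px_per_cm,
    target_luminance = bundle$target_luminance,
    target_diameter_px = bundle$target_diameter_px,
    calibration = calibration_anchors(),
    palette = sort(unique(as.vector(bundle$image)))
  )
  jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, c(".png", "_mask_left.png", "_mask_right.png",
                           ".json")))
}

#' Write a model output as a CSV matrix with a JSON parameter record
#'
#' @param output a `model_output` or `lightness_map`.
#' @param file CSV path; the parameter record goes to `<file>.json`.
#' @return invisibly, the CSV path.
#' @export
write_model_output <- function(output, file) {
  values <- if (inherits(output, "lightness_map")) output$values
            else output$response
  utils::write.table(values, file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  rec <- list(model_id = output$model_id, params = output$params,
              optional_tier = isTRUE(output$optional_tier))
  if (inherits(output, "lightness_map")) {
    rec$raw_min <- output$raw_min
    rec$raw_max <- output$raw_max
  }
  jsonlite::write_json(rec, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Write a scoreboard and its per-display results to CSV
#'
#' Writes `scoreboard.csv` (matched grid with row totals and fidelity
#' flags), `results.csv` (per model x display readouts, raw ranges and
#' error annotations), `variants.csv`, and `manifest.json` (the
#' configuration of the run).
#'
#' @param dt a `direction_table`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_scoreboard <- function(dt, dir) {
  stopifnot(inherits(dt, "direction_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- as.data.frame(dt$grid)
  grid <- cbind(model = rownames(dt$grid), grid, total = dt$totals,
                best_effort_tier = dt$optional_tier)
  utils::write.csv(grid, file.path(dir, "scoreboard.csv"),
                   row.names = FALSE)
  utils::write.csv(dt$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(dt$variants, file.path(dir, "variants.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(resolution = dt$resolution, ppd = dt$ppd, eps = dt$eps,
         mode = dt$mode, seed = dt$seed,
         mondrian_reference = dt$mondrian_reference,
         mondrian_delta = dt$mondrian_delta,
         package_version = as.character(utils::packageVersion("lightbench"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
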