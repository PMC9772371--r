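## Display catalogue: the 13 achromatic displays, their target geometry and
## the direction of the human illusion (sign of the left-minus-right mean
## lightness match).  Physical frame is always 9 x 9 cm laid out on a
## 16 x 16 pattern lattice; the printed target sizes are in cm.

LUM_BLACK <- 6
LUM_GRAY  <- 69
LUM_WHITE <- 145
LUM_DARK_TARGET  <- 25
LUM_LIGHT_TARGET <- 105
FRAME_CM <- 9

#' List the benchmark displays
#'
#' Returns the catalogue of the 13 displays: 11 illusions plus the two
#' Mondrian patchworks.  For the illusions, \code{human_sign} gives the
#' direction of the illusion in the human data (+1 when the left target
#' is matched lighter than the right, -1 when darker); the Mondrians have
#' no direction and carry \code{NA}.  \code{scoreboard_category} names the
#' column of the model scoreboard the display contributes to; the SLC
#' luminance variants and the large-stripe White's are variants reported
#' separately and do not enter the row totals.
#'
#' @return data.frame with one row per display: \code{name},
#'   \code{human_sign}, \code{scoreboard_category}, \code{variant_of},
#'   \code{target_w_cm}, \code{target_h_cm} (printed target size),
#'   \code{target_luminance} (cd/m2), \code{symmetric} (TRUE when the right
#'   target mask is the mirror image of the left one), \code{needs_seed}.
#' @export
#' @examples
#' list_displays()
list_displays <- function() {
  df <- data.frame(
    name = c("slc", "slc_dark", "slc_light", "maniatis",
             "whites", "whites_large", "wedding_cake", "reversed_contrast",
             "dungeon", "checkerboard", "bullseye",
             "mondrian4", "mondrian34"),
    human_sign = c(+1, +1, +1, +1,
                   +1, +1, +1, -1,
                   -1, -1, -1,
                   NA, NA),
    scoreboard_category = c("slc", NA, NA, "maniatis",
                            "whites", NA, "wedding_cake", "reversed_contrast",
                            "dungeon", "checkerboard", "bullseye",
                            "mondrians", "mondrians"),
    variant_of = c(NA, "slc", "slc", NA,
                   NA, "whites", NA, NA,
                   NA, NA, NA,
                   NA, NA),
    target_w_cm = c(2.2, 2.2, 2.2, 2.2,
                    1.1, 2.2, 1.5, 2.2,
                    0.5, 1.0, 5.0,
                    2.2, 2.2),
    target_h_cm = c(2.2, 2.2, 2.2, 2.2,
                    2.2, 2.2, 0.5, 0.3,
                    0.5, 1.0, 0.5,
                    2.2, 2.2),
    target_luminance = c(LUM_GRAY, LUM_DARK_TARGET, LUM_LIGHT_TARGET, LUM_GRAY,
                         LUM_GRAY, LUM_GRAY, LUM_GRAY, LUM_GRAY,
                         LUM_GRAY, LUM_GRAY, LUM_GRAY,
                         LUM_GRAY, LUM_GRAY),
    symmetric = c(TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, TRUE,
                  TRUE, FALSE, TRUE,
                  FALSE, FALSE),
    needs_seed = c(FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE,
                   TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  ## area of one target region in cm^2 (bullseye target is a square ring
  ## 0.5 cm thick whose mid-perimeter is 5 cm, so its area is still w x h)
  df$target_area_cm2 <- df$target_w_cm * df$target_h_cm
  df
}

## Names of the eight illusion categories entering the scoreboard rows,
## in scoreboard column order.
illusion_categories <- function() {
  c("slc", "maniatis", "whites", "dungeon",
    "wedding_cake", "checkerboard", "bullseye", "reversed_contrast")
}

display_info <- function(name) {
  cat <- list_displays()
  i <- match(name, cat$name)
  if (is.na(i)) {
    stop("unknown display '", name, "'; see list_displays()")
  }
  cat[i, , drop = FALSE]
}
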