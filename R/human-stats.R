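## Embedded human reference statistics and the paired statistics used to
## analyse matching data.  85 participants matched the left and right
## target of each display four times; matches were recorded as 8-bit gray
## values and normalized to the 0-1 scale by gray/255.

#' Human paired-comparison statistics for the 11 illusion displays
#'
#' Per display: mean left-minus-right difference of the unit-scale matches
#' (`Md`), its standard deviation (`SDd`) and standard error (`SEd`), the
#' paired t statistic, degrees of freedom (84 = participants - 1), the
#' printed p bound and Cohen's d for paired data (`Md / SDd`).
#'
#' @return data.frame with one row per illusion display.
#' @export
#' @examples
#' table1_stats()[, c("display", "Md", "d")]
table1_stats <- function() {
  data.frame(
    display = c("slc", "maniatis", "whites", "wedding_cake",
                "reversed_contrast", "dungeon", "checkerboard", "bullseye",
                "slc_dark", "slc_light", "whites_large"),
    Md  = c(0.060, 0.040, 0.050, 0.027, -0.015, -0.098, -0.038, -0.073,
            0.059, 0.048, 0.024),
    SDd = c(0.057, 0.044, 0.050, 0.054, 0.048, 0.071, 0.043, 0.051,
            0.047, 0.064, 0.040),
    SEd = c(0.006, 0.005, 0.005, 0.006, 0.005, 0.008, 0.005, 0.006,
            0.005, 0.007, 0.004),
    t   = c(9.744, 8.285, 9.103, 4.557, -2.876, -12.598, -8.103, -13.324,
            11.606, 6.930, 5.464),
    df  = rep(84L, 11),
    p_bound = c(1e-4, 1e-4, 1e-4, 1e-4, 0.005, 1e-4, 1e-4, 1e-4,
                1e-4, 1e-4, 1e-4),
    d   = c(1.057, 0.899, 0.987, 0.494, -0.312, -1.366, -0.879, -1.445,
            1.259, 0.752, 0.593),
    stringsAsFactors = FALSE
  )
}

#' Paired-sample statistics on per-participant matches
#'
#' @param left,right numeric vectors of per-participant mean matches
#'   (unit lightness), paired by position.
#' @return list with `Md` (mean difference), `SDd` (sample sd, n - 1
#'   denominator), `SEd`, `t`, `df`, `p` (two-sided) and `d` (Cohen's d
#'   for paired data).
#' @export
#' @examples
#' paired_stats(c(0.5, 0.6, 0.7), c(0.4, 0.55, 0.6))
paired_stats <- function(left, right) {
  stopifnot(is.numeric(left), is.numeric(right))
  if (length(left) != length(right)) stop("left and right must be paired")
  n <- length(left)
  if (n < 2) stop("need at least two pairs")
  diffs <- left - right
  Md <- mean(diffs)
  SDd <- stats::sd(diffs)
  if (SDd == 0) stop("zero variance of differences: t undefined")
  SEd <- SDd / sqrt(n)
  t <- Md / SEd
  df <- n - 1L
  list(Md = Md, SDd = SDd, SEd = SEd, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df), d = Md / SDd)
}

#' One-sample statistics against a fixed reference lightness
#'
#' @param values numeric vector of per-participant matches.
#' @param reference scalar unit lightness to test against.
#' @return list with `mean`, `t`, `df`, `p` (two-sided).
#' @export
one_sample_stats <- function(values, reference) {
  stopifnot(is.numeric(values), length(reference) == 1)
  n <- length(values)
  if (n < 2) stop("need at least two values")
  s <- stats::sd(values)
  if (s == 0) {
    if (mean(values) == reference) {
      return(list(mean = reference, t = 0, df = n - 1L, p = 1))
    }
    stop("zero variance: t undefined")
  }
  t <- (mean(values) - reference) / (s / sqrt(n))
  list(mean = mean(values), t = t, df = n - 1L,
       p = 2 * stats::pt(-abs(t), n - 1L))
}

#' Compare illusion magnitudes between two displays
#'
#' Paired t-test over per-participant illusion magnitudes (left minus
#' right mean match) of two displays, e.g. the standard versus the
#' dark-target SLC.
#'
#' @param matches a `match_data` object.
#' @param display_a,display_b display identifiers present in `matches`.
#' @return as [paired_stats()].
#' @export
contrast_illusion_sizes <- function(matches, display_a, display_b) {
  stopifnot(inherits(matches, "match_data"))
  mag <- function(d) {
    sub <- matches[matches$display == d, , drop = FALSE]
    if (nrow(sub) == 0) stop("display '", d, "' not present in matches")
    pm <- stats::aggregate(match ~ participant + side, sub, mean)
    wide <- stats::reshape(pm, idvar = "participant", timevar = "side",
                           direction = "wide")
    if (anyNA(wide) || !all(c("match.left", "match.right") %in% names(wide))) {
      stop("both sides required for every participant in '", d, "'")
    }
    wide <- wide[order(wide$participant), ]
    data.frame(participant = wide$participant,
               mag = wide$match.left - wide$match.right)
  }
  a <- mag(display_a); b <- mag(display_b)
  if (!identical(a$participant, b$participant)) {
    stop("participants must be present for both displays")
  }
  paired_stats(a$mag, b$mag)
}

#' Construct a matching-data table
#'
#' @param df data.frame with columns `participant`, `display`, `side`
#'   (`"left"`/`"right"`), `repetition` and `gray` (8-bit match).
#' @return a validated `match_data` data.frame with the additional unit
#'   column `match = gray / 255`.
#' @export
match_data <- function(df) {
  need <- c("participant", "display", "side", "repetition", "gray")
  if (!all(need %in% names(df))) {
    stop("matches table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  if (nrow(df) > 0) {
    if (any(df$gray < 0 | df$gray > 255)) {
      stop("gray values must lie in [0, 255]")
    }
    if (!all(df$side %in% c("left", "right"))) {
      stop("side must be 'left' or 'right'")
    }
    key <- paste(df$participant, df$display, df$side, df$repetition)
    if (anyDuplicated(key)) {
      stop("duplicate (participant, display, side, repetition) records")
    }
    reps <- stats::aggregate(repetition ~ participant + display + side,
                             df, length)
    if (any(reps$repetition > 4)) {
      stop("more than 4 repetitions per (participant, display, side)")
    }
  }
  df$match <- df$gray / 255
  class(df) <- c("match_data", "data.frame")
  df
}

#' Load a raw-matches table from CSV
#'
#' Reads a five-column CSV (`participant, display, side, repetition,
#' gray`) such as the supplementary raw data of the matching experiment,
#' validates it and converts gray to unit lightness.
#'
#' @param file path to the CSV file.
#' @return a `match_data` object (possibly with zero rows).
#' @export
load_matches <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  match_data(df)
}

#' Write a matches table to CSV
#'
#' @param matches a `match_data` object.
#' @param file output path.
#' @export
write_matches <- function(matches, file) {
  stopifnot(inherits(matches, "match_data"))
  utils::write.csv(
    matches[, c("participant", "display", "side", "repetition", "gray")],
    file, row.names = FALSE)
  invisible(file)
}

## per-participant mean matches of one display, wide by side
participant_means <- function(matches, display) {
  sub <- matches[matches$display == display, , drop = FALSE]
  pm <- stats::aggregate(match ~ participant + side, sub, mean)
  left <- pm[pm$side == "left", ]
  right <- pm[pm$side == "right", ]
  left <- left[order(left$participant), ]
  right <- right[order(right$participant), ]
  stopifnot(identical(left$participant, right$participant))
  list(left = left$match, right = right$match,
       participant = left$participant)
}
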